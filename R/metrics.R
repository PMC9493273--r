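#' Within-environment predictive correlations
#'
#' For every environment with at least 3 predicted records and
#' non-degenerate variation, computes the Pearson correlation r_j between
#' predicted and observed values and its sampling variance
#' V(r_j) = (1 - r_j^2) / (n_j - 2).
#'
#' @param result a `cv_result` (or any data frame with columns `env`,
#'   `observed`, `predicted`).
#' @return list with `correlations` (data frame: env, r, n, V; `|r| = 1`
#'   is snapped to exact unity so V = 0) and `skipped` (data frame: env,
#'   reason) for environments with fewer than 3 records or degenerate
#'   variance.  Entries with V = 0 (infinite weight) are excluded later,
#'   by [weighted_mean_correlation()].
#' @export
env_correlations <- function(result) {
  df <- if (inherits(result, "cv_result")) result$predictions else result
  stopifnot(all(c("env", "observed", "predicted") %in% names(df)))
  envs <- unique(df$env)
  rows <- list()
  skipped <- list()
  skip <- function(e, why) {
    skipped[[length(skipped) + 1L]] <<- data.frame(env = e, reason = why,
                                                   stringsAsFactors = FALSE)
  }
  for (e in envs) {
    d <- df[df$env == e, ]
    n <- nrow(d)
    if (n < 3L) { skip(e, "fewer than 3 records"); next }
    if (stats::sd(d$observed) == 0 || stats::sd(d$predicted) == 0) {
      skip(e, "zero variance"); next
    }
    r <- stats::cor(d$observed, d$predicted)
    if (abs(r) > 1 - 1e-12) r <- sign(r)
    V <- (1 - r^2) / (n - 2)
    rows[[length(rows) + 1L]] <- data.frame(env = e, r = r, n = n, V = V,
                                            stringsAsFactors = FALSE)
  }
  list(correlations = do.call(rbind, rows),
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}

#' Inverse-variance weighted mean of within-environment correlations
#'
#' Computes r_w = sum_j (r_j / V_j) / sum_j (1 / V_j) with
#' V_j = (1 - r_j^2)/(n_j - 2), the across-environment predictive-ability
#' summary that downweights small or noisy environments.
#'
#' Environments with V = 0 (perfect correlation, infinite weight) are
#' excluded.
#'
#' @param entries output of [env_correlations()], or its `correlations`
#'   data frame.
#' @return the weighted mean correlation (scalar).
#' @export
weighted_mean_correlation <- function(entries) {
  df <- if (is.list(entries) && !is.data.frame(entries)) {
    entries$correlations
  } else entries
  if (!is.null(df)) df <- df[is.finite(df$V) & df$V > 0, , drop = FALSE]
  if (is.null(df) || nrow(df) == 0L) {
    stop("no eligible environments for the weighted mean correlation",
         call. = FALSE)
  }
  w <- 1 / df$V
  sum(df$r * w) / sum(w)
}

#' Percentage of phenotypic variability per model term
#'
#' Converts a variance-component table into the percentage of explained
#' variability: each component divided by the sum of all components, times
#' 100.  The `"within"` scope removes the environment main effect E from
#' both numerator set and denominator, giving the within-environment
#' decomposition.
#'
#' @param components data frame with columns `term` and `estimate` (e.g.
#'   from [variance_components()]), or a named numeric vector.
#' @param scope `"across"` or `"within"`.
#' @return data frame with columns `term` and `pct`, summing to 100.
#' @export
variance_percentages <- function(components, scope = c("across", "within")) {
  scope <- match.arg(scope)
  if (is.numeric(components)) {
    components <- data.frame(term = names(components),
                             estimate = unname(components),
                             stringsAsFactors = FALSE)
  }
  stopifnot(all(c("term", "estimate") %in% names(components)))
  if (any(components$estimate < 0)) {
    stop("variance components must be nonnegative", call. = FALSE)
  }
  if (scope == "within") {
    components <- components[components$term != "E", , drop = FALSE]
  }
  total <- sum(components$estimate)
  if (total <= 0) stop("all variance components are zero", call. = FALSE)
  data.frame(term = components$term,
             pct = 100 * components$estimate / total,
             stringsAsFactors = FALSE)
}

#' Percentile classification grid of predicted versus observed values
#'
#' Categorizes predictions and observations by their own empirical 20/50/80
#' percentiles (linear interpolation between order statistics; boundary
#' values fall in the lower category) and tabulates the conditional
#' proportion of observed categories given each predicted category.  The
#' (top, top) and (bottom, bottom) cells are the top-20% and bottom-20%
#' classification success rates.  Also reports the R-squared of the
#' ordinary least-squares regression of observed on predicted, the mean
#' squared error, and (when environment labels are supplied) the weighted
#' mean correlation.
#'
#' @param pred,obs numeric vectors of equal length >= 5.
#' @param cuts percentile cut points (default 20/50/80).
#' @param env optional environment labels for the r_w summary.
#' @return list of class `percentile_grid`: `proportions` (4x4 matrix,
#'   rows = observed categories, columns = predicted categories, columns
#'   sum to 1), `top20`, `bottom20`, `r_squared`, `mse`, `r_w` (or `NA`),
#'   `counts`, and `empty_categories` flag.
#' @export
percentile_grid <- function(pred, obs, cuts = c(20, 50, 80), env = NULL) {
  stopifnot(length(pred) == length(obs))
  if (length(pred) < 5L) stop("need at least 5 points", call. = FALSE)
  categorize <- function(x) {
    q <- stats::quantile(x, probs = cuts / 100, type = 7, names = FALSE)
    cut(x, breaks = c(-Inf, q, Inf), labels = FALSE, right = TRUE)
  }
  pc <- categorize(pred)
  oc <- categorize(obs)
  nc <- length(cuts) + 1L
  counts <- matrix(0L, nc, nc)
  for (i in seq_along(pc)) counts[oc[i], pc[i]] <- counts[oc[i], pc[i]] + 1L
  labels <- c("bottom20", "20-50", "50-80", "top20")[seq_len(nc)]
  dimnames(counts) <- list(observed = labels, predicted = labels)
  col_n <- colSums(counts)
  props <- sweep(counts, 2L, pmax(col_n, 1L), "/")
  r_w <- NA_real_
  if (!is.null(env)) {
    ec <- env_correlations(data.frame(env = env, observed = obs,
                                      predicted = pred))
    r_w <- tryCatch(weighted_mean_correlation(ec),
                    error = function(e) NA_real_)
  }
  structure(list(
    proportions = props,
    counts = counts,
    top20 = props[nc, nc],
    bottom20 = props[1L, 1L],
    # R^2 of the OLS regression of observed on predicted; for a simple
    # regression this equals the squared Pearson correlation
    r_squared = if (stats::sd(pred) > 0 && stats::sd(obs) > 0) {
      stats::cor(obs, pred)^2
    } else NA_real_,
    mse = mean((obs - pred)^2),
    r_w = r_w,
    empty_categories = any(col_n == 0L)),
    class = "percentile_grid")
}

#' @export
print.percentile_grid <- function(x, ...) {
  cat("Percentile classification grid (conditional proportions)\n")
  print(round(x$proportions, 2))
  cat(sprintf("top-20 success %.2f | bottom-20 success %.2f | R2 %.2f | MSE %.1f",
              x$top20, x$bottom20, x$r_squared, x$mse))
  if (!is.na(x$r_w)) cat(sprintf(" | r_w %.3f", x$r_w))
  cat("\n")
  invisible(x)
}

#' Environment-centered overall genotype performance
#'
#' Within each environment, subtracts the environment mean from the
#' observed and from the predicted values, then averages the centered
#' values per line across environments.  The resulting per-line pairs
#' summarize overall genotype merit free of environment level differences
#' and feed [percentile_grid()].
#'
#' @param result a `cv_result` or data frame with columns `line`, `env`,
#'   `observed`, `predicted`.
#' @return data frame with columns `line`, `observed`, `predicted`
#'   (centered per-line means).
#' @export
genotype_overall <- function(result) {
  df <- if (inherits(result, "cv_result")) result$predictions else result
  stopifnot(all(c("line", "env", "observed", "predicted") %in% names(df)))
  obs_c <- df$observed - stats::ave(df$observed, df$env)
  pred_c <- df$predicted - stats::ave(df$predicted, df$env)
  lines <- unique(df$line)
  data.frame(
    line = lines,
    observed = as.numeric(tapply(obs_c, df$line, mean)[lines]),
    predicted = as.numeric(tapply(pred_c, df$line, mean)[lines]),
    stringsAsFactors = FALSE)
}
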