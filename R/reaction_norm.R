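#' Prior specification for variance components
#'
#' Every variance component (one per model term, plus the residual) gets a
#' scaled-inverse-chi-square prior with degrees of freedom `df` and scale
#' `Sc`.  When `scales` is `NULL` the scales are derived at fit time so
#' that the prior mode of each model term equals an equal share of `R2`
#' times the observed phenotypic variance, and the residual prior mode
#' equals the remaining `1 - R2` share: with mode = Sc * df / (df + 2),
#' `Sc_t = mode_t * (df + 2) / df`.
#'
#' @param df prior degrees of freedom (> 0), shared by all terms.
#' @param scales optional named numeric vector of prior scales (one entry
#'   per model term plus `"R"` for the residual); overrides the automatic
#'   derivation.
#' @param R2 share of phenotypic variance assigned, a priori, to the model
#'   terms jointly (default 0.5).
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(df = 5, scales = NULL, R2 = 0.5) {
  if (df <= 0) stop("prior degrees of freedom must be positive",
                    call. = FALSE)
  if (!is.null(scales) && any(scales <= 0)) {
    stop("prior scales must be positive", call. = FALSE)
  }
  if (R2 <= 0 || R2 >= 1) stop("R2 must lie in (0, 1)", call. = FALSE)
  structure(list(df = df, scales = scales, R2 = R2), class = "prior_spec")
}

#' Derive the actual prior scales for a fit
#' @noRd
resolve_priors <- function(priors, terms, vary) {
  df <- priors$df
  if (!is.null(priors$scales)) {
    need <- c(terms, "R")
    if (!all(need %in% names(priors$scales))) {
      stop("prior scales must be named for each of: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    return(list(df = df, Sc = priors$scales[need]))
  }
  # floor keeps the sampler non-degenerate when the observed phenotypes
  # are (numerically) constant
  vary <- max(vary, 1e-8)
  mode_term <- priors$R2 * vary / length(terms)
  mode_res <- (1 - priors$R2) * vary
  Sc <- c(stats::setNames(rep(mode_term * (df + 2) / df, length(terms)),
                          terms),
          R = mode_res * (df + 2) / df)
  list(df = df, Sc = Sc)
}

#' MCMC settings for the Gibbs sampler
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded before summarizing (< `n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; identical inputs and seed give bit-identical
#'   results.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(n_iter = 12000, burn_in = 2000, thin = 5,
                         seed = 1) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter",
                              call. = FALSE)
  if (thin < 1) stop("thin must be >= 1", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_control")
}

# Eigendecomposition of a record-level kernel, truncated to numerically
# positive eigenvalues.  Computed once per fit and reused by every Gibbs
# update of that term.
kernel_eigen <- function(K, tol = 1e-8) {
  ee <- eigen(K, symmetric = TRUE)
  lmax <- max(ee$values, 0)
  if (min(ee$values) < -tol * max(lmax, 1)) {
    stop("kernel is not positive semidefinite within tolerance",
         call. = FALSE)
  }
  keep <- ee$values > tol * max(lmax, 1)
  list(vectors = ee$vectors[, keep, drop = FALSE],
       values = ee$values[keep])
}

#' Fit a soil-augmented reaction-norm genomic prediction model
#'
#' Fits the hierarchical model
#' \deqn{y = \mu + \sum_t u_t + \varepsilon, \quad
#'       u_t \sim N(0, K_t \sigma^2_t), \quad
#'       \varepsilon \sim N(0, I\sigma^2_\varepsilon)}
#' by Gibbs sampling, where the record-level kernels \eqn{K_t} are those of
#' the requested model (see [model_kernels()]): environment, line, soil and
#' genomic main effects plus Hadamard-structured marker-by-environment and
#' marker-by-soil interactions.  Each \eqn{u_t} is reparameterized through
#' the eigendecomposition \eqn{K_t = \Gamma_t \Lambda_t \Gamma_t'} as
#' \eqn{u_t = \Gamma_t \alpha_t} with independent coordinates, giving
#' closed-form normal full conditionals; the variances have conjugate
#' scaled-inverse-chi-square full conditionals.  Records whose yield is
#' `NA`, or that are listed in `mask`, are treated as missing and imputed
#' from the current linear predictor plus residual noise each iteration
#' (data augmentation), so a single code path serves the full-data fit and
#' every cross-validation scheme.
#'
#' @param table a `trial_table` (see [trial_table()]).
#' @param markers a `marker_matrix` covering every line in `table`; ignored
#'   when `kernels` is supplied.
#' @param model one of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_control()].
#' @param mask optional integer or logical index of records whose yield is
#'   withheld from training and predicted.
#' @param kernels optional precomputed `kernel_set` (e.g. to reuse across
#'   cross-validation folds); must match `table` row order.
#' @param fixed_variances optional named numeric vector (terms plus `"R"`)
#'   of variance components; when given, variance sampling is disabled and
#'   the sampler conditions on these values (used for oracle checks).
#' @param G optional precomputed genomic relationship matrix.
#' @return object of class `reaction_norm` with posterior summaries:
#'   `mu`, `varcomp` (posterior mean, SD and effective sample size per
#'   variance component), `u` (posterior-mean effect vectors per term),
#'   `yhat` (posterior mean linear predictor for all records), `mask`, and
#'   retained prediction/variance samples.
#' @seealso [predict.reaction_norm()], [variance_components()],
#'   [mme_oracle()]
#' @export
reaction_norm <- function(table, markers = NULL, model = "M3",
                          priors = prior_spec(), mcmc = mcmc_control(),
                          mask = NULL, kernels = NULL,
                          fixed_variances = NULL, G = NULL) {
  stopifnot(inherits(table, "trial_table"))
  if (is.null(kernels)) {
    if (is.null(G)) {
      if (is.null(markers)) {
        stop("supply markers, G, or a precomputed kernel set", call. = FALSE)
      }
      G <- genomic_relationship(markers)
    }
    kernels <- model_kernels(model, table, G)
  }
  model <- kernels$model
  n <- nrow(table)
  if (kernels$n != n) stop("kernel set does not match the trial table",
                           call. = FALSE)

  y <- table$yield
  miss <- rep(FALSE, n)
  if (!is.null(mask)) {
    miss[mask] <- TRUE
  }
  miss <- miss | is.na(y)
  obs <- !miss
  if (sum(obs) < 2L) stop("need at least 2 observed records", call. = FALSE)

  terms <- names(kernels$kernels)
  eig <- lapply(kernels$kernels, kernel_eigen)
  pr <- resolve_priors(priors, terms, stats::var(y[obs]))
  df <- pr$df

  fixed <- !is.null(fixed_variances)
  if (fixed) {
    need <- c(terms, "R")
    if (!all(need %in% names(fixed_variances))) {
      stop("fixed_variances must name each of: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    if (any(fixed_variances[need] <= 0)) {
      stop("fixed variances must be positive", call. = FALSE)
    }
  }

  # --- initialization -------------------------------------------------
  rng_has_state <- exists(".Random.seed", envir = .GlobalEnv)
  if (rng_has_state) old_seed <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(if (rng_has_state) {
    assign(".Random.seed", old_seed, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(mcmc$seed)

  mu <- mean(y[obs])
  sig <- if (fixed) fixed_variances[terms] else {
    stats::setNames(pr$Sc[terms] * df / (df + 2), terms)
  }
  sig_e <- if (fixed) unname(fixed_variances["R"]) else {
    unname(pr$Sc["R"] * df / (df + 2))
  }
  alpha <- lapply(eig, function(e) numeric(length(e$values)))
  u <- lapply(eig, function(e) numeric(n))
  usum <- numeric(n)
  y_cur <- y
  y_cur[miss] <- mu
  r <- y_cur - mu

  n_keep <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
  keep_sig <- matrix(NA_real_, n_keep, length(terms) + 1L,
                     dimnames = list(NULL, c(terms, "R")))
  keep_mu <- numeric(n_keep)
  keep_pred <- matrix(NA_real_, n_keep, sum(miss))
  eta_sum <- numeric(n)
  u_sum <- lapply(terms, function(t) numeric(n))
  names(u_sum) <- terms
  kept <- 0L

  # --- Gibbs loop -----------------------------------------------------
  for (it in seq_len(mcmc$n_iter)) {
    # grand mean (flat prior)
    mu_new <- stats::rnorm(1, mu + mean(r), sqrt(sig_e / n))
    r <- r + (mu - mu_new)
    mu <- mu_new

    for (t in terms) {
      Gam <- eig[[t]]$vectors
      lam <- eig[[t]]$values
      v <- drop(crossprod(Gam, r)) + alpha[[t]]
      prec <- 1 / sig_e + 1 / (sig[[t]] * lam)
      m <- (v / sig_e) / prec
      a_new <- m + stats::rnorm(length(lam)) / sqrt(prec)
      u_new <- drop(Gam %*% a_new)
      r <- r + u[[t]] - u_new
      usum <- usum - u[[t]] + u_new
      alpha[[t]] <- a_new
      u[[t]] <- u_new
      if (!fixed) {
        ss <- sum(a_new^2 / lam)
        sig[[t]] <- (df * pr$Sc[[t]] + ss) /
          stats::rchisq(1, df + length(lam))
      }
    }

    # data augmentation for masked / missing records
    if (any(miss)) {
      eta_miss <- mu + usum[miss]
      noise <- stats::rnorm(sum(miss), 0, sqrt(sig_e))
      y_cur[miss] <- eta_miss + noise
      r[miss] <- noise
    }

    if (!fixed) {
      sig_e <- (df * pr$Sc[["R"]] + sum(r^2)) / stats::rchisq(1, df + n)
    }

    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0L) {
      kept <- kept + 1L
      eta <- mu + usum
      eta_sum <- eta_sum + eta
      keep_mu[kept] <- mu
      keep_sig[kept, ] <- c(unlist(sig), sig_e)
      if (any(miss)) keep_pred[kept, ] <- eta[miss]
      for (t in terms) u_sum[[t]] <- u_sum[[t]] + u[[t]]
    }
  }

  yhat <- eta_sum / kept
  varcomp <- data.frame(
    term = c(terms, "R"),
    estimate = colMeans(keep_sig),
    sd = apply(keep_sig, 2L, stats::sd),
    ess = apply(keep_sig, 2L, ess),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(
    model = model,
    table = table,
    terms = terms,
    mask = which(miss),
    mu = c(mean = mean(keep_mu), sd = stats::sd(keep_mu)),
    varcomp = varcomp,
    u = lapply(u_sum, function(v) v / kept),
    yhat = yhat,
    samples = list(mu = keep_mu, sigma = keep_sig, pred = keep_pred),
    priors = pr,
    mcmc = mcmc,
    fixed_variances = if (fixed) fixed_variances else NULL,
    call = match.call()),
    class = "reaction_norm")
}

# Effective sample size from the empirical autocorrelation function,
# truncated at the first non-positive lag (initial positive sequence).
ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  cut <- which(ac <= 0)
  if (length(cut) > 0L) ac <- ac[seq_len(cut[1L] - 1L)]
  max(1, n / (1 + 2 * sum(ac)))
}

#' Closed-form mixed-model prediction oracle with fixed variances
#'
#' With all variance components known, the model is a Gaussian process on
#' the records with covariance \eqn{C = \sum_t \sigma^2_t K_t}: the best
#' linear predictor of the test records is
#' \deqn{\hat y_{test} = C_{test,train} (C_{train,train} +
#'   \sigma^2_\varepsilon I)^{-1} (y_{train} - \bar y) + \bar y.}
#' Deterministic; used as an independent cross-check of the Gibbs sampler.
#'
#' @param y numeric response over all records.
#' @param train logical or integer index of training records.
#' @param kernels a `kernel_set`.
#' @param variances named numeric vector of variance components (one per
#'   kernel term plus `"R"` for the residual), all > 0.
#' @return numeric vector of predictions for every record (training
#'   records get their leave-nothing-out BLUP as well).
#' @export
mme_oracle <- function(y, train, kernels, variances) {
  terms <- names(kernels$kernels)
  need <- c(terms, "R")
  if (!all(need %in% names(variances))) {
    stop("variances must name each of: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(variances[need] < 0) || variances[["R"]] <= 0) {
    stop("variances must be nonnegative with a positive residual",
         call. = FALSE)
  }
  n <- kernels$n
  tr <- rep(FALSE, n)
  tr[train] <- TRUE
  if (is.logical(train)) tr <- train
  C <- matrix(0, n, n)
  for (t in terms) C <- C + variances[[t]] * kernels$kernels[[t]]
  ybar <- mean(y[tr])
  A <- C[tr, tr, drop = FALSE]
  diag(A) <- diag(A) + variances[["R"]]
  rhs <- y[tr] - ybar
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    diag(A) <- diag(A) + 1e-8
    solve(A, rhs)
  })
  drop(C[, tr, drop = FALSE] %*% sol) + ybar
}

#' Posterior variance-component table
#'
#' @param fit a `reaction_norm` fit.
#' @return data frame with one row per model term plus the residual `R`:
#'   posterior mean, posterior SD and effective sample size.
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "reaction_norm"))
  fit$varcomp
}

#' @export
print.reaction_norm <- function(x, ...) {
  cat("Reaction-norm genomic prediction fit (model ", x$model, ")\n",
      sep = "")
  cat("  records: ", nrow(x$table), " (", length(x$mask), " masked)\n",
      sep = "")
  cat("  terms:   ", paste(x$terms, collapse = " + "), "\n", sep = "")
  cat("  mu:      ", signif(x$mu[["mean"]], 5), "\n", sep = "")
  cat("  variance components (posterior means):\n")
  vc <- x$varcomp
  cat(paste0("    ", format(vc$term, width = 4), " ",
             format(signif(vc$estimate, 4), width = 10), "\n"), sep = "")
  invisible(x)
}

#' @export
summary.reaction_norm <- function(object, ...) {
  vc <- object$varcomp
  vc$pct_across <- 100 * vc$estimate / sum(vc$estimate)
  keep <- vc$term != "E"
  vc$pct_within <- NA_real_
  vc$pct_within[keep] <- 100 * vc$estimate[keep] / sum(vc$estimate[keep])
  out <- list(model = object$model, mu = object$mu, varcomp = vc,
              n = nrow(object$table), n_masked = length(object$mask),
              mcmc = object$mcmc)
  class(out) <- "summary.reaction_norm"
  out
}

#' @export
print.summary.reaction_norm <- function(x, ...) {
  cat("Reaction-norm fit, model ", x$model, " (", x$n, " records, ",
      x$n_masked, " masked)\n", sep = "")
  cat("MCMC: ", x$mcmc$n_iter, " iterations, burn-in ", x$mcmc$burn_in,
      ", thin ", x$mcmc$thin, "\n\n", sep = "")
  vc <- x$varcomp
  vc$estimate <- signif(vc$estimate, 4)
  vc$sd <- signif(vc$sd, 3)
  vc$ess <- round(vc$ess)
  vc$pct_across <- round(vc$pct_across, 1)
  vc$pct_within <- round(vc$pct_within, 1)
  print(vc, row.names = FALSE)
  invisible(x)
}

#' @export
coef.reaction_norm <- function(object, ...) {
  stats::setNames(object$varcomp$estimate, object$varcomp$term)
}

#' @export
fitted.reaction_norm <- function(object, ...) object$yhat

#' @export
residuals.reaction_norm <- function(object, ...) {
  object$table$yield - object$yhat
}

#' Predictions from a reaction-norm fit
#'
#' @param object a `reaction_norm` fit.
#' @param what `"masked"` (default) returns the records that were withheld
#'   during fitting; `"all"` returns every record.
#' @param ... unused.
#' @return data frame with record index, line, environment, observed yield
#'   and posterior-mean prediction.
#' @export
predict.reaction_norm <- function(object, what = c("masked", "all"), ...) {
  what <- match.arg(what)
  idx <- if (what == "masked") object$mask else seq_len(nrow(object$table))
  data.frame(record = idx,
             line = object$table$line[idx],
             env = object$table$env[idx],
             observed = object$table$yield[idx],
             predicted = object$yhat[idx],
             stringsAsFactors = FALSE)
}

#' @export
plot.reaction_norm <- function(x, ...) {
  obs <- x$table$yield
  graphics::plot(x$yhat, obs, xlab = "predicted yield",
                 ylab = "observed yield",
                 main = paste("Model", x$model), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate phenotypes from a fitted reaction-norm model
#'
#' Draws new phenotype vectors from the fitted generative model, i.e.
#' \eqn{\hat\mu + \sum_t u_t + \varepsilon} with fresh
#' \eqn{u_t \sim N(0, K_t\hat\sigma^2_t)}.  Kernel eigendecompositions are
#' recomputed from the stored trial table.
#'
#' @param object a `reaction_norm` fit carrying its kernel structure (refit
#'   objects always do); requires the original `markers`/`G` via
#'   `kernels`.
#' @param nsim number of replicate phenotype vectors.
#' @param seed integer seed.
#' @param kernels the `kernel_set` used in fitting (kernels are not stored
#'   on the fit object to keep it light).
#' @param ... unused.
#' @return matrix with `nsim` columns of simulated yields.
#' @export
simulate.reaction_norm <- function(object, nsim = 1, seed = NULL,
                                   kernels = NULL, ...) {
  if (is.null(kernels)) {
    stop("supply the kernel_set used for fitting", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  vc <- stats::setNames(object$varcomp$estimate, object$varcomp$term)
  n <- kernels$n
  out <- matrix(NA_real_, n, nsim)
  eig <- lapply(kernels$kernels, kernel_eigen)
  for (s in seq_len(nsim)) {
    y <- rep(object$mu[["mean"]], n)
    for (t in object$terms) {
      lam <- eig[[t]]$values
      z <- stats::rnorm(length(lam), 0, sqrt(vc[[t]] * lam))
      y <- y + drop(eig[[t]]$vectors %*% z)
    }
    out[, s] <- y + stats::rnorm(n, 0, sqrt(vc[["R"]]))
  }
  out
}
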