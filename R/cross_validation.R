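#' Training/testing partitions for the four breeding CV schemes
#'
#' Generates the partitions used to benchmark genomic prediction across
#' breeding scenarios:
#' \describe{
#'   \item{CV2}{tested genotypes, observed environments: records are
#'     randomly assigned to `k` folds (incomplete field trials); `reps`
#'     replicates.}
#'   \item{CV1}{untested genotypes, observed environments: whole lines are
#'     assigned to folds, so all records of a line share its fold.}
#'   \item{CV0}{tested genotypes, unobserved environments: leave one
#'     environment out, training on all other environments (no
#'     randomness, one partition per environment).}
#'   \item{CV00}{untested genotypes, unobserved environments: as CV0, but
#'     every record, in any environment, of the lines present in the
#'     held-out environment is also removed from training.}
#' }
#'
#' @param scheme one of `"CV2"`, `"CV1"`, `"CV0"`, `"CV00"`.
#' @param table a `trial_table`.
#' @param k number of folds (CV2/CV1).
#' @param reps number of replicates (CV2/CV1).
#' @param seed master seed; replicate r uses `seed + r` so replicates are
#'   reproducible and independent.
#' @return list of partitions; each has `scheme`, `replicate`, `fold`
#'   (fold number or held-out environment label), `train` and `test`
#'   integer record indices, and for CV00 an `empty_train` flag.
#' @export
cv_partitions <- function(scheme = c("CV2", "CV1", "CV0", "CV00"),
                          table, k = 5, reps = 10, seed = 1) {
  scheme <- match.arg(scheme)
  n <- nrow(table)
  if (n == 0L) stop("empty trial table", call. = FALSE)
  out <- list()

  if (scheme %in% c("CV2", "CV1")) {
    units <- if (scheme == "CV2") seq_len(n) else unique(table$line)
    if (k > length(units)) {
      stop("k = ", k, " exceeds the number of ",
           if (scheme == "CV2") "records" else "lines", call. = FALSE)
    }
    for (r in seq_len(reps)) {
      rng_state <- if (exists(".Random.seed", envir = .GlobalEnv)) {
        get(".Random.seed", envir = .GlobalEnv)
      }
      set.seed(seed + r)
      fold_of <- sample(rep_len(seq_len(k), length(units)))
      if (!is.null(rng_state)) {
        assign(".Random.seed", rng_state, envir = .GlobalEnv)
      }
      for (f in seq_len(k)) {
        test_units <- units[fold_of == f]
        test <- if (scheme == "CV2") test_units else {
          which(table$line %in% test_units)
        }
        out[[length(out) + 1L]] <- list(
          scheme = scheme, replicate = r, fold = f,
          train = setdiff(seq_len(n), test), test = sort(test))
      }
    }
    return(out)
  }

  envs <- unique(table$env)
  if (length(envs) < 2L) {
    stop(scheme, " needs at least 2 environments", call. = FALSE)
  }
  for (e in envs) {
    test <- which(table$env == e)
    train <- which(table$env != e)
    part <- list(scheme = scheme, replicate = 1L, fold = e,
                 train = train, test = test)
    if (scheme == "CV00") {
      test_lines <- unique(table$line[test])
      part$train <- setdiff(train, which(table$line %in% test_lines))
      part$empty_train <- length(part$train) == 0L
      if (part$empty_train) {
        warning("CV00 training set is empty for environment '", e, "'",
                call. = FALSE)
      }
    }
    out[[length(out) + 1L]] <- part
  }
  out
}

#' Export a list of partitions as a manifest data frame
#'
#' @param parts output of [cv_partitions()].
#' @param table the `trial_table` the partitions refer to.
#' @return data frame with columns scheme, replicate, fold, record, line,
#'   env, role (train/test); writable with [utils::write.csv()].
#' @export
cv_manifest <- function(parts, table) {
  do.call(rbind, lapply(parts, function(p) {
    idx <- c(p$train, p$test)
    data.frame(scheme = p$scheme, replicate = p$replicate,
               fold = as.character(p$fold), record = idx,
               line = table$line[idx], env = table$env[idx],
               role = rep(c("train", "test"),
                          c(length(p$train), length(p$test))),
               stringsAsFactors = FALSE)
  }))
}

#' Run a model through a cross-validation scheme
#'
#' For every partition the test records' yields are masked, the model is
#' refitted from scratch, and the posterior-mean predictions for the
#' masked records are collected.  Kernel eigendecompositions depend on the
#' full record set only, so the kernel set is built once and shared across
#' partitions.
#'
#' @param table a `trial_table` (aligned with `markers`).
#' @param markers a `marker_matrix`; ignored when `G` is given.
#' @param model one of `"M1"`..`"M4"`.
#' @param scheme one of `"CV2"`, `"CV1"`, `"CV0"`, `"CV00"`.
#' @param k,reps fold count and replicate count (CV2/CV1).
#' @param seed master seed; drives both the partitions and the per-fit
#'   sampler seeds.
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_control()]; its seed is replaced by one derived
#'   from `seed` and the partition index.
#' @param G optional precomputed genomic relationship matrix.
#' @param skip_failures if `TRUE`, failed partitions are dropped with a
#'   warning instead of aborting the scheme.
#' @return object of class `cv_result`: data frame `predictions` with one
#'   row per (replicate, test record), plus scheme/model metadata.
#' @export
run_cv <- function(table, markers = NULL, model = "M3", scheme = "CV2",
                   k = 5, reps = 10, seed = 1,
                   priors = prior_spec(), mcmc = mcmc_control(),
                   G = NULL, skip_failures = FALSE) {
  if (is.null(G)) {
    if (is.null(markers)) stop("supply markers or G", call. = FALSE)
    G <- genomic_relationship(markers)
  }
  kernels <- model_kernels(model, table, G)
  parts <- cv_partitions(scheme, table, k = k, reps = reps, seed = seed)
  rows <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (isTRUE(p$empty_train)) next
    mc <- mcmc
    mc$seed <- as.integer((seed * 131L + i) %% .Machine$integer.max)
    # mask every record outside the training set: the test records plus,
    # for CV00, the test lines' records in other environments
    fit <- tryCatch(
      reaction_norm(table, model = model, priors = priors, mcmc = mc,
                    mask = setdiff(seq_len(nrow(table)), p$train),
                    kernels = kernels),
      error = function(e) {
        msg <- paste0("fit failed for ", scheme, " replicate ",
                      p$replicate, ", fold ", p$fold, ": ",
                      conditionMessage(e))
        if (skip_failures) {
          warning(msg, call. = FALSE)
          NULL
        } else stop(msg, call. = FALSE)
      })
    if (is.null(fit)) next
    rows[[length(rows) + 1L]] <- data.frame(
      scheme = scheme, model = model, replicate = p$replicate,
      fold = as.character(p$fold), record = p$test,
      line = table$line[p$test], env = table$env[p$test],
      observed = table$yield[p$test],
      predicted = fit$yhat[p$test],
      stringsAsFactors = FALSE)
  }
  structure(list(scheme = scheme, model = model, seed = seed,
                 predictions = do.call(rbind, rows)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validation result: model ", x$model, ", scheme ", x$scheme,
      "\n  ", nrow(x$predictions), " predictions over ",
      length(unique(x$predictions$replicate)), " replicate(s)\n", sep = "")
  invisible(x)
}
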