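#' Read a pipeline run configuration from YAML
#'
#' A run configuration names either input CSV paths (`phenotypes`,
#' `markers`) or a `simulation` block passed to [sim_config()], the model
#' and scheme lists, the fold/replicate counts, the master seed, MCMC and
#' prior settings, and the output directory.
#'
#' @param path YAML file path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(models = "M3", schemes = "CV2", k = 5, reps = 10,
                   seed = 1, out_dir = ".", duplicates = "error",
                   mcmc = list(), priors = list())
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  cfg$models <- unlist(cfg$models)
  cfg$schemes <- unlist(cfg$schemes)
  bad <- setdiff(cfg$models, c("M1", "M2", "M3", "M4"))
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(cfg$schemes, c("CV2", "CV1", "CV0", "CV00"))
  if (length(bad)) stop("unknown scheme(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(cfg, class = "run_config")
}

run_config_mcmc <- function(cfg) {
  do.call(mcmc_control, utils::modifyList(
    list(n_iter = 12000, burn_in = 2000, thin = 5, seed = cfg$seed),
    cfg$mcmc))
}

run_config_priors <- function(cfg) {
  do.call(prior_spec, cfg$priors)
}

load_run_data <- function(cfg) {
  if (!is.null(cfg$simulation)) {
    sim <- simulate_trials(do.call(sim_config, cfg$simulation))
    list(table = sim$table, markers = sim$markers, truth = sim$truth)
  } else {
    if (is.null(cfg$phenotypes) || is.null(cfg$markers)) {
      stop("run config needs either input paths or a simulation block",
           call. = FALSE)
    }
    al <- align_trial(read_trial_table(cfg$phenotypes,
                                       duplicates = cfg$duplicates),
                      read_marker_matrix(cfg$markers))
    list(table = al$table, markers = al$markers, truth = NULL)
  }
}

report_header <- function(cfg) {
  c(paste0("# soilnorm ",
           as.character(utils::packageVersion("soilnorm"))),
    paste0("# config_hash ", config_hash(cfg)),
    paste0("# seed ", cfg$seed))
}

# order-insensitive content hash of the configuration list
config_hash <- function(cfg) {
  x <- unclass(cfg)
  x <- x[order(names(x))]
  txt <- paste(deparse(x), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 997)))
}

write_report_csv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a dataset and write it to disk
#'
#' @param config a `run_config` (or path to one) with a `simulation`
#'   block.
#' @return invisibly, the file paths written.
#' @export
run_simulate <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (is.null(cfg$simulation)) cfg$simulation <- list()
  cfg$simulation$seed <- cfg$seed
  sim <- simulate_trials(do.call(sim_config, cfg$simulation))
  paths <- write_simulation(sim, cfg$out_dir)
  invisible(paths)
}

#' Full-data variance-component report for a set of models
#'
#' Fits each requested model on the complete data (no masking) and writes
#' a variance-share report with one row per model: the percentage of
#' phenotypic variability explained by each term across environments, and
#' the within-environment percentages (environment term removed).
#'
#' @param config a `run_config` or path to one.
#' @return list with `fits` (per model), `across` and `within` share
#'   tables (data frames in report layout, one decimal), and
#'   `across_raw`/`within_raw` (unrounded share matrices).
#' @export
run_full_fit <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  dat <- load_run_data(cfg)
  mcmc <- run_config_mcmc(cfg)
  priors <- run_config_priors(cfg)
  G <- genomic_relationship(dat$markers)
  all_terms <- c("E", "L", "S", "G", "GxE", "GxS", "R")
  fits <- list()
  across <- within_ <- across_raw <- within_raw <- list()
  for (m in cfg$models) {
    mc <- mcmc
    mc$seed <- as.integer((cfg$seed * 131L + match(m, cfg$models)) %%
                            .Machine$integer.max)
    fit <- tryCatch(
      reaction_norm(dat$table, model = m, priors = priors, mcmc = mc,
                    G = G),
      error = function(e) {
        warning("full-data fit failed for ", m, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    fits[[m]] <- fit
    if (is.null(fit)) next
    vc <- variance_components(fit)
    row_of <- function(shares, digits = NULL) {
      out <- stats::setNames(rep(NA_real_, length(all_terms)), all_terms)
      out[shares$term] <- if (is.null(digits)) shares$pct else {
        round(shares$pct, digits)
      }
      out
    }
    across[[m]] <- row_of(variance_percentages(vc, "across"), 1)
    within_[[m]] <- row_of(variance_percentages(vc, "within"), 1)
    across_raw[[m]] <- row_of(variance_percentages(vc, "across"))
    within_raw[[m]] <- row_of(variance_percentages(vc, "within"))
  }
  across <- data.frame(model = names(across),
                       do.call(rbind, across), check.names = FALSE)
  within_ <- data.frame(model = names(within_),
                        do.call(rbind, within_[names(fits)[
                          !vapply(fits, is.null, logical(1))]]),
                        check.names = FALSE)
  if (!is.null(cfg$out_dir) && dir.exists(cfg$out_dir)) {
    hdr <- report_header(cfg)
    write_report_csv(across, file.path(cfg$out_dir, "shares_across.csv"),
                     hdr)
    write_report_csv(within_, file.path(cfg$out_dir, "shares_within.csv"),
                     hdr)
  }
  list(fits = fits, across = across, within = within_,
       across_raw = do.call(rbind, across_raw),
       within_raw = do.call(rbind, within_raw))
}

#' Cross-validation predictive-ability report
#'
#' Runs every requested (model, scheme) combination, writes per-
#' environment correlation tables and collects the weighted mean
#' correlations into a models x schemes matrix (the headline
#' predictive-ability summary), plus a percentile classification grid per
#' combination.
#'
#' @param config a `run_config` or path to one.
#' @return list with `r_w` (models x schemes matrix), `per_env` (named
#'   list of per-environment correlation tables), `grids` (named list of
#'   `percentile_grid` objects) and `cv` (named list of `cv_result`s).
#' @export
run_cv_suite <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  dat <- load_run_data(cfg)
  mcmc <- run_config_mcmc(cfg)
  priors <- run_config_priors(cfg)
  G <- genomic_relationship(dat$markers)
  rw <- matrix(NA_real_, length(cfg$models), length(cfg$schemes),
               dimnames = list(cfg$models, cfg$schemes))
  per_env <- list()
  grids <- list()
  cvs <- list()
  for (m in cfg$models) {
    for (s in cfg$schemes) {
      key <- paste(m, s, sep = "_")
      cv <- run_cv(dat$table, model = m, scheme = s, k = cfg$k,
                   reps = cfg$reps,
                   seed = cfg$seed + 7L * match(s, cfg$schemes),
                   priors = priors, mcmc = mcmc, G = G,
                   skip_failures = isTRUE(cfg$skip_failures))
      cvs[[key]] <- cv
      ec <- env_correlations(cv)
      per_env[[key]] <- ec$correlations
      if (!is.null(ec$correlations) && nrow(ec$correlations) > 0) {
        rw[m, s] <- weighted_mean_correlation(ec)
      }
      ov <- genotype_overall(cv)
      if (nrow(ov) >= 5) {
        grids[[key]] <- percentile_grid(ov$predicted, ov$observed)
      }
    }
  }
  if (!is.null(cfg$out_dir) && dir.exists(cfg$out_dir)) {
    hdr <- report_header(cfg)
    rw_df <- data.frame(model = rownames(rw), rw, check.names = FALSE)
    write_report_csv(rw_df, file.path(cfg$out_dir, "weighted_cor.csv"),
                     hdr)
    for (key in names(per_env)) {
      if (!is.null(per_env[[key]])) {
        write_report_csv(per_env[[key]],
                         file.path(cfg$out_dir,
                                   paste0("per_env_", key, ".csv")), hdr)
      }
    }
    summary_json <- list(
      package = as.character(utils::packageVersion("soilnorm")),
      config_hash = config_hash(cfg), seed = cfg$seed,
      r_w = apply(rw, 1L, as.list, simplify = FALSE))
    jsonlite::write_json(summary_json,
                         file.path(cfg$out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(r_w = rw, per_env = per_env, grids = grids, cv = cvs)
}
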