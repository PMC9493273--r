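#' Configuration for the multi-environment trial simulator
#'
#' Describes a soybean-like advanced-yield-trial structure: lines split
#' into yearly cohorts, each year hosting a set of environments (distinct
#' trials) labeled with soil texture classes, and phenotypes generated
#' from the full reaction-norm model
#' \deqn{y_{ij} = \mu + E_j + S_k + L_i + g_i + gE_{ij} + gS_{ik} +
#'   \varepsilon_{ij}.}
#' The defaults emulate the trial system the package targets: five years,
#' each with two silt-loam, two clay and one fine-sand environment on two
#' farms, roughly 800 lines in yearly cohorts, a ~6k SNP panel, grand
#' mean 50 and total variance 100 split as in the fitted M3 decomposition
#' of that system.
#'
#' @param n_lines number of breeding lines.
#' @param p number of biallelic SNP markers.
#' @param freq_range allele-frequency range for the simulated panel.
#' @param n_years number of trial years; lines are split evenly into one
#'   cohort per year.
#' @param env_per_year named integer vector: environments per year for
#'   each soil class.
#' @param obs_rate probability that a cohort line is observed in each of
#'   its year's environments (< 1 gives the unbalanced incidence typical
#'   of real trials).
#' @param carryover fraction of each cohort also observed the following
#'   year (0 = strict single-year cohorts).
#' @param mu grand mean yield.
#' @param variances named vector of generative variance components
#'   `E, L, S, G, GxE, GxS, R` (all >= 0).
#' @param scale_exact if `TRUE` (default) every sampled effect vector is
#'   centered and rescaled so its empirical variance equals its configured
#'   component exactly (variance targeting); `FALSE` keeps the raw normal
#'   draws.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 797,
                       p = 6000,
                       freq_range = c(0.05, 0.95),
                       n_years = 5,
                       env_per_year = c(silt_loam = 2, clay = 2,
                                        fine_sand = 1),
                       obs_rate = 0.9,
                       carryover = 0,
                       mu = 50,
                       variances = c(E = 45.7, L = 2.2, S = 12.5,
                                     G = 3.5, GxE = 10.9, GxS = 9.5,
                                     R = 15.7),
                       scale_exact = TRUE,
                       seed = 1) {
  # YAML configs hand these in as named lists
  env_per_year <- unlist(env_per_year)
  variances <- unlist(variances)
  freq_range <- unlist(freq_range)
  if (p < 1) stop("need at least one marker", call. = FALSE)
  if (length(freq_range) != 2L || any(freq_range < 0) ||
      any(freq_range > 1) || freq_range[1L] > freq_range[2L]) {
    stop("freq_range must be an increasing pair within [0, 1]",
         call. = FALSE)
  }
  need <- c("E", "L", "S", "G", "GxE", "GxS", "R")
  if (!all(need %in% names(variances))) {
    stop("variances must name each of: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(variances < 0)) stop("variances must be nonnegative",
                               call. = FALSE)
  if (is.null(names(env_per_year)) || any(env_per_year < 0) ||
      sum(env_per_year) < 1) {
    stop("env_per_year must be a named nonnegative count per soil class",
         call. = FALSE)
  }
  if (n_years * sum(env_per_year) < 2) {
    stop("layout must yield at least 2 environments", call. = FALSE)
  }
  if (n_lines < 2 * n_years) {
    stop("need at least 2 lines per yearly cohort", call. = FALSE)
  }
  if (obs_rate <= 0 || obs_rate > 1) stop("obs_rate must be in (0, 1]",
                                          call. = FALSE)
  structure(list(n_lines = n_lines, p = p, freq_range = freq_range,
                 n_years = n_years, env_per_year = env_per_year,
                 obs_rate = obs_rate, carryover = carryover, mu = mu,
                 variances = variances[need], scale_exact = scale_exact,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# center a draw and rescale its empirical variance to the target (variance
# targeting); a single-level vector cannot be targeted and is returned as
# drawn.
target_variance <- function(x, sigma2, enabled) {
  if (!enabled || length(x) < 2L || sigma2 == 0) {
    return(if (sigma2 == 0) x * 0 else x)
  }
  x <- x - mean(x)
  s <- stats::sd(x) * sqrt((length(x) - 1) / length(x))
  if (s == 0) return(x)
  x * sqrt(sigma2) / s
}

#' Simulate a biallelic SNP panel
#'
#' Codes for marker m are binomial(2, q_m) dosage draws with q_m uniform
#' in the configured frequency range.
#'
#' @param config a [sim_config()].
#' @return a `marker_matrix` (lines x p).
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  q <- stats::runif(config$p, config$freq_range[1L], config$freq_range[2L])
  codes <- vapply(q, function(qm) {
    stats::rbinom(config$n_lines, 2L, qm)
  }, numeric(config$n_lines))
  codes <- matrix(codes, nrow = config$n_lines)
  rownames(codes) <- sprintf("g%04d", seq_len(config$n_lines))
  colnames(codes) <- sprintf("m%05d", seq_len(config$p))
  marker_matrix(codes)
}

#' Simulate an unbalanced multi-environment trial with known truth
#'
#' Generates markers, a trial layout (environments nested in year by farm
#' with soil labels, yearly line cohorts, incomplete incidence) and
#' phenotypes from the full reaction-norm generative model.  Genomic
#' values are a linear combination of the centered marker codes
#' (g = X_c b with i.i.d. marker effects); the marker-by-environment and
#' marker-by-soil interaction effects are drawn per environment/soil class
#' from N(0, G) via the eigendecomposition of G, which induces exactly the
#' Hadamard covariance structures of the model.
#'
#' @param config a [sim_config()].
#' @return list with `table` (a `trial_table`), `markers` (a
#'   `marker_matrix`) and `truth` (the configuration, every sampled effect
#'   vector, the marker effects and the per-record residuals; recombining
#'   them reproduces the phenotypes exactly).
#' @export
simulate_trials <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  markers <- simulate_markers(config)
  set.seed(config$seed + 1L)

  # layout: environments nested in year x farm, labeled by soil class;
  # fine-sand trials sit on the second farm as in the emulated system
  soils <- names(config$env_per_year)
  env_table <- do.call(rbind, lapply(seq_len(config$n_years), function(y) {
    do.call(rbind, lapply(soils, function(s) {
      cnt <- config$env_per_year[[s]]
      if (cnt == 0) return(NULL)
      data.frame(
        env = sprintf("y%d_%s_%d", y, s, seq_len(cnt)),
        year = 2016L + y,
        location = if (s == "fine_sand") "farm_B" else "farm_A",
        soil = s, stringsAsFactors = FALSE)
    }))
  }))
  n_env <- nrow(env_table)

  # yearly cohorts with optional carryover and incomplete incidence
  lines <- rownames(markers)
  cohort <- sort(rep_len(seq_len(config$n_years), config$n_lines))
  recs <- list()
  for (y in seq_len(config$n_years)) {
    members <- lines[cohort == y]
    if (config$carryover > 0 && y > 1) {
      prev <- lines[cohort == y - 1L]
      n_extra <- floor(config$carryover * length(prev))
      if (n_extra > 0) members <- c(members, sample(prev, n_extra))
    }
    envs_y <- env_table$env[env_table$year == 2016L + y]
    for (e in envs_y) {
      seen <- members[stats::runif(length(members)) <= config$obs_rate]
      if (length(seen) < 2L) seen <- members[seq_len(min(2L,
                                                         length(members)))]
      recs[[length(recs) + 1L]] <- data.frame(line = seen, env = e,
                                              stringsAsFactors = FALSE)
    }
  }
  recs <- unique(do.call(rbind, recs))
  tab <- merge(recs, env_table, by = "env", sort = FALSE)
  tab <- tab[order(match(tab$env, env_table$env), tab$line), ]

  v <- config$variances
  sx <- config$scale_exact

  # environment effects; under variance targeting they are additionally
  # centered within soil classes so no environment-level variance aliases
  # into the soil main effect
  E <- stats::rnorm(n_env, 0, sqrt(v[["E"]]))
  if (sx && length(unique(env_table$soil)) > 1L) {
    E <- E - stats::ave(E, env_table$soil)
  }
  E <- target_variance(E, v[["E"]], sx)
  names(E) <- env_table$env
  S <- target_variance(stats::rnorm(length(soils), 0, sqrt(v[["S"]])),
                       v[["S"]], sx)
  names(S) <- soils
  L <- target_variance(stats::rnorm(config$n_lines, 0, sqrt(v[["L"]])),
                       v[["L"]], sx)
  names(L) <- lines

  # genomic values: linear combination of centered/scaled marker codes
  Xc <- scale(unclass(markers))
  Xc[is.na(Xc)] <- 0  # monomorphic columns scale to NaN; they carry no signal
  b <- stats::rnorm(config$p)
  g <- target_variance(drop(Xc %*% b) / sqrt(config$p), v[["G"]], sx)
  names(g) <- lines

  # interaction deviations: per environment (and per soil class) draws
  # from N(0, G sigma^2), correlated across lines through G
  G <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- eg$values > 1e-8 * max(eg$values)
  Half <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eg$values[keep]), sum(keep))
  draw_g <- function(sigma2, n_col) {
    m <- Half %*% matrix(stats::rnorm(ncol(Half) * n_col), ncol = n_col)
    m * sqrt(sigma2)
  }
  gE <- draw_g(v[["GxE"]], n_env)
  dimnames(gE) <- list(lines, env_table$env)
  gS <- draw_g(v[["GxS"]], length(soils))
  dimnames(gS) <- list(lines, soils)
  if (sx) {
    # remove the lower-order components the interaction draws would
    # otherwise randomly carry: per-line means within each soil class of
    # gE (aliased with L/g and gS) and per-line means of gS across soil
    # classes (aliased with L/g)
    for (s in unique(env_table$soil)) {
      cols <- which(env_table$soil == s)
      gE[, cols] <- gE[, cols, drop = FALSE] -
        rowMeans(gE[, cols, drop = FALSE])
    }
    gS <- gS - rowMeans(gS)
  }

  i <- match(tab$line, lines)
  j <- match(tab$env, env_table$env)
  k <- match(tab$soil, soils)
  gE_rec <- gE[cbind(i, j)]
  gS_rec <- gS[cbind(i, k)]
  if (sx) {
    # variance-target the interaction deviations at the record level,
    # where their share of the phenotypic variance is defined
    scale_rec <- function(M, rec, sigma2) {
      if (sigma2 == 0) return(list(M = M * 0, rec = rec * 0))
      m0 <- mean(rec)
      s <- sqrt(mean((rec - m0)^2))
      if (s == 0) return(list(M = M, rec = rec))
      f <- sqrt(sigma2) / s
      list(M = (M - m0) * f, rec = (rec - m0) * f)
    }
    tmp <- scale_rec(gE, gE_rec, v[["GxE"]]); gE <- tmp$M; gE_rec <- tmp$rec
    tmp <- scale_rec(gS, gS_rec, v[["GxS"]]); gS <- tmp$M; gS_rec <- tmp$rec
  }

  eps <- target_variance(stats::rnorm(nrow(tab), 0, sqrt(v[["R"]])),
                         v[["R"]], sx)

  tab$yield <- config$mu + E[j] + S[k] + L[i] + g[i] + gE_rec + gS_rec + eps
  table <- trial_table(tab[, c("line", "env", "year", "location", "soil",
                               "yield")])

  truth <- list(config = config,
                effects = list(E = E, S = S, L = L, g = g, gE = gE,
                               gS = gS),
                marker_effects = b,
                residuals = eps,
                env_table = env_table)
  list(table = table, markers = markers, truth = truth)
}

#' Write a simulated dataset (phenotypes, markers, truth, config) to disk
#'
#' @param sim output of [simulate_trials()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    phenotypes = file.path(dir, "phenotypes.csv"),
    markers = file.path(dir, "markers.csv"),
    truth = file.path(dir, "truth_effects.csv"),
    config = file.path(dir, "sim_config.yaml"))
  write_trial_table(sim$table, paths[["phenotypes"]])
  write_marker_matrix(sim$markers, paths[["markers"]])
  eff <- sim$truth$effects
  long <- rbind(
    data.frame(effect = "E", level = names(eff$E), value = unname(eff$E)),
    data.frame(effect = "S", level = names(eff$S), value = unname(eff$S)),
    data.frame(effect = "L", level = names(eff$L), value = unname(eff$L)),
    data.frame(effect = "g", level = names(eff$g), value = unname(eff$g)),
    data.frame(effect = "gE",
               level = paste(rownames(eff$gE)[row(eff$gE)],
                             colnames(eff$gE)[col(eff$gE)], sep = ":"),
               value = as.vector(eff$gE)),
    data.frame(effect = "gS",
               level = paste(rownames(eff$gS)[row(eff$gS)],
                             colnames(eff$gS)[col(eff$gS)], sep = ":"),
               value = as.vector(eff$gS)))
  utils::write.csv(long, paths[["truth"]], row.names = FALSE, quote = FALSE)
  cfg <- sim$truth$config
  yaml::write_yaml(lapply(unclass(cfg), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  }), paths[["config"]])
  invisible(paths)
}
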