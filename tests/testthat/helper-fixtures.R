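# Small in-code fixtures shared across test files.

# toy trial table from a compact record spec: list of c(line, env) pairs;
# environment metadata derived from the env label ("e1" -> year 2017, soil
# cycles through the three texture classes)
toy_table <- function(pairs, yields = NULL, soils = NULL) {
  df <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(line = p[[1]], env = p[[2]], stringsAsFactors = FALSE)
  }))
  envs <- unique(df$env)
  soil_cycle <- c("silt_loam", "clay", "fine_sand")
  if (is.null(soils)) {
    soils <- stats::setNames(
      rep_len(soil_cycle, length(envs)), envs)
  }
  df$year <- 2017L + (match(df$env, envs) - 1L) %% 2L
  df$location <- "farm_A"
  df$soil <- soils[df$env]
  df$yield <- if (is.null(yields)) seq_len(nrow(df)) + 40 else yields
  trial_table(df)
}

# deterministic toy marker matrix covering the given lines
toy_markers <- function(lines, p = 20, seed = 11) {
  set.seed(seed)
  m <- matrix(sample(0:2, length(lines) * p, replace = TRUE),
              nrow = length(lines),
              dimnames = list(lines, paste0("m", seq_len(p))))
  marker_matrix(m)
}

# small simulated dataset for integration-style tests
small_sim <- function(seed = 1, n_lines = 60, p = 300, n_years = 2,
                      env_per_year = c(silt_loam = 1, clay = 1,
                                       fine_sand = 1),
                      variances = NULL) {
  args <- list(n_lines = n_lines, p = p, n_years = n_years,
               env_per_year = env_per_year, seed = seed)
  if (!is.null(variances)) args$variances <- variances
  simulate_trials(do.call(sim_config, args))
}

# genetics-rich variance split used where predictive signal must be
# clearly detectable at toy scale
strong_g_variances <- c(E = 40, L = 5, S = 10, G = 15, GxE = 10,
                        GxS = 8, R = 12)

# short MCMC settings for toy fits
quick_mcmc <- function(seed = 1, n_iter = 1500, burn_in = 400, thin = 2) {
  mcmc_control(n_iter, burn_in, thin, seed = seed)
}
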