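test_that("marker simulation matches binomial moments and is seeded", {
  cfg <- sim_config(n_lines = 400, p = 60, freq_range = c(0.5, 0.5),
                    n_years = 2, seed = 21)
  mm <- simulate_markers(cfg)
  expect_equal(dim(mm), c(400L, 60L))
  # mean dosage 2q = 1, SE = sqrt(2*0.5*0.5 / n) per marker, pooled
  expect_lt(abs(mean(mm) - 1), 3 * sqrt(0.5 / (400 * 60)))
  expect_identical(unclass(simulate_markers(cfg)), unclass(mm))

  # boundary: q = 1 gives a monomorphic all-2 marker
  cfg1 <- sim_config(n_lines = 10, p = 1, freq_range = c(1, 1),
                     n_years = 2, seed = 1)
  expect_true(all(simulate_markers(cfg1) == 2))
  expect_error(sim_config(freq_range = c(0.9, 0.1)), "freq_range")
})

test_that("stored effects and residuals recombine into the phenotypes", {
  sim <- small_sim(seed = 31, n_lines = 40, p = 100)
  tab <- sim$table
  tr <- sim$truth
  y <- tr$config$mu +
    tr$effects$E[tab$env] +
    tr$effects$S[tab$soil] +
    tr$effects$L[tab$line] +
    tr$effects$g[tab$line] +
    tr$effects$gE[cbind(tab$line, tab$env)] +
    tr$effects$gS[cbind(tab$line, tab$soil)] +
    tr$residuals
  expect_equal(unname(y), tab$yield, tolerance = 1e-10)
})

test_that("trial structure honours the configured layout", {
  cfg <- sim_config(n_lines = 50, p = 40, n_years = 3,
                    env_per_year = c(silt_loam = 2, clay = 2,
                                     fine_sand = 1),
                    obs_rate = 0.8, seed = 7)
  sim <- simulate_trials(cfg)
  tab <- sim$table
  expect_equal(length(unique(tab$env)), 15L)
  expect_equal(sort(unique(tab$soil)),
               c("clay", "fine_sand", "silt_loam"))
  # environments nested in year x location; fine sand on the second farm
  env_info <- unique(tab[, c("env", "year", "location", "soil")])
  expect_equal(anyDuplicated(env_info$env), 0L)
  expect_true(all(env_info$location[env_info$soil == "fine_sand"] ==
                    "farm_B"))
  # unbalanced incidence: not every line in every environment of its year
  expect_lt(nrow(tab), 50 * 5)
  # every environment carries at least 2 lines
  expect_true(all(table(tab$env) >= 2))
  # at most one record per line x environment
  expect_equal(anyDuplicated(tab[, c("line", "env")]), 0L)
})

test_that("variance targeting makes stored effect variances exact", {
  sim <- small_sim(seed = 12, n_lines = 50, p = 80, n_years = 4,
                   env_per_year = c(silt_loam = 2, clay = 2, fine_sand = 1))
  v <- sim$truth$config$variances
  pvar <- function(x) mean((x - mean(x))^2)
  expect_equal(pvar(sim$truth$effects$E), v[["E"]], tolerance = 1e-10)
  expect_equal(pvar(sim$truth$effects$S), v[["S"]], tolerance = 1e-10)
  expect_equal(pvar(sim$truth$effects$L), v[["L"]], tolerance = 1e-10)
  expect_equal(pvar(sim$truth$effects$g), v[["G"]], tolerance = 1e-10)
  expect_equal(pvar(sim$truth$residuals), v[["R"]], tolerance = 1e-10)
  # interaction effects are targeted at the record level
  tab <- sim$table
  expect_equal(pvar(sim$truth$effects$gE[cbind(tab$line, tab$env)]),
               v[["GxE"]], tolerance = 1e-10)
  expect_equal(pvar(sim$truth$effects$gS[cbind(tab$line, tab$soil)]),
               v[["GxS"]], tolerance = 1e-10)
})

test_that("raw draws recover configured moments at large n", {
  # thousands of records, 1000 lines, 100 environments; tolerances are
  # ~3 sampling SDs of the respective empirical variances
  cfg <- sim_config(n_lines = 1000, p = 50, n_years = 20,
                    env_per_year = c(silt_loam = 2, clay = 2,
                                     fine_sand = 1),
                    scale_exact = FALSE, seed = 5)
  sim <- simulate_trials(cfg)
  v <- cfg$variances
  expect_gt(nrow(sim$table), 4000)
  # residuals: n ~ 10^4 draws, SD of the sample variance ~ 1.4%
  expect_equal(stats::var(sim$truth$residuals), v[["R"]],
               tolerance = 0.1)
  # line effects: 1000 draws, SD ~ 4.5%
  expect_equal(stats::var(sim$truth$effects$L), v[["L"]],
               tolerance = 0.15)
  # environment effects: 100 draws, SD ~ 14%
  expect_equal(stats::var(sim$truth$effects$E), v[["E"]],
               tolerance = 0.4)
})

test_that("degenerate generative settings behave as limits", {
  # all variances zero: every yield equals the grand mean
  v0 <- c(E = 0, L = 0, S = 0, G = 0, GxE = 0, GxS = 0, R = 0)
  sim <- small_sim(seed = 3, n_lines = 12, p = 20, variances = v0)
  expect_true(all(sim$table$yield == 50))

  # only line + genomic signal: within any environment, yield differences
  # equal the L + g differences exactly
  v <- c(E = 0, L = 3, S = 0, G = 5, GxE = 0, GxS = 0, R = 0)
  sim <- small_sim(seed = 4, n_lines = 12, p = 20, variances = v)
  tab <- sim$table
  e1 <- tab[tab$env == tab$env[1], ]
  sig <- sim$truth$effects$L[e1$line] + sim$truth$effects$g[e1$line]
  expect_equal(diff(e1$yield), unname(diff(sig)), tolerance = 1e-10)
})

test_that("simulation writer emits re-loadable files", {
  sim <- small_sim(seed = 6, n_lines = 15, p = 25)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(unlist(paths))))
  tab <- read_trial_table(paths[["phenotypes"]])
  expect_equal(nrow(tab), nrow(sim$table))
  expect_equal(tab$yield, sim$table$yield, tolerance = 1e-12)
  mm <- read_marker_matrix(paths[["markers"]])
  expect_equal(unclass(mm), unclass(sim$markers))
  cfg <- yaml::read_yaml(paths[["config"]])
  expect_equal(cfg$n_lines, 15)
})
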