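test_that("mme_oracle reduces to known closed forms", {
  # pure noise: all structural variances ~ 0 -> every prediction is the
  # training mean
  ks <- structure(list(model = "toy", n = 3,
                       kernels = list(U = diag(3))),
                  class = "kernel_set")
  y <- c(10, 20, 30)
  pred <- mme_oracle(y, train = c(1, 2), ks, c(U = 1e-12, R = 1))
  expect_equal(pred[3], 15, tolerance = 1e-6)

  # identity kernel: ridge shrinkage of each training residual by
  # s2u / (s2u + s2e), checked by scalar algebra at n = 3
  s2u <- 2; s2e <- 1
  pred <- mme_oracle(y, train = 1:3, ks, c(U = s2u, R = s2e))
  ybar <- mean(y)
  expect_equal(pred, ybar + s2u / (s2u + s2e) * (y - ybar))

  # a masked duplicate record shrinks to its twin's value as s2e -> 0
  K <- rbind(c(1, 0, 0), c(0, 1, 1), c(0, 1, 1))
  ks2 <- structure(list(model = "toy", n = 3, kernels = list(U = K)),
                   class = "kernel_set")
  pred <- mme_oracle(c(10, 20, NA), train = 1:2, ks2,
                     c(U = 1, R = 1e-8))
  expect_equal(pred[3], 20, tolerance = 1e-3)

  expect_error(mme_oracle(y, 1:2, ks, c(U = 1)), "R")
})

test_that("constant phenotypes give constant predictions and ~zero variances", {
  tab <- toy_table(list(c("g1", "e1"), c("g2", "e1"), c("g3", "e1"),
                        c("g1", "e2"), c("g2", "e2"), c("g3", "e2")),
                   yields = rep(50, 6))
  mm <- toy_markers(c("g1", "g2", "g3"), p = 25, seed = 3)
  fit <- reaction_norm(tab, mm, model = "M1", mask = 6,
                       mcmc = quick_mcmc(seed = 2))
  expect_lt(abs(fit$yhat[6] - 50), 0.5)
  expect_true(all(variance_components(fit)$estimate < 1e-4))
})

test_that("identical seed reproduces the fit bit-for-bit", {
  sim <- small_sim(seed = 8, n_lines = 20, p = 60)
  f1 <- reaction_norm(sim$table, sim$markers, model = "M2",
                      mcmc = quick_mcmc(seed = 99, n_iter = 600,
                                        burn_in = 200))
  f2 <- reaction_norm(sim$table, sim$markers, model = "M2",
                      mcmc = quick_mcmc(seed = 99, n_iter = 600,
                                        burn_in = 200))
  expect_identical(f1$yhat, f2$yhat)
  expect_identical(f1$varcomp, f2$varcomp)
  f3 <- reaction_norm(sim$table, sim$markers, model = "M2",
                      mcmc = quick_mcmc(seed = 100, n_iter = 600,
                                        burn_in = 200))
  expect_false(identical(f1$yhat, f3$yhat))
})

test_that("fitted + residuals reproduce observed yields; methods work", {
  sim <- small_sim(seed = 9, n_lines = 20, p = 60)
  fit <- reaction_norm(sim$table, sim$markers, model = "M3",
                       mask = 1:4, mcmc = quick_mcmc(seed = 5))
  expect_equal(fitted(fit) + residuals(fit), sim$table$yield,
               tolerance = 1e-8)
  vc <- variance_components(fit)
  expect_equal(vc$term, c("E", "L", "S", "G", "GxE", "GxS", "R"))
  expect_true(all(vc$estimate >= 0))
  expect_equal(variance_components(
    reaction_norm(sim$table, sim$markers, model = "M1",
                  mcmc = quick_mcmc(seed = 5, n_iter = 400,
                                    burn_in = 100)))$term,
    c("E", "L", "G", "R"))

  pr <- predict(fit)
  expect_equal(pr$record, 1:4)
  expect_equal(pr$predicted, fit$yhat[1:4])
  expect_equal(nrow(predict(fit, "all")), nrow(sim$table))
  expect_named(coef(fit), c("E", "L", "S", "G", "GxE", "GxS", "R"))
  expect_output(print(fit), "model M3")
  expect_output(print(summary(fit)), "pct_across")

  # simulate() draws phenotype vectors on the fitted scale
  ks <- model_kernels("M3", sim$table, genomic_relationship(sim$markers))
  ysim <- simulate(fit, nsim = 2, seed = 1, kernels = ks)
  expect_equal(dim(ysim), c(nrow(sim$table), 2L))
  expect_true(all(is.finite(ysim)))
})

test_that("configuration errors are caught", {
  expect_error(mcmc_control(100, 100), "burn_in")
  expect_error(mcmc_control(100, 10, thin = 0), "thin")
  expect_error(prior_spec(df = 0), "positive")
  expect_error(prior_spec(R2 = 1.2), "R2")
  tab <- toy_table(list(c("g1", "e1"), c("g2", "e1")))
  mm <- toy_markers(c("g1", "g2"))
  expect_error(reaction_norm(tab, mm, model = "M1", mask = 1:2),
               "observed")
})

test_that("fixed-variance Gibbs matches the closed-form oracle", {
  # oracle equivalence on several toy configurations: posterior-mean
  # predictions for masked records agree with the deterministic
  # mixed-model solution within Monte-Carlo error
  configs <- list(
    list(seed = 1, model = "M1", v = c(E = 30, L = 3, G = 6, R = 15)),
    list(seed = 3, model = "M3",
         v = c(E = 30, L = 3, S = 8, G = 6, GxE = 8, GxS = 6, R = 15)))
  for (cf in configs) {
    sim <- small_sim(seed = cf$seed, n_lines = 15, p = 80)
    ks <- model_kernels(cf$model, sim$table,
                        genomic_relationship(sim$markers))
    n <- nrow(sim$table)
    mask <- seq(2, n, by = 5)
    oracle <- mme_oracle(sim$table$yield, setdiff(seq_len(n), mask), ks,
                         cf$v)
    fit <- reaction_norm(sim$table, model = cf$model, kernels = ks,
                         mask = mask, fixed_variances = cf$v,
                         mcmc = mcmc_control(6000, 1000, 2,
                                             seed = cf$seed + 50))
    mcse <- vapply(seq_along(mask), function(i) {
      s <- fit$samples$pred[, i]
      stats::sd(s) / sqrt(soilnorm:::ess(s))
    }, numeric(1))
    expect_true(all(abs(fit$yhat[mask] - oracle[mask]) <=
                      pmax(3 * mcse, 1e-6)))
  }
})
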