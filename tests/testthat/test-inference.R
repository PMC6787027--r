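test_that("the Gaussian likelihood matches its closed form", {
  M <- matrix(1L, 1, 1, dimnames = list("v", "x"))
  # zero residual
  fs0 <- fs_from_dg(-2.9)
  expect_equal(log_likelihood(fs0, 0.1, -2.9, M),
               -0.5 * log(2 * pi * 0.01))
  # one-sigma residual costs exactly one half
  expect_equal(log_likelihood(fs0 + 0.1, 0.1, -2.9, M),
               -0.5 * log(2 * pi * 0.01) - 0.5)
  # wild-type-like single A3 change at its fitted free energy
  expect_equal(log_likelihood(0.755, 0.02, -2.9, M),
               -0.5 * log(2 * pi * 0.02^2), tolerance = 1e-4)
  # kinetic factor damps the model efficiency before the residual
  expect_equal(log_likelihood(fs0 * 0.9, 0.02, -2.9, M, kappa = 0.1),
               -0.5 * log(2 * pi * 0.02^2))
  expect_error(log_likelihood(0.5, 0, 0, M), "positive")
  expect_error(log_likelihood(c(0.5, 0.5), c(0.1, 0.1), 0, M), "disagree")
})

test_that("the uniform prior box is closed and rejects outside points", {
  expect_equal(log_prior(rep(0, 5)), 0)
  expect_equal(log_prior(c(0, 26)), -Inf)
  expect_equal(log_prior(c(-25, 25)), 0)       # boundary included
  expect_equal(log_prior(25.0000001), -Inf)
  expect_equal(log_prior(3, prior = c(-1, 1)), -Inf)
})

test_that("compiled sampler and pure-R reference walk identical paths", {
  v <- variant_table(c("GAAAAAG", "AAAGAAG"), "UUS", "UUS",
                     fs = c(0.28, 0.44), sigma = 0.02)
  reg <- invitro_registry()
  M <- build_design_matrix(v, reg)
  M <- M[, colSums(abs(M)) > 0, drop = FALSE]
  co <- thermo_constants()
  lp <- function(x) log_likelihood(v$fs, v$sigma, x, M, constants = co) +
    log_prior(x)
  for (pin_j in list(rep(FALSE, ncol(M)), c(TRUE, rep(FALSE, ncol(M) - 1)))) {
    withr_seed(42)
    ref <- fsthermo:::metropolis_reference(lp, rep(0, ncol(M)), 400,
                                           pinned = pin_j)
    withr_seed(42)
    cpp <- fsthermo:::metropolis_cpp(M, v$fs, v$sigma, 400L, 0.2, -25, 25,
                                     pin_j, co$kT, FALSE, 0, 0)
    expect_identical(unname(cpp$dg_samples), ref)
  }
})

test_that("the acceptance rule depends only on posterior ratios", {
  # multiplying the target by a constant must leave the chain unchanged
  lp1 <- function(x) -0.5 * sum((x - 1)^2) / 0.3^2
  lp2 <- function(x) lp1(x) + 7.3
  withr_seed(11)
  a <- fsthermo:::metropolis_reference(lp1, c(0, 0), 300)
  withr_seed(11)
  b <- fsthermo:::metropolis_reference(lp2, c(0, 0), 300)
  expect_identical(a, b)
})

test_that("with a flat likelihood the posterior reduces to the prior", {
  v <- variant_table("GAAAAAG", "UUS", "UUS", fs = 0.5, sigma = 1e6)
  reg <- normalize_label(c("P1 A.U->G.U", "A3 G.S->A.S"))
  fit <- fs_fit(v, reg, n_steps = 1e5, n_chains = 2, proposal_sigma = 10,
                seed = 1)
  s <- pooled_samples(fit)
  expect_gte(nrow(s), 1e5)
  for (j in seq_len(ncol(s))) {
    ks <- suppressWarnings(stats::ks.test(s[, j], stats::punif, -25, 25))
    expect_lt(unname(ks$statistic), 0.02)
  }
})

test_that("a symmetric measurement centres the posterior at zero", {
  # single change variable, FS measured at exactly one half
  v <- variant_table("GAAAAAA", "UUS", "UUS", fs = 0.5, sigma = 0.02)
  fit <- fs_fit(v, "P1 A.U->G.U", n_steps = 2e4, n_chains = 2, seed = 3)
  expect_lt(abs(fit$posterior$mean), 0.1)
})

test_that("Metropolis marginals match a dense-grid posterior oracle", {
  reg <- normalize_label(c("P1 A.U->G.U", "A3 G.S->A.S"))
  # identifiable two-variable problem: FS(x) and FS(x + y) measured
  v <- variant_table(c("GAAAAAA", "GAAAAAG"), "UUS", "UUS",
                     fs = c(0.25, 0.30), sigma = 0.02)
  fit <- fs_fit(v, reg, n_steps = 1e5, n_chains = 2, seed = 5)
  s <- pooled_samples(fit)
  oracle <- grid_posterior_2vars(0.25, 0.30, 0.02)
  breaks <- seq(-25, 25, by = 0.25)
  expect_lt(tv_distance(s[, 1], breaks,
                        coarse_density(oracle$grid, oracle$marg_x, breaks)),
            0.05)
  expect_lt(tv_distance(s[, 2], breaks,
                        coarse_density(oracle$grid, oracle$marg_y, breaks)),
            0.05)
})

test_that("sum-coupled variables pin their sum to the grid posterior", {
  # one variant, two variables entering only through their sum: the sum
  # is sharply determined (and grid-checkable), each marginal is not
  v <- variant_table("GAAAAAG", "UUS", "UUS", fs = 0.3, sigma = 0.02)
  reg <- normalize_label(c("P1 A.U->G.U", "A3 G.S->A.S"))
  fit <- fs_fit(v, reg, n_steps = 2e5, n_chains = 2, seed = 5)
  s <- pooled_samples(fit)

  total <- s[, 1] + s[, 2]
  oracle <- grid_posterior_sum(0.3, 0.02)
  breaks <- seq(floor(min(total)) - 1, ceiling(max(total)) + 1, by = 0.1)
  expect_lt(tv_distance(total, breaks,
                        coarse_density(oracle$grid, oracle$dens, breaks)),
            0.05)
  expect_equal(mean(total), dg_from_fs(0.3), tolerance = 0.1)
  expect_lt(stats::sd(total), 0.5)
  # the orthogonal direction stays prior-wide
  expect_gt(stats::sd(s[, 1] - s[, 2]), 5)
})

test_that("fits are bit-reproducible under a fixed seed", {
  fx <- dnax_fixtures()
  f1 <- fs_fit(fx$invitro_subset, n_steps = 500, n_chains = 2, seed = 9)
  f2 <- fs_fit(fx$invitro_subset, n_steps = 500, n_chains = 2, seed = 9)
  expect_identical(f1$chains, f2$chains)
  f3 <- fs_fit(fx$invitro_subset, n_steps = 500, n_chains = 2, seed = 10)
  expect_false(identical(f1$chains, f3$chains))
  # chains use distinct streams
  expect_false(identical(f1$chains[[1]], f1$chains[[2]]))
})

test_that("retained samples always respect the prior box", {
  fx <- dnax_fixtures()
  fit <- fs_fit(fx$invitro_subset, n_steps = 2000, n_chains = 2, seed = 4)
  s <- pooled_samples(fit)
  expect_true(all(s >= -25 & s <= 25))
})

test_that("pinned variables stay at zero and pinning is validated", {
  fx <- dnax_fixtures()
  fit <- fs_fit(fx$invitro_subset, n_steps = 1000, pin = "P3 G.S->A.S",
                seed = 2)
  expect_true(all(pooled_samples(fit)[, normalize_label("P3 G.S->A.S")] == 0))
  expect_error(fs_fit(fx$invitro_subset, pin = "P9 A.U->G.U"),
               "not in the registry")
  expect_error(fs_fit(fx$invitro_subset, pin = "P2 A.U->G.U"),
               "not in the registry")
  expect_error(fs_fit(fx$invitro_subset, registry = "A3 G.S->A.S",
                      pin = "A3 G.S->A.S"), "no free variables")
})

test_that("posterior summaries pool chains after burn-in", {
  fake <- structure(list(
    chains = list(matrix(c(0, 0, 2, 2), ncol = 1,
                         dimnames = list(NULL, "x")),
                  matrix(c(1, 1, 3, 3), ncol = 1,
                         dimnames = list(NULL, "x"))),
    kappa_chains = NULL,
    config = list(burn_in = 0.5, pin = character(0), pooled_chains = TRUE,
                  n_chains = 2, kinetic = FALSE)), class = "fs_fit")
  s <- pooled_samples(fake)
  expect_equal(sort(as.numeric(s)), c(2, 2, 3, 3))
  post <- posterior_summary(fake)
  expect_equal(post$mean, 2.5)
  expect_equal(post$sd, stats::sd(c(2, 2, 3, 3)))
  expect_true(attr(post, "pooled"))
  # histogram densities integrate to one
  h <- attr(post, "histograms")[["x"]]
  expect_equal(sum(h$density * diff(h$breaks)), 1)
  # constant chain: sd 0
  fake$chains <- list(matrix(rep(1.5, 10), ncol = 1,
                             dimnames = list(NULL, "x")))
  fake$config$n_chains <- 1
  post <- posterior_summary(fake)
  expect_equal(post$mean, 1.5)
  expect_equal(post$sd, 0)
})

test_that("variants without measurements are dropped with a warning", {
  v <- variant_table(c("GAAAAAG", "AAAGAAG"), "UUS", "UUS",
                     fs = c(0.28, NA), sigma = c(0.02, NA))
  expect_warning(fit <- fs_fit(v, n_steps = 200, seed = 1), "dropped")
  expect_equal(nrow(fit$design), 1L)
  expect_error(suppressWarnings(
    fs_fit(variant_table("GAAAAAG", "UUS", "UUS"), n_steps = 10)),
    "no variant")
  v2 <- variant_table("GAAAAAG", "UUS", "UUS", fs = 0.28, sigma = 0)
  expect_warning(fit2 <- fs_fit(v2, n_steps = 200, seed = 1), "floored")
})
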