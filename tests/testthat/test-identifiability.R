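# one well-mixed fit of the full synthetic design, shared across tests;
# identifiability calls need chains long enough for the flat directions to
# spread to prior scale
invitro_fit_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      design <- enumerate_invitro_design()
      truth <- invitro_truth(21)
      dat <- simulate_fs_dataset(design, truth, sigma = 0.02, seed = 8)
      cache <<- list(dat = dat, truth = truth,
                     fit = fs_fit(dat, n_steps = 1.5e5, n_chains = 2,
                                  seed = 4))
    }
    cache
  }
})

test_that("the Lys/Phe design leaves exactly six variables undetermined", {
  cc <- invitro_fit_cache()
  u <- flag_underdetermined(cc$fit)
  expect_length(u, 6L)
  expect_setequal(u, normalize_label(c(
    "P3 G.S->A.S", "A1 A.U->G.U", "A1 U.A->G.A",
    "P3 C.G->U.G", "A1 A.U->C.U", "A1 U.A->C.A")))
  # a zero-sd summary flags nothing
  fake <- data.frame(label = c("a", "b"), mean = 0, sd = 0, pinned = FALSE)
  expect_length(flag_underdetermined(fake), 0L)
})

test_that("posterior correlations expose the coupled triples", {
  cc <- invitro_fit_cache()
  r <- sample_correlations(cc$fit)
  expect_true(isSymmetric(r, tol = 1e-12))
  expect_equal(unname(diag(r)), rep(1, ncol(r)))
  # sum-coupling: representative anti-correlates with its partners,
  # partners correlate positively with each other
  expect_lt(r[normalize_label("P3 G.S->A.S"), normalize_label("A1 A.U->G.U")],
            -0.9)
  expect_lt(r[normalize_label("P3 C.G->U.G"), normalize_label("A1 U.A->C.A")],
            -0.9)
  expect_gt(r[normalize_label("A1 A.U->G.U"), normalize_label("A1 U.A->G.A")],
            0.9)
  # determined variables never reach the strong-coupling regime
  det <- setdiff(colnames(r), flag_underdetermined(cc$fit))
  off <- r[det, det]; diag(off) <- 0
  expect_lt(max(abs(off)), 0.9)
  # pinned (constant) series are defined as zero with a warning
  fitp <- fs_fit(cc$dat, n_steps = 1000, pin = "P3 G.S->A.S", seed = 2)
  expect_warning(rp <- sample_correlations(fitp), "zero-variance")
  expect_true(all(rp[normalize_label("P3 G.S->A.S"), -match(
    normalize_label("P3 G.S->A.S"), colnames(rp))] == 0))
})

test_that("pinning turns coupled variables into determined combinations", {
  cc <- invitro_fit_cache()
  res <- pin_and_refit(cc$dat, pin = p3_labels(), reference_fit = cc$fit,
                       n_steps = 5e4, n_chains = 2, seed = 4)
  post <- res$fit$posterior
  free <- !post$pinned & post$label != "kappa_bar"
  expect_length(fsthermo:::determined_labels(post), 14L)
  # every free variable recovers the corresponding combination free energy
  want <- pinned_truth(cc$truth)
  z <- abs(post$mean[free] - want[post$label[free]]) / post$sd[free]
  expect_true(all(z < 3.5))
  # reported combinations carry the pinned partner and small sd
  expect_equal(nrow(res$combinations), 4L)
  expect_true(all(res$combinations$sd < 2))
  expect_true(all(grepl("P3", res$combinations$pinned)))
  # pinning an already determined variable warns
  expect_warning(pin_and_refit(cc$dat, pin = "P1 A.U->G.U",
                               reference_fit = cc$fit, n_steps = 500,
                               seed = 4),
                 "already determined")
})

test_that("iterative pinning reproduces the two-wobble-pin structure", {
  cc <- invitro_fit_cache()
  ip <- iterative_pinning(cc$dat, n_steps = 1.5e5, n_chains = 2, seed = 4)
  expect_true(ip$converged)
  expect_length(ip$steps[[1]]$determined, 10L)
  expect_equal(ip$pins, p3_labels())   # the P3 representatives, in order
  expect_length(ip$final$determined, 14L)
  # each single pin determines its two coupled partners
  expect_length(ip$steps[[2]]$newly_determined, 2L)
  expect_length(ip$steps[[3]]$newly_determined, 2L)
  # the data rmsd is unchanged by pinning (flat directions carry no signal)
  rmsds <- c(vapply(ip$steps, function(s) s$rmsd, 0), ip$final$rmsd)
  expect_lt(diff(range(rmsds)), 0.5)
  expect_lt(abs(ip$final$rmsd - ip$steps[[1]]$rmsd), 0.2)
})

test_that("a fully identifiable design needs no pinning", {
  v <- variant_table(c("GAAAAAA", "AAAAAAG", "GAAAAAG"), "UUS", "UUS")
  reg <- normalize_label(c("P1 A.U->G.U", "A3 G.S->A.S"))
  truth <- stats::setNames(c(3.5, -2.2), reg)
  dat <- simulate_fs_dataset(v, truth, sigma = 0.02, seed = 2)
  ip <- iterative_pinning(dat, reg, n_steps = 2e4, n_chains = 2, seed = 7)
  expect_length(ip$pins, 0L)
  expect_length(ip$steps, 1L)
  expect_setequal(ip$final$determined, reg)
  expect_length(flag_underdetermined(ip$final$fit), 0L)

  # two variants measuring disjoint single changes: the variables are
  # independent and their posterior correlation is negligible
  v2 <- variant_table(c("GAAAAAA", "AAAAAAG"), "UUS", "UUS",
                      fs = c(0.3, 0.8), sigma = 0.02)
  fit2 <- fs_fit(v2, reg, n_steps = 2e4, n_chains = 2, seed = 9)
  r2 <- sample_correlations(fit2)
  expect_lt(abs(r2[1, 2]), 0.3)
})

test_that("site comparisons subtract posterior series per sample", {
  # degenerate single-sample posterior: exact arithmetic
  s <- matrix(c(5.1, 2.0, 4.0, 1.0), nrow = 1,
              dimnames = list(NULL, normalize_label(
                c("P1 A.U->C.U", "P1 U.A->C.A",
                  "A1 A.U->C.U", "A1 U.A->C.A"))))
  cmp <- data.frame(name = c("P site C.A->C.U", "A site C.A->C.U"),
                    minuend = c("P1 A.U->C.U", "A1 A.U->C.U"),
                    subtrahend = c("P1 U.A->C.A", "A1 U.A->C.A"))
  out <- site_comparison(s, cmp)
  expect_equal(out$mean, c(3.1, 3.0))
  expect_equal(out$sd, c(0, 0))
  # identical minuend and subtrahend: zero difference
  cmp0 <- data.frame(name = "null", minuend = "P1 A.U->C.U",
                     subtrahend = "P1 A.U->C.U")
  expect_equal(site_comparison(s, cmp0)$mean, 0)
  expect_error(site_comparison(s, data.frame(name = "x",
                                             minuend = "P1 A.U->U.U",
                                             subtrahend = "P1 U.A->C.A")),
               "lacks label")
})

test_that("derived P-vs-A differences recover the synthetic truth", {
  cc <- invitro_fit_cache()
  res <- pin_and_refit(cc$dat, pin = p3_labels(), reference_fit = cc$fit,
                       n_steps = 5e4, n_chains = 2, seed = 4)
  out <- site_comparison(res$fit)
  expect_equal(nrow(out), 4L)
  tr <- cc$truth
  lab <- normalize_label
  want <- c(
    tr[lab("P1 A.U->C.U")] - tr[lab("P1 U.A->C.A")],
    tr[lab("A1 A.U->C.U")] - tr[lab("A1 U.A->C.A")],  # shared pin cancels
    tr[lab("P1 A.U->G.U")] - tr[lab("P1 U.A->G.A")],
    tr[lab("A1 A.U->G.U")] - tr[lab("A1 U.A->G.A")])
  z <- abs(out$mean - unname(want)) / out$sd
  expect_true(all(z < 3.5))
})
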