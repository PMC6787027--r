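# shared fixtures, all built in code

# ground-truth free energies for the 64-variant Lys/Phe design, drawn once
# per seed inside the identifiable range of the study conditions
invitro_truth <- function(seed = 21, low = -6, high = 6) {
  reg <- invitro_registry()
  withr_seed(seed)
  stats::setNames(stats::runif(length(reg), low, high), reg)
}

# what a fit with both P3 wobble variables pinned to 0 should recover:
# the A1 variables absorb the free energy of their co-occurring P3 change
pinned_truth <- function(truth) {
  lab <- function(x) normalize_label(x)
  out <- truth
  out[lab("A1 A.U->G.U")] <- truth[lab("A1 A.U->G.U")] + truth[lab("P3 G.S->A.S")]
  out[lab("A1 U.A->G.A")] <- truth[lab("A1 U.A->G.A")] + truth[lab("P3 G.S->A.S")]
  out[lab("A1 A.U->C.U")] <- truth[lab("A1 A.U->C.U")] + truth[lab("P3 C.G->U.G")]
  out[lab("A1 U.A->C.A")] <- truth[lab("A1 U.A->C.A")] + truth[lab("P3 C.G->U.G")]
  out[lab(c("P3 G.S->A.S", "P3 C.G->U.G"))] <- 0
  out
}

normalize_label <- fsthermo:::normalize_label

p3_labels <- function() normalize_label(c("P3 G.S->A.S", "P3 C.G->U.G"))

# seed the global RNG without leaking state into later tests
withr_seed <- function(seed) {
  set.seed(seed)
  invisible(seed)
}

# total-variation distance between a sample and a discrete density on the
# same bin grid
tv_distance <- function(samples, breaks, density) {
  p_hat <- graphics::hist(samples, breaks = breaks, plot = FALSE)$density
  w <- diff(breaks)
  0.5 * sum(abs(p_hat - density) * w)
}

# dense-grid posterior for a single variant whose two change variables
# enter only through their sum: f(x, y) on the prior box
grid_posterior_2d <- function(fs_exp, sigma, prior = c(-25, 25),
                              n_grid = 501, constants = thermo_constants()) {
  g <- seq(prior[1], prior[2], length.out = n_grid)
  fs_model <- outer(g, g, function(x, y) fs_from_dg(x + y, constants))
  logf <- -(fs_exp - fs_model)^2 / (2 * sigma^2)
  f <- exp(logf - max(logf))
  f <- f / sum(f)
  dx <- g[2] - g[1]
  list(grid = g,
       marg_x = rowSums(f) / dx,   # density over x
       marg_y = colSums(f) / dx)
}

# dense-grid posterior for two variants measuring FS(x) and FS(x + y):
# both variables are determined, so short chains mix fully
grid_posterior_2vars <- function(fs1, fs2, sigma, prior = c(-25, 25),
                                 n_grid = 1001,
                                 constants = thermo_constants()) {
  g <- seq(prior[1], prior[2], length.out = n_grid)
  lx <- -(fs1 - fs_from_dg(g, constants))^2 / (2 * sigma^2)
  lsum <- function(x, y) -(fs2 - fs_from_dg(x + y, constants))^2 /
    (2 * sigma^2)
  logf <- outer(g, g, lsum) + lx
  f <- exp(logf - max(logf))
  f <- f / sum(f)
  dx <- g[2] - g[1]
  list(grid = g, marg_x = rowSums(f) / dx, marg_y = colSums(f) / dx)
}

# 1-D grid posterior of the determined sum u = x + y for one variant
# measuring FS(u); the flat prior on the box induces a triangular prior
# on the sum, which the oracle must carry
grid_posterior_sum <- function(fs_exp, sigma, prior = c(-25, 25),
                               n_grid = 40001,
                               constants = thermo_constants()) {
  width <- prior[2] - prior[1]
  u <- seq(2 * prior[1], 2 * prior[2], length.out = n_grid)
  prior_u <- pmax(2 * width - abs(u - prior[1] - prior[2]), 0)
  logl <- -(fs_exp - fs_from_dg(u, constants))^2 / (2 * sigma^2)
  f <- prior_u * exp(logl - max(logl))
  du <- u[2] - u[1]
  list(grid = u, dens = f / (sum(f) * du))
}

# integrate a fine-grid density onto histogram bins, returning bin-level
# densities comparable with hist(..., plot = FALSE)$density
coarse_density <- function(grid, dens, breaks) {
  idx <- cut(grid, breaks, include.lowest = TRUE)
  dx <- grid[2] - grid[1]
  p <- tapply(dens * dx, idx, sum)
  p[is.na(p)] <- 0
  as.numeric(p) / diff(breaks)
}
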