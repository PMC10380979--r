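# Independent brute-force oracles and small utilities for the test-suite.
# The oracles evaluate the cost formulas directly from their definitions
# (pre-simplification forms) and never call the package's coefficient or
# geometry code, so they are an independent check of the partitions.

# Normalized misclassification-only cost, from rc0*rho*(1-se) + rc1*(1-rho)*(1-sp)
# with rc0 = 1 - rc1.
ref_misc_rc <- function(se, sp, rho, rc1) {
  rho * (1 - se) * (1 - rc1) + (1 - rho) * (1 - sp) * rc1
}

# Normalized misclassification+rejection cost, from the three-term form with
# rc2 = 1 - rc0 - rc1.
ref_miscrej_rc <- function(se, sp, alpha, rho, rc0, rc1) {
  alpha * rho * (1 - se) * rc0 + alpha * (1 - rho) * (1 - sp) * rc1 +
    (1 - alpha) * (1 - rc0 - rc1)
}

# Winner (earliest-index minimum) fractions over a deterministic rc1 grid.
ref_misc_grid_fractions <- function(profiles, rho, n_grid = 1e5) {
  rc1 <- (seq_len(n_grid) - 0.5) / n_grid
  cost <- sapply(seq_len(nrow(profiles)), function(i) {
    ref_misc_rc(profiles$se[i], profiles$sp[i], rho, rc1)
  })
  win <- max.col(-cost, ties.method = "first")
  counts <- tabulate(win, nbins = nrow(profiles))
  stats::setNames(counts / n_grid, profiles$name)
}

# Monte-Carlo winner fractions on the triangle, independent of the package
# (its own folding sampler and the unsimplified cost form).
ref_miscrej_mc_fractions <- function(profiles, rho, n = 1e5, seed = 1) {
  set.seed(seed)
  u <- runif(n); v <- runif(n)
  fold <- u + v > 1
  u[fold] <- 1 - u[fold]; v[fold] <- 1 - v[fold]
  cost <- sapply(seq_len(nrow(profiles)), function(i) {
    ref_miscrej_rc(profiles$se[i], profiles$sp[i], profiles$alpha[i], rho, u, v)
  })
  win <- max.col(-cost, ties.method = "first")
  stats::setNames(tabulate(win, nbins = nrow(profiles)) / n, profiles$name)
}

# Fractions vector aligned to the full profile set (zero for absent owners).
full_fractions <- function(partition, profiles) {
  out <- stats::setNames(rep(0, nrow(profiles)), profiles$name)
  f <- scenario_fractions(partition)
  out[names(f)] <- f
  out
}

# Is pt inside (or on the boundary of) the convex CCW polygon?
point_in_convex <- function(pt, poly, tol = 1e-12) {
  n <- nrow(poly)
  nxt <- c(2:n, 1L)
  e <- poly[nxt, , drop = FALSE] - poly
  w1 <- pt[1] - poly[, 1]; w2 <- pt[2] - poly[, 2]
  all(e[, 1] * w2 - e[, 2] * w1 >= -tol)
}

# Index of the face of a region_partition containing pt (first match).
face_containing <- function(partition, pt, tol = 1e-12) {
  for (i in seq_along(partition$faces)) {
    if (point_in_convex(pt, partition$faces[[i]], tol)) return(i)
  }
  NA_integer_
}

# Random interior point of a convex polygon (Dirichlet mixture of vertices).
random_interior_point <- function(poly) {
  w <- -log(runif(nrow(poly)))
  w <- w / sum(w)
  c(sum(w * poly[, 1]), sum(w * poly[, 2]))
}
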