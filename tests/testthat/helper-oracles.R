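# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately avoid the package's estimation code paths: they
# evaluate likelihoods directly from model formulas on dense grids, or solve
# least squares through an explicit pseudo-inverse.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
          "F","P","S","T","W","Y","V")

# K80 pairwise likelihood of observed (transition, transversion) counts at
# divergence t, maximized analytically-free over kappa by inner bounded
# search; the oracle maximizes over t on a dense grid.
oracle_k80_grid <- function(n_sites, n_transition, n_transversion,
                            t_range = c(1e-4, 3), coarse = 1e-3, fine = 1e-4) {
  loglik_t <- function(t) {
    f <- function(kappa) {
      pr <- k80_probs(k80_model(kappa), t)
      ps <- pr$p_transition; pv <- pr$p_transversion
      p0 <- 1 - ps - pv
      if (ps <= 0 || pv <= 0 || p0 <= 0) return(-Inf)
      (n_sites - n_transition - n_transversion) * log(p0) +
        n_transition * log(ps) + n_transversion * log(pv)
    }
    stats::optimize(f, c(0.05, 60), maximum = TRUE, tol = 1e-8)$objective
  }
  grid <- seq(t_range[1], t_range[2], by = coarse)
  ll <- vapply(grid, loglik_t, 0)
  t0 <- grid[which.max(ll)]
  grid2 <- seq(max(t_range[1], t0 - 2 * coarse), t0 + 2 * coarse, by = fine)
  ll2 <- vapply(grid2, loglik_t, 0)
  grid2[which.max(ll2)]
}

# dense grid for the WAG pairwise likelihood around a bracketing interval
oracle_wag_grid <- function(a, b, model, t_range, step = 1e-4) {
  ia <- match(strsplit(a, "")[[1]], AA20)
  ib <- match(strsplit(b, "")[[1]], AA20)
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]; ib <- ib[keep]
  ll <- function(t) {
    P <- transition_probs(model, t)
    sum(log(model$freqs[ia] * P[cbind(ia, ib)]))
  }
  grid <- seq(t_range[1], t_range[2], by = step)
  grid[which.max(vapply(grid, ll, 0))]
}

# least squares via explicit pseudo-inverse (no lm/qr in common with the fit)
oracle_ols_pinv <- function(D, y) {
  s <- svd(D)
  as.numeric(s$v %*% ((t(s$u) %*% y) / s$d))
}

# small deterministic fixture family reused where a fresh simulation is
# unnecessary
fixture_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_family(seed = 42)
    cache
  }
})

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
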