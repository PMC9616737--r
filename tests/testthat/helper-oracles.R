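# Independent oracles used across the suite. They deliberately avoid the
# package's own integration and ranking code paths.

# Fixed-step forward Euler endpoint for the two-compartment system.
euler_endpoint <- function(params, h = 1e-4) {
  p <- params$p0
  d <- params$d0
  s <- if (is.null(params$decay_scale)) params$c else params$decay_scale
  horizon <- params$t_end - params$t_onset
  n <- round(horizon / h)
  for (i in seq_len(n)) {
    t <- (i - 1) * h
    u <- params$c * (1 + d / p)^params$k * exp(-t^2 / s)
    flux <- u * p
    p <- p + h * (2 * params$f_p - 1) * flux
    d <- d + h * (1 - params$f_p) * flux
  }
  c(p_end = p, d_end = d)
}

# Ten-point parameter panel for solver-vs-Euler endpoint comparisons:
# moderate growth regimes spanning the amplitude, feedback and
# self-renewal ranges the calibration searches.
oracle_panel <- list(
  c(0.5, 0, 0.6), c(0.5, 1, 0.75), c(1, 0.5, 0.9), c(1, 2, 0.7),
  c(1.5, 2, 0.8), c(1.5, 1, 0.55), c(2, 0, 0.85), c(2, 1.5, 0.65),
  c(2.5, 0.5, 0.75), c(2.5, 2, 0.9))

panel_params <- function(v) sg_params(c = v[1], k = v[2], f_p = v[3])

# True ellipsoid surface area by 2D quadrature of the parametric surface
# element |r_theta x r_phi|.
ellipsoid_surface_quadrature <- function(a, b, c) {
  f <- function(theta, phi) {
    st <- sin(theta)
    st * sqrt((b * c * st * cos(phi))^2 + (a * c * st * sin(phi))^2 +
                (a * b * cos(theta))^2)
  }
  pracma::integral2(f, 0, pi, 0, 2 * pi, reltol = 1e-10)$Q
}

# Brute-force filter-then-sort reference for the marker screen.
brute_force_rank <- function(rows, annotations, go_terms) {
  keep <- vapply(seq_len(nrow(rows)), function(i) {
    ids <- annotations[[rows$gene[i]]]
    !is.null(ids) && length(intersect(ids, go_terms)) > 0
  }, TRUE)
  kept <- rows[keep, , drop = FALSE]
  res <- NULL
  for (comp in sort(unique(kept$compartment))) {
    sub <- kept[kept$compartment == comp, , drop = FALSE]
    sub <- sub[order(-sub$fold_change, sub$gene), , drop = FALSE]
    sub$rank <- seq_len(nrow(sub))
    res <- rbind(res, sub)
  }
  rownames(res) <- NULL
  res
}

# silence the Fortran step-size chatter lsoda emits near the basal-layer
# exhaustion singularity (f_p < 0.5 runs); results are unaffected
quiet <- function(expr) {
  out <- withCallingHandlers(
    suppressMessages(expr),
    warning = function(w) invokeRestart("muffleWarning"))
  out
}
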