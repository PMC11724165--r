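# Shared test helpers: hand-built geometries and an independent
# numeric-quadrature oracle for the time-averaged area integrals.

make_geometry <- function(L0, W0, constants = model_constants()) {
  structure(
    list(initial_total_length_m = L0, initial_width_m = W0,
         rupture_length_km = NA_real_,
         recovery_time_a = recovery_time(constants)),
    class = "fissure_geometry"
  )
}

trapz <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# Time averages of the instantaneous areas by brute-force trapezoid
# quadrature; independent of the closed-form implementation.
quadrature_avg_areas <- function(geometry, elapsed_T,
                                 constants = model_constants(),
                                 n_steps = 1e5) {
  t <- seq(0, elapsed_T, length.out = n_steps + 1)
  L <- length_at_age(geometry, t, constants)
  W <- width_at_age(geometry, t, constants)
  c(sidewall = trapz(t, 2 * constants$depth_D * L) / elapsed_T,
    bottom = trapz(t, L * W) / elapsed_T)
}

# Maximum-likelihood b-value for a doubly truncated Gutenberg-Richter
# sample: solves the truncated-exponential mean equation for beta.
ml_b_value <- function(m, m_min, m_max) {
  mbar <- mean(m) - m_min
  dm <- m_max - m_min
  f <- function(beta) 1 / beta - dm / (exp(beta * dm) - 1) - mbar
  stats::uniroot(f, c(1e-6, 50))$root / log(10)
}
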