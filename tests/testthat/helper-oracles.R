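# Independent oracles used to cross-check the implementation. Everything in
# this file deliberately takes the dumbest correct route (bisection, explicit
# enumeration, frequency-domain matrix inversion) rather than sharing code
# with the package.

# 1:1 complex concentration by root bracketing of the mass balance
oracle_1to1 <- function(P0, L0, kd) {
  if (L0 == 0 || P0 == 0) return(0)
  f <- function(pl) pl * kd - (P0 - pl) * (L0 - pl)
  stats::uniroot(f, c(0, min(P0, L0)), tol = min(P0, L0) * 1e-14)$root
}

# free ligand for the two-equivalent-site model by root bracketing
oracle_two_site_free <- function(N0, L0, kd) {
  if (L0 == 0) return(0)
  g <- function(x) x + 2 * N0 * x / (kd + x) - L0
  stats::uniroot(g, c(0, L0), tol = L0 * 1e-14)$root
}

# trimmed mean + n*sigma threshold via explicit sort/drop/mean/sd
oracle_threshold <- function(x, trim, n_sigma, sigma_on = "trimmed") {
  s <- sort(x)
  k <- floor(length(s) * trim)
  kept <- if (k > 0) s[(k + 1):(length(s) - k)] else s
  sg <- if (sigma_on == "trimmed") stats::sd(kept) else stats::sd(x)
  if (is.na(sg)) sg <- 0
  mean(kept) + n_sigma * sg
}

# exhaustive enumeration of 2 independent sites each occupied w.p. theta
oracle_species_fractions <- function(theta) {
  p <- c(0, 0, 0)
  for (s1 in 0:1) for (s2 in 0:1) {
    prob <- (if (s1) theta else 1 - theta) * (if (s2) theta else 1 - theta)
    n <- s1 + s2
    p[n + 1] <- p[n + 1] + prob
  }
  p
}

# frequency-domain (resolvent) two-state McConnell spectrum: per frequency
# point, invert i*omega*I - L directly. Independent of the package's
# time-domain propagation + FFT route. Apodization enters as extra R2.
oracle_mcconnell <- function(ppm_axis, offsets_ppm, r2, k_fb, k_bf, pops,
                             carrier_ppm, freq_mhz, lb_hz = 0) {
  om <- 2 * pi * (offsets_ppm - carrier_ppm) * freq_mhz
  r2eff <- r2 + pi * lb_hz
  L <- matrix(c(1i * om[1] - r2eff[1] - k_fb, k_fb,
                k_bf, 1i * om[2] - r2eff[2] - k_bf), 2)
  vapply(ppm_axis, function(p) {
    w <- 2 * pi * (p - carrier_ppm) * freq_mhz
    v <- solve(1i * w * diag(2) - L, pops)
    2 * Re(sum(v))
  }, numeric(1))
}

# quick default acquisition with a finer grid for oracle comparisons
fine_acq <- function(lb_hz = 0) {
  acquisition_params(field_mhz = 900, nucleus = "13C", sw_ppm = 3,
                     n_points = 2048L, carrier_ppm = 21.475, lb_hz = lb_hz)
}
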