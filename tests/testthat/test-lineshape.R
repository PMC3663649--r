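acq0 <- acquisition_params(lb_hz = 0)

test_that("pseudo-first-order rates satisfy detailed balance and tie to the mass balance", {
  r0 <- pseudo_first_order_rates(1.5e-6, 500, 0)
  expect_equal(r0$k_free_to_bound, 0)
  expect_equal(r0$p_bound, 0)
  r1 <- pseudo_first_order_rates(2e-6, 300, 2e-6)  # free ligand == kd
  expect_equal(r1$k_free_to_bound, 300)
  expect_equal(r1$p_bound, 0.5)
  # cross-module: implied p_bound equals theta from the two-site solver
  ms <- solve_two_site(116e-6, 232e-6, 1.5e-6)
  r <- pseudo_first_order_rates(1.5e-6, 500, ms$free_ligand)
  expect_equal(r$p_bound, ms$occupancy, tolerance = 1e-12)
  expect_equal(r$p_bound, 0.92, tolerance = 0.01)
})

test_that("evolution matrix conserves population and has McConnell eigenvalues", {
  # kinetic part (real, exchange-only) has zero column sums for any rates
  set.seed(21)
  for (i in 1:20) {
    kfb <- stats::runif(1, 0, 5000)
    kbf <- stats::runif(1, 0, 5000)
    r2 <- stats::runif(2, 1, 100)
    L <- evolution_matrix(c(21.3, 21.65), r2, kfb, kbf, acq0)
    kin <- Re(L) + diag(r2)
    expect_equal(colSums(kin), c(0, 0), tolerance = 1e-12)
  }
  # no exchange: block-diagonal
  L0 <- evolution_matrix(c(21.3, 21.65), c(8, 40), 0, 0, acq0)
  expect_equal(L0[1, 2], 0 + 0i)
  expect_equal(L0[2, 1], 0 + 0i)
  # symmetric two-state exchange: eigenvalues match the closed form
  # lambda(+/-) = i*mean(omega) - R2 - k +/- sqrt(k^2 - (d_omega/2)^2)
  k <- 400
  r2c <- 10
  L <- evolution_matrix(c(21.3, 21.65), c(r2c, r2c), k, k, acq0)
  om <- 2 * pi * (c(21.3, 21.65) - acq0$carrier_ppm) * acq0$frequency_mhz
  dw <- om[1] - om[2]
  closed <- c(1i * mean(om) - r2c - k + sqrt(as.complex(k^2 - dw^2 / 4)),
              1i * mean(om) - r2c - k - sqrt(as.complex(k^2 - dw^2 / 4)))
  ev <- eigen(L, only.values = TRUE)$values
  expect_equal(sort(Im(ev)), sort(Im(closed)), tolerance = 1e-9)
  expect_equal(sort(Re(ev)), sort(Re(closed)), tolerance = 1e-9)
})

test_that("FID propagation: pure decay, contraction, fast-exchange limit, divergence", {
  # single populated state on resonance: purely real exponential decay
  L <- evolution_matrix(c(acq0$carrier_ppm, 22), c(12, 12), 0, 0, acq0)
  fid <- simulate_fid(L, c(1, 0), acq0$dwell_s, 512L)
  t <- (0:511) * acq0$dwell_s
  expect_equal(fid, as.complex(exp(-12 * t)), tolerance = 1e-10)
  # contraction: |FID(t)| <= FID(0) = 1
  L2 <- evolution_matrix(c(21.3, 21.65), c(8, 40), 700, 500, acq0)
  fid2 <- simulate_fid(L2, c(0.4, 0.6), acq0$dwell_s, 512L)
  expect_equal(Mod(fid2[1]), 1)
  expect_true(all(Mod(fid2) <= 1 + 1e-12))
  # fast limit k >> d_omega: population-weighted averaged oscillator
  p <- c(0.3, 0.7)
  om <- 2 * pi * (c(21.3, 21.65) - acq0$carrier_ppm) * acq0$frequency_mhz
  kex <- 2e6  # >> |d_omega| ~ 500 rad/s
  L3 <- evolution_matrix(c(21.3, 21.65), c(8, 40), p[2] * kex, p[1] * kex,
                         acq0)
  fid3 <- simulate_fid(L3, p, acq0$dwell_s, 512L)
  avg <- exp((1i * sum(p * om) - sum(p * c(8, 40))) * t)
  expect_lt(max(Mod(fid3 - avg)), 0.01)
  # positive real eigenvalue must be rejected
  Lbad <- matrix(c(5 + 0i, 0, 0, -10 + 0i), 2)
  expect_error(simulate_fid(Lbad, c(1, 0), acq0$dwell_s, 512L),
               "divergent")
})

test_that("spectrum: Lorentzian width, position, integral normalisation", {
  r2 <- 20
  L <- evolution_matrix(c(21.3, 22), c(r2, r2), 0, 0, acq0)
  tr <- spectrum_from_fid(simulate_fid(L, c(1, 0), acq0$dwell_s,
                                       acq0$n_points), acq0)
  pk <- peak_positions(list(tr))$ppm
  dres <- (tr$ppm[2] - tr$ppm[1])
  expect_lt(abs(pk - 21.3), dres)
  # FWHM = R2/pi Hz, half-crossings located by linear interpolation
  y <- tr$intensity
  half <- max(y) / 2
  imax <- which.max(y)
  cross <- function(i1, i2) {
    tr$ppm[i1] + (half - y[i1]) * (tr$ppm[i2] - tr$ppm[i1]) / (y[i2] - y[i1])
  }
  il <- max(which(y[1:imax] < half))
  ir <- imax - 1L + min(which(y[imax:length(y)] < half))
  fwhm_hz <- (cross(ir - 1L, ir) - cross(il, il + 1L)) *
    acq0$frequency_mhz
  expect_lt(abs(fwhm_hz - r2 / pi), dres * acq0$frequency_mhz)
  # integral equals FID(0) = 1 within discretisation
  expect_equal(trace_integral(tr), 1, tolerance = 5e-3)
})

test_that("slow-exchange spectrum shows two peaks with population-proportional integrals", {
  p <- c(0.35, 0.65)
  acq <- fine_acq()
  kex <- 5  # << d_omega
  L <- evolution_matrix(c(21.3, 21.65), c(15, 15), p[2] * kex, p[1] * kex,
                        acq)
  tr <- spectrum_from_fid(simulate_fid(L, p, acq$dwell_s, acq$n_points),
                          acq)
  # split at the midpoint and integrate each half numerically
  mid <- 21.475
  df_hz <- (tr$ppm[2] - tr$ppm[1]) * acq$frequency_mhz
  i_low <- sum(tr$intensity[tr$ppm < mid]) * df_hz
  i_high <- sum(tr$intensity[tr$ppm >= mid]) * df_hz
  expect_equal(i_low / (i_low + i_high), p[1], tolerance = 0.02)
  expect_equal(i_high / (i_low + i_high), p[2], tolerance = 0.02)
})

test_that("propagated spectra match the frequency-domain McConnell oracle in all regimes", {
  acq <- fine_acq()
  p <- c(0.45, 0.55)
  om <- 2 * pi * (c(21.3, 21.65) - acq$carrier_ppm) * acq$frequency_mhz
  dw <- abs(diff(om))  # ~ 500 rad/s
  for (kex in c(0.02 * dw, dw, 50 * dw)) {  # slow, intermediate, fast
    kfb <- p[2] * kex
    kbf <- p[1] * kex
    L <- evolution_matrix(c(21.3, 21.65), c(8, 40), kfb, kbf, acq)
    tr <- spectrum_from_fid(simulate_fid(L, p, acq$dwell_s, acq$n_points),
                            acq)
    orc <- oracle_mcconnell(tr$ppm, c(21.3, 21.65), c(8, 40), kfb, kbf, p,
                            acq$carrier_ppm, acq$frequency_mhz)
    rms <- sqrt(mean((tr$intensity - orc)^2)) / max(abs(orc))
    expect_lt(rms, 0.001)
    # integral conservation across exchange regimes
    expect_equal(trace_integral(tr), 1, tolerance = 5e-3)
  }
})

test_that("coalescence: two maxima in slow exchange, one in fast", {
  acq <- fine_acq()
  p <- c(0.5, 0.5)
  om <- 2 * pi * (c(21.3, 21.65) - acq$carrier_ppm) * acq$frequency_mhz
  dw <- abs(diff(om))
  n_maxima <- function(kex) {
    L <- evolution_matrix(c(21.3, 21.65), c(5, 5), kex / 2, kex / 2, acq)
    tr <- spectrum_from_fid(simulate_fid(L, p, acq$dwell_s, acq$n_points),
                            acq)
    y <- tr$intensity
    thr <- 0.2 * max(y)
    sum(y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
          y[2:(length(y) - 1)] > y[3:length(y)] &
          y[2:(length(y) - 1)] > thr)
  }
  expect_equal(n_maxima(0.02 * dw), 2L)
  expect_equal(n_maxima(20 * dw), 1L)
})

test_that("titration line shapes move from free to bound position with saturation", {
  ratios <- c(0, 0.5, 1, 1.8, 2.7, 100)
  trs <- titration_lineshapes(1.5e-6, 500, 116e-6, ratios,
                              acquisition = acq0)
  pos <- peak_positions(trs, ratios)$ppm
  dres <- trs[[1]]$ppm[2] - trs[[1]]$ppm[1]
  expect_lt(abs(pos[1] - 21.3), dres)          # free reference
  expect_lt(abs(pos[6] - 21.65), dres)         # saturated limit
  expect_true(all(diff(pos) > -dres))          # monotone shift
  # at 2.7 equivalents the position sits within 2% of d_omega of the
  # bound limit, consistent with theta from the mass balance
  theta <- solve_two_site(116e-6, 2.7 * 116e-6, 1.5e-6)$occupancy
  expect_gt(theta, 0.93)
  expect_lt(abs(pos[5] - 21.65), 0.02 * 0.35 + dres)
  # position curve tracks theta(ratio) where exchange is fast (kex >> dw);
  # at sub-stoichiometric ratios exchange is intermediate and the peak is
  # pulled towards the free position, so those points are excluded
  theta_all <- solve_two_site(116e-6, ratios * 116e-6, 1.5e-6)$occupancy
  fast <- c(1, 4, 5, 6)  # ratios 0, 1.8, 2.7, 100
  expect_lt(max(abs((pos[fast] - 21.3) / 0.35 - theta_all[fast])), 0.02)
  expect_error(titration_lineshapes(1.5e-6, 500, 116e-6, c(0.5, 1)),
               "include 0")
})

test_that("peak positions are parabolic-refined and reject flat traces", {
  tr <- titration_lineshapes(1e-6, 500, 100e-6, 0, acquisition = acq0)[[1]]
  dres <- tr$ppm[2] - tr$ppm[1]
  expect_lt(abs(peak_positions(list(tr))$ppm - 21.3), dres)
  flat <- tr
  flat$intensity <- rep(1, nrow(flat))
  expect_error(peak_positions(list(flat)), "flat trace")
})

test_that("the fitter's fast spectrum path equals the public simulation route", {
  spec <- exchange_defaults()
  eng <- bindfit:::trace_engine(spec$acquisition)
  for (kd in c(1.5e-6, 5e-8)) for (koff in c(100, 500, 3000)) {
    fast <- bindfit:::lineshape_intensities(
      kd, koff, spec$receptor_total, spec$ratios, spec$offsets_ppm,
      spec$r2, eng)
    pub <- titration_lineshapes(kd, koff, spec$receptor_total, spec$ratios,
                                spec$offsets_ppm, spec$r2,
                                spec$acquisition)
    for (j in seq_along(fast)) {
      expect_identical(fast[[j]], pub[[j]]$intensity)
    }
  }
})

test_that("exchange fit recovers noiseless truth and flags one-sided intervals", {
  spec <- exchange_defaults()
  spec$noise_frac <- 0
  sim <- simulate_exchange_titration(spec, seed = 1)
  fit <- fit_exchange(sim$traces, sim$ratios, sim$receptor_total,
                      interval = FALSE)
  expect_equal(fit$kd, spec$kd, tolerance = 1e-4)
  expect_equal(fit$koff, spec$koff, tolerance = 1e-4)
  expect_equal(fit$delta_omega_ppm, 0.35, tolerance = 1e-4)

  # near-stoichiometric binding at realistic noise: kd only bounded from
  # above, as in a saturating titration
  spec2 <- exchange_defaults()
  spec2$kd <- 5e-8
  spec2$noise_frac <- 0.08
  sim2 <- simulate_exchange_titration(spec2, seed = 2)
  fit2 <- suppressWarnings(
    fit_exchange(sim2$traces, sim2$ratios, sim2$receptor_total,
                 interval = TRUE))
  expect_true("kd_lower_open" %in% fit2$flags)
  expect_false("kd_upper_open" %in% fit2$flags)
  expect_true(is.finite(fit2$interval95_kd[2]))
})

test_that("exchange fit input validation", {
  spec <- exchange_defaults()
  sim <- simulate_exchange_titration(spec, seed = 1)
  expect_error(fit_exchange(sim$traces[1:3], sim$ratios[1:3],
                            spec$receptor_total), "at least 4")
  expect_error(fit_exchange(sim$traces[2:5], sim$ratios[2:5],
                            spec$receptor_total), "include 0")
})
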