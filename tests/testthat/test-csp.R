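test_that("combined CSP is the weighted quadrature sum, sign-invariant", {
  expect_equal(combined_csp(0, 0), 0)
  expect_equal(combined_csp(0.1, 0, 0.7), 0.1)
  expect_equal(combined_csp(0.03, 0.2, 0.2), 0.05)
  expect_equal(combined_csp(-0.03, 0.2, 0.2), combined_csp(0.03, -0.2, 0.2))
  expect_equal(csp_weight("15N"), 0.2)
  expect_equal(csp_weight("13C"), 0.3)
})

test_that("compute_csp matches residues and is symmetric in direction", {
  free <- data.frame(residue_id = c(18, 21), residue_name = c("TYR", "TRP"),
                     shift_h = c(8.0, 8.2), shift_x = c(118, 121))
  bound <- free
  bound$shift_h <- bound$shift_h + c(0.03, -0.01)
  bound$shift_x <- bound$shift_x + c(0.2, -0.4)
  out <- compute_csp(free, bound)
  expect_equal(out$csp, c(combined_csp(0.03, 0.2), combined_csp(0.01, 0.4)))
  # symmetric under swapping free/bound
  expect_equal(compute_csp(bound, free)$csp, out$csp)
  bad <- bound
  bad$residue_name <- c("TRP", "TYR")
  expect_error(compute_csp(free, bad), "residue mismatch")
})

test_that("csp_threshold equals a brute-force sort/trim/mean/sd recomputation", {
  # all equal: sigma 0 so threshold is the common value
  expect_equal(csp_threshold(rep(0.07, 10)), 0.07)
  # no trim, no sigma: plain mean
  x <- c(0.01, 0.05, 0.3)
  expect_equal(csp_threshold(x, trim_fraction = 0, n_sigma = 0), mean(x))
  # the spec's spike example with an explicit remaining set
  spike <- c(rep(0, 9), 1)
  expect_equal(csp_threshold(spike, 0.10, 2),
               oracle_threshold(spike, 0.10, 2))
  set.seed(11)
  for (i in 1:50) {
    v <- stats::rlnorm(sample(5:40, 1), sdlog = 1) / 20
    tf <- stats::runif(1, 0, 0.3)
    ns <- stats::runif(1, 0, 3)
    expect_equal(csp_threshold(v, tf, ns), oracle_threshold(v, tf, ns))
    expect_equal(csp_threshold(v, tf, ns, sigma_on = "full"),
                 oracle_threshold(v, tf, ns, sigma_on = "full"))
  }
  expect_error(csp_threshold(c(0.1, 0.2)), "at least 3")
  expect_error(csp_threshold(1:5, trim_fraction = 0.5), "trim_fraction")
})

test_that("truncate_series restricts the schedule and keeps the free point", {
  spec <- csp_defaults("csp_peptide")
  spec$schedule <- c(0, 1, 2, 4, 8, 16) * 1e-3
  spec$noise_sd <- 0
  sim <- simulate_csp_titration(spec, seed = 1)
  tr <- truncate_series(sim$curves, 4e-3)
  expect_equal(sort(unique(tr$ligand_total)), c(0, 1, 2, 4) * 1e-3)
  # cutoff above all points: identity
  expect_equal(nrow(truncate_series(sim$curves, 1)), nrow(sim$curves))
  expect_error(truncate_series(sim$curves, 0.5e-3), "fewer than 3")
  # noiseless fit on truncated vs full data returns the same kd
  f_full <- fit_csp(sim$curves, spec$receptor_total)
  f_trunc <- fit_csp(tr, spec$receptor_total)
  expect_equal(f_trunc$kd, f_full$kd, tolerance = 1e-6)
})

test_that("global isotherm fit recovers noiseless truth across the kd range", {
  for (kd_true in c(1e-6, 1e-4, 1e-2, 0.1)) {
    spec <- csp_defaults("csp_peptide")
    spec$kd <- kd_true
    spec$noise_sd <- 0
    # schedule spanning the relevant range for each kd
    spec$schedule <- c(0, 0.25, 0.5, 1, 2, 4) * (2 * kd_true + 0.3e-3)
    sim <- simulate_csp_titration(spec, seed = 3)
    fit <- fit_csp(sim$curves, spec$receptor_total,
                   kd_bounds = c(1e-8, 10))
    expect_equal(fit$kd, kd_true, tolerance = 1e-6)
    expect_equal(unname(fit$csp_max[names(spec$csp_max)]),
                 unname(spec$csp_max), tolerance = 1e-6)
  }
})

test_that("isotherm fit errors on degenerate input", {
  spec <- csp_defaults("csp_peptide")
  spec$noise_sd <- 0
  sim <- simulate_csp_titration(spec, seed = 1)
  zero <- sim$curves
  zero$csp <- 0
  expect_error(fit_csp(zero, spec$receptor_total), "no binding signal")
  single <- sim$curves[sim$curves$ligand_total %in% c(0, 30e-3), ]
  expect_error(fit_csp(single, spec$receptor_total), "under-determined")
})

test_that("kd recovery under noise is nearly unbiased with a saturating schedule", {
  # schedule reaches >= 2x kd; median over 200 replicates within 5%
  spec <- csp_defaults("csp_dna")  # kd 150 uM, schedule to 1.2 mM (8x kd)
  kds <- vapply(1:200, function(s) {
    sim <- simulate_csp_titration(spec, seed = s)
    fit_csp(sim$curves, spec$receptor_total)$kd
  }, numeric(1))
  expect_lt(abs(stats::median(kds) - spec$kd) / spec$kd, 0.05)
})

test_that("profile-likelihood interval collapses on noiseless data, widens when unsaturated", {
  spec <- csp_defaults("csp_dna")
  spec$noise_sd <- 0
  sim <- simulate_csp_titration(spec, seed = 2)
  fit <- fit_csp(sim$curves, spec$receptor_total)
  ci <- confint(fit)
  expect_lt((ci[2] - ci[1]) / fit$kd, 0.01)
  expect_gt(ci[1], 0)
  expect_true(ci[1] <= fit$kd && fit$kd <= ci[2])

  # truncated weak-binding titration: wide asymmetric interval
  spec2 <- csp_defaults("csp_mla")  # kd 11 mM, schedule to 4 mM
  sim2 <- simulate_csp_titration(spec2, seed = 5)
  fit2 <- fit_csp(truncate_series(sim2$curves, 4e-3),
                  spec2$receptor_total)
  ci2 <- confint(fit2)
  expect_gt(ci2[1], 0)
  upper <- if (is.finite(ci2[2])) ci2[2] else 1
  expect_gt((upper - fit2$kd) / (fit2$kd - ci2[1]), 2)
})
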