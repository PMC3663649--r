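test_that("1:1 solver returns the physical root of the mass balance", {
  # no ligand, stoichiometric limit, and a representative weak-binding point
  expect_equal(solve_1to1_complex(0.3e-3, 0, 17e-3), 0)
  expect_equal(solve_1to1_complex(0.3e-3, 17e-3, 1e-15), 0.3e-3,
               tolerance = 1e-9)
  expect_equal(solve_1to1_complex(0.3e-3, 17e-3, 17e-3),
               oracle_1to1(0.3e-3, 17e-3, 17e-3), tolerance = 1e-10)
  expect_error(solve_1to1_complex(-1e-3, 1e-3, 1e-3), "receptor_total")
  expect_error(solve_1to1_complex(1e-3, 1e-3, 0), "kd")
})

test_that("1:1 solver agrees with bisection on random parameter sets and is monotone", {
  set.seed(42)
  for (i in 1:1000) {
    P0 <- 10^stats::runif(1, -7, -2)
    L0 <- 10^stats::runif(1, -7, -1)
    kd <- 10^stats::runif(1, -8, -1)
    pl <- solve_1to1_complex(P0, L0, kd)
    expect_equal(pl, oracle_1to1(P0, L0, kd), tolerance = 1e-8)
    expect_lte(pl, min(P0, L0) * (1 + 1e-12))
  }
  # monotone non-decreasing in ligand, non-increasing in kd
  set.seed(43)
  for (i in 1:50) {
    P0 <- 10^stats::runif(1, -6, -3)
    kd <- 10^stats::runif(1, -7, -2)
    lig <- sort(10^stats::runif(8, -7, -2))
    pl <- solve_1to1_complex(P0, lig, kd)
    expect_true(all(diff(pl) >= -1e-15))
    kds <- sort(10^stats::runif(8, -7, -2))
    pk <- vapply(kds, function(k) solve_1to1_complex(P0, 1e-3, k),
                 numeric(1))
    expect_true(all(diff(pk) <= 1e-15))
  }
})

test_that("two-site solver conserves mass and matches the bisection oracle", {
  ms <- solve_two_site(116e-6, 232e-6, 1.5e-6)
  expect_equal(ms$free_ligand, oracle_two_site_free(116e-6, 232e-6, 1.5e-6),
               tolerance = 1e-10)
  expect_equal(ms$free_ligand * 1e6, 17.9, tolerance = 0.01)
  expect_equal(ms$occupancy, 0.92, tolerance = 0.01)
  set.seed(7)
  for (i in 1:200) {
    N0 <- 10^stats::runif(1, -7, -3)
    L0 <- 10^stats::runif(1, -8, -2)
    kd <- 10^stats::runif(1, -8, -3)
    ms <- solve_two_site(N0, L0, kd)
    expect_equal(ms$free_ligand, oracle_two_site_free(N0, L0, kd),
                 tolerance = 1e-8)
    # mass balance: free + 2 N0 theta = L0
    expect_equal(ms$free_ligand + 2 * N0 * ms$occupancy, L0,
                 tolerance = 1e-9)
    expect_equal(ms$f0 + ms$f1 + ms$f2, 1, tolerance = 1e-12)
    expect_true(ms$free_ligand >= 0 && ms$free_ligand <= L0)
    expect_true(ms$occupancy >= 0 && ms$occupancy <= 1)
  }
})

test_that("two-site species fractions are binomial and limits behave", {
  # zero ligand
  ms0 <- solve_two_site(1e-6, 0, 1e-6)
  expect_equal(ms0$occupancy, 0)
  expect_equal(c(ms0$f0, ms0$f1, ms0$f2), c(1, 0, 0))
  # binomial composition vs exhaustive 2-site enumeration
  for (theta in c(0.1, 0.5, 0.77)) {
    # construct a state with this occupancy: free ligand = kd*theta/(1-theta)
    kd <- 2e-6
    x <- kd * theta / (1 - theta)
    N0 <- 5e-6
    L0 <- x + 2 * N0 * theta
    ms <- solve_two_site(N0, L0, kd)
    expect_equal(ms$occupancy, theta, tolerance = 1e-10)
    expect_equal(c(ms$f0, ms$f1, ms$f2), oracle_species_fractions(theta),
                 tolerance = 1e-10)
  }
  expect_equal(oracle_species_fractions(0.5), c(0.25, 0.5, 0.25))
  # weak-binding linear limit: theta ~ L0/kd when kd >= 100*L0
  N0 <- 1e-6; L0 <- 1e-6; kd <- 100 * L0
  ms <- solve_two_site(N0, L0, kd)
  expect_equal(ms$occupancy, L0 / kd, tolerance = 0.01)
})

test_that("avidity arithmetic: effective concentration, fold enhancement, lifetime", {
  expect_equal(effective_concentration(1.7e-2, 1.5e-4, 1.5e-6), 1.7,
               tolerance = 1e-12)
  expect_equal(effective_concentration(1, 1, 1), 1)
  expect_equal(effective_concentration(1e-3, 1e-3, 1e-6), 1)
  expect_error(effective_concentration(0, 1, 1), "kd_tail")

  fe <- fold_enhancement(17e-3, 1.5e-6)
  expect_equal(fe$ratio, 17e-3 / 1.5e-6)
  expect_equal(fe$nearest_power_of_ten, 1e4)
  expect_equal(fold_enhancement(1.5e-4, 1.5e-6)$ratio, 100)
  expect_equal(fold_enhancement(3, 3), list(ratio = 1,
                                            nearest_power_of_ten = 1))

  expect_equal(complex_lifetime(500), 0.002)
  expect_equal(complex_lifetime(1), 1)
  expect_equal(complex_lifetime(1000), 1e-3)
  expect_error(complex_lifetime(0), "koff")
  expect_error(complex_lifetime(-5), "koff")
})
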