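test_that("phases follow the step-time / stride-time ratio on constructed events", {
  hs <- heel_strike_series(times_left = c(0, 1.07), times_right = 0.535)
  # a single usable triple is below the 2-phase minimum
  expect_error(compute_phase_series(hs, "RreL"), "insufficient data")

  hs <- heel_strike_series(times_left = c(0, 1.07, 2.14),
                           times_right = c(0.535, 1.605))
  expect_equal(as.numeric(compute_phase_series(hs, "RreL")), c(180, 180),
               tolerance = 1e-12)

  hs2 <- heel_strike_series(c(0, 1.0, 2.0), c(0.25, 1.75))
  expect_equal(as.numeric(compute_phase_series(hs2, "RreL")), c(90, 270),
               tolerance = 1e-12)
})

test_that("phases are invariant under positive affine rescaling of time", {
  set.seed(11)
  st <- rnorm(20, 1.07, 0.02)
  phi <- 180 + rnorm(20, 0, 10)
  hs <- simulate_heel_strikes(st, phi, "RreL")
  for (scale in c(2.5, 0.1)) {
    hs2 <- heel_strike_series(3.7 + scale * hs$times_left,
                              3.7 + scale * hs$times_right)
    expect_equal(as.numeric(compute_phase_series(hs2, "RreL")),
                 as.numeric(compute_phase_series(hs, "RreL")),
                 tolerance = 1e-9)
  }
})

test_that("malformed heel-strike input is rejected with located errors", {
  expect_error(heel_strike_series(c(0, 1, 0.5), c(0.2, 0.7)),
               "not strictly increasing at event 3")
  # role-A strike outside its role-B stride
  hs <- heel_strike_series(times_left = c(0, 1, 2, 3),
                           times_right = c(0.5, 2.5, 2.7))
  expect_error(compute_phase_series(hs, "RreL"),
               "interleaving violated at gait cycle 2")
})

test_that("leading and trailing unmatched events are dropped with a warning", {
  hs <- heel_strike_series(times_left = c(0, 1, 2, 3),
                           times_right = c(0.5, 1.5, 2.5, 3.5))
  expect_warning(phi <- compute_phase_series(hs, "RreL"), "trailing")
  expect_length(phi, 3)
  # complementary convention drops the leading left strike at t = 0
  expect_warning(phi2 <- compute_phase_series(hs, "LreR"), "leading")
  expect_length(phi2, 3)
})

test_that("PCI matches direct evaluation of its two-term formula", {
  expect_identical(compute_pci(c(180, 180, 180, 180)), 0)

  cmp <- pci_components(c(170, 190))
  expect_equal(cmp$phi_cv, 100 * sqrt(200) / 180, tolerance = 1e-9)
  expect_equal(cmp$p_phi_abs, 100 * 10 / 180, tolerance = 1e-9)
  expect_equal(cmp$pci, 13.4122975, tolerance = 1e-6)

  # independent direct-formula evaluation on arbitrary vectors
  set.seed(21)
  for (phi in list(c(90, 270), 180 + rnorm(15, 0, 6), runif(8, 100, 260))) {
    direct <- 100 * sd(phi) / mean(phi) + 100 * mean(abs(phi - 180)) / 180
    expect_equal(compute_pci(phi), direct, tolerance = 1e-12)
  }
  expect_error(compute_pci(180), "insufficient data")
})

test_that("PCI is non-negative and zero only for perfect anti-phase", {
  set.seed(31)
  for (i in 1:25) {
    phi <- 180 + rnorm(12, 0, runif(1, 0.1, 30))
    expect_gte(compute_pci(phi), 0)
    if (any(phi != 180)) expect_gt(compute_pci(phi), 0)
  }
})

test_that("cumulative PCI series has the prefix property", {
  set.seed(41)
  phi <- 180 + rnorm(50, 0, 5)
  s <- cumulative_pci_series(phase_series(phi, "RreL", "p1"))
  expect_s3_class(s, "pci_series")
  expect_length(s, 49)
  expect_identical(strides(s), 2:50)
  for (j in c(1, 7, 23, 49)) {
    expect_equal(as.numeric(s)[j], compute_pci(phi[1:(j + 1)]),
                 tolerance = 1e-9)
  }
  expect_equal(as.numeric(cumulative_pci_series(rep(180, 20))), rep(0, 19))
})

test_that("average PCI series is the element-wise mean", {
  a <- pci_series(c(2, 4), "RreL")
  b <- pci_series(c(4, 2), "LreR")
  avg <- average_pci_series(a, b)
  expect_equal(as.numeric(avg), c(3, 3))
  expect_identical(attr(avg, "side"), "average")
  expect_equal(as.numeric(average_pci_series(a, a)), as.numeric(a))

  set.seed(51)
  x <- pci_series(runif(10, 1, 9)); y <- pci_series(runif(10, 1, 9))
  expect_equal(as.numeric(average_pci_series(x, y)),
               (as.numeric(x) + as.numeric(y)) / 2, tolerance = 1e-12)
  expect_error(average_pci_series(a, pci_series(1:3)), "length mismatch")
})

test_that("cumulative CV series generalizes the detector to other metrics", {
  expect_equal(as.numeric(cumulative_cv_series(rep(1.07, 10))), rep(0, 9))
  expect_equal(as.numeric(cumulative_cv_series(c(1, 1.1))),
               100 * (0.1 / sqrt(2)) / 1.05, tolerance = 1e-9)
  set.seed(61)
  x <- rnorm(30, 1.07, 0.05)
  s <- cumulative_cv_series(x)
  for (j in c(1, 10, 29)) {
    expect_equal(as.numeric(s)[j], 100 * sd(x[1:(j + 1)]) / mean(x[1:(j + 1)]),
                 tolerance = 1e-9)
  }
  expect_error(cumulative_cv_series(1.07), "insufficient data")
})

test_that("both phase conventions are recoverable from one trial", {
  set.seed(71)
  st <- rnorm(31, 1.07, 0.02)
  phi <- 180 + rnorm(31, 0, 5)
  hs <- simulate_heel_strikes(st, phi, "RreL")
  r <- compute_phase_series(hs, "RreL")
  l <- suppressWarnings(compute_phase_series(hs, "LreR"))
  expect_length(r, 31)
  expect_length(l, 30)
  # with near-equal strides the conventions are complementary around 360
  expect_equal(mean(as.numeric(r)[-31] + as.numeric(l)), 360, tolerance = 1)
})
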