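# Binding isotherms, Kd fitting, CSP analysis, remnant masses.

test_that("fraction_bound is the physical root of the binding quadratic", {
  # half-saturation in the dilute limit
  expect_equal(fraction_bound(0, 26.5e-6, 26.5e-6), 0.5)
  expect_equal(fraction_bound(1e-12, 26.5e-6, 26.5e-6), 0.5, tolerance = 1e-4)
  # with P = 50 nM and L = Kd = 26.5 uM, depletion barely shifts fb
  expect_equal(fraction_bound(50e-9, 26.5e-6, 26.5e-6), 0.4998,
               tolerance = 1e-3)
  # saturation
  expect_gt(fraction_bound(50e-9, 1, 26.5e-6), 0.999)
  # monotone increasing in L, decreasing in Kd; bounded
  L <- 10^seq(-8, -2, length.out = 30)
  fb <- fraction_bound(50e-9, L, 1e-5)
  expect_true(all(diff(fb) > 0))
  expect_true(all(fb >= 0 & fb <= 1))
  kds <- 10^seq(-7, -3, length.out = 20)
  fk <- vapply(kds, function(k) fraction_bound(50e-9, 1e-5, k), numeric(1))
  expect_true(all(diff(fk) < 0))
  # P -> 0 limit matches L/(L+Kd)
  expect_equal(fraction_bound(1e-15, L, 1e-5), L / (L + 1e-5),
               tolerance = 1e-6)
})

test_that("simulate_titration is exact at zero noise and seeded", {
  concs <- 10^seq(-7, -3.5, length.out = 10)
  c0 <- simulate_titration(1e-5, 0.05, 0.25, 50e-9, concs, 0, 1)
  mu <- 0.05 + 0.2 * fraction_bound(50e-9, concs, 1e-5)
  expect_equal(c0$response, mu)
  flat <- simulate_titration(1e-5, 0.1, 0.1, 50e-9, concs, 0, 1)
  expect_true(all(flat$response == 0.1))
  n1 <- simulate_titration(1e-5, 0.05, 0.25, 50e-9, concs, 0.01, 7)
  n2 <- simulate_titration(1e-5, 0.05, 0.25, 50e-9, concs, 0.01, 7)
  expect_identical(n1$response, n2$response)
  expect_false(identical(n1$response,
                         simulate_titration(1e-5, 0.05, 0.25, 50e-9, concs,
                                            0.01, 8)$response))
})

test_that("fit_kd recovers noise-free parameters and flags pathologies", {
  concs <- exp(seq(log(0.25e-6), log(320e-6), length.out = 12))
  for (kd in c(1e-6, 2.65e-5, 1.482e-4)) {
    f <- fit_kd(simulate_titration(kd, 0.05, 0.25, 50e-9, concs, 0, 1))
    expect_true(f$converged)
    expect_lt(abs(f$Kd - kd) / kd, 1e-3)
  }
  # flat curve: non-convergence flag, no exception
  flat <- fit_kd(simulate_titration(1e-5, 0.1, 0.1, 50e-9, concs, 0, 1))
  expect_false(flat$converged)
  # far-from-saturating curve flagged by the diagnostic
  ns <- fit_kd(simulate_titration(5e-3, 0.05, 0.25, 50e-9, concs, 0, 1))
  expect_false(ns$saturated)
  sat <- fit_kd(simulate_titration(5e-6, 0.05, 0.25, 50e-9, concs, 0, 1))
  expect_true(sat$saturated)
})

test_that("fit_kd Monte-Carlo recovery: median relative error < 10%", {
  concs <- exp(seq(log(0.25e-6), log(320e-6), length.out = 12))
  errs <- c()
  for (kd in c(1e-6, 1e-5, 1e-4)) {
    for (i in 1:50) {
      cur <- simulate_titration(kd, 0.05, 0.25, 50e-9, concs,
                                noise_sd = 0.02 * 0.2, seed = 1000 + i)
      f <- fit_kd(cur)
      expect_gt(f$Kd, 0)
      errs <- c(errs, abs(f$Kd - kd) / kd)
    }
  }
  expect_lt(median(errs), 0.10)
})

test_that("csp combines 1H and scaled 15N shifts", {
  free <- peak_list(c("G10", "A11"), dH = c(8.1, 8.3), dN = c(110, 121))
  bound <- peak_list(c("G10", "A11", "K12"), dH = c(8.13, 8.3, 7.9),
                     dN = c(110.1, 121, 105))
  d <- csp(free, bound)
  expect_equal(unname(d["G10"]), sqrt(0.03^2 + (0.2 * 0.1)^2),
               tolerance = 1e-9)
  expect_equal(unname(d["G10"]), 0.036056, tolerance = 1e-4)
  expect_equal(unname(d["A11"]), 0)
  expect_equal(attr(d, "unassigned"), "K12")
  # symmetric in which list is free vs bound
  expect_equal(unname(csp(bound, free)["G10"]), unname(d["G10"]))
  expect_error(csp(free, peak_list("Z9", 1, 1)), "shared")
})

test_that("classify_csp applies the printed thresholds with lower-class ties", {
  x <- c(a = 0, b = 0.02, c = 0.025, d = 0.03, e = 0.04, f = 0.05)
  cls <- classify_csp(x, c(0.025, 0.04))
  expect_equal(as.character(cls),
               c("slight", "slight", "slight", "intermediate",
                 "intermediate", "strong"))
  g <- classify_csp(c(r = 0.15), c(0.1, 0.2))
  expect_equal(as.character(g), "intermediate")
  expect_equal(as.character(classify_csp(c(r = 0), c(0.1, 0.2))), "slight")
  expect_error(classify_csp(x, c(0.2, 0.1)), "t1 < t2")
})

test_that("intensity_ratio caps and flags as specified", {
  free <- peak_list(c("A", "B", "C"), 0, 0, intensity = c(10, 10, 0))
  bound <- peak_list(c("A", "B", "C"), 0, 0, intensity = c(32, 0, 5))
  r <- intensity_ratio(bound, free)
  expect_equal(unname(r["A"]), 3.2)
  expect_equal(unname(r["B"]), 0)
  expect_true(is.na(r["C"]))
  capped <- intensity_ratio(bound, free, cap = 1.0)
  expect_equal(unname(capped["A"]), 1.0)
  ident <- intensity_ratio(free, free)
  expect_equal(unname(ident[c("A", "B")]), c(1, 1))
})

test_that("remnant_mass reproduces standard monoisotopic arithmetic", {
  expect_equal(remnant_mass("GG"), 114.042928, tolerance = 1e-9)
  expect_error(remnant_mass("VBG"), "unknown residue")
  # additivity over concatenation
  withr::with_seed(37, {
    for (i in 1:10) {
      a <- random_protein(sample(1:6, 1)); b <- random_protein(sample(1:6, 1))
      expect_equal(remnant_mass(paste0(a, b)),
                   remnant_mass(a) + remnant_mass(b), tolerance = 1e-9)
    }
  })
})
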