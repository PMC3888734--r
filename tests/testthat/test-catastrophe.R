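test_that("the registry is exactly Thom's seven with fixed dimensions", {
  reg <- normal_form_registry()
  expect_length(reg, 7)
  expect_equal(unname(vapply(reg, `[[`, numeric(1), "control_dim")),
               c(1, 2, 3, 4, 3, 3, 4))
  expect_equal(unname(vapply(reg, `[[`, numeric(1), "corank")),
               c(1, 1, 1, 1, 2, 2, 2))
  expect_lte(max(vapply(reg, `[[`, numeric(1), "control_dim")), 5)
  # germ of the cusp at the origin: value, gradient, Hessian all degenerate
  cusp <- reg[["cusp"]]
  expect_equal(cusp$germ(0), 0)
  expect_equal(cusp$grad(0), 0)
  expect_equal(cusp$hess(0)[1, 1], 0)
  # registry contents do not vary across calls
  expect_identical(vapply(normal_form_registry(), `[[`, "", "name"),
                   vapply(reg, `[[`, "", "name"))
})

test_that("each registry germ classifies as itself (self-classification)", {
  reg <- normal_form_registry()
  for (nm in names(reg)) {
    e <- reg[[nm]]
    if (e$state_dim == 1) {
      s <- seq(-0.5, 0.5, length.out = 41)
      samp <- data.frame(s = s, f = vapply(s, e$germ, numeric(1)))
    } else {
      g <- expand.grid(s1 = seq(-0.5, 0.5, length.out = 21),
                       s2 = seq(-0.5, 0.5, length.out = 21))
      samp <- data.frame(g, f = apply(g, 1, function(r) e$germ(r)))
    }
    res <- classify_germ(samp, e$state_dim)
    expect_equal(res$class, nm)
    expect_equal(res$corank, e$corank)
    expect_lt(res$residual, 1e-8)
  }
})

test_that("classification edge cases: morse, noise robustness, guards", {
  s <- seq(-0.5, 0.5, length.out = 41)
  # double-well quartic away from degeneracy: central max is nondegenerate
  res <- classify_germ(data.frame(s = s, f = 0.25 * s^4 - 0.5 * s^2), 1)
  expect_equal(res$class, "morse")

  # quartic germ with vanishing controls recovers cusp with controls ~ 0
  res2 <- classify_germ(data.frame(s = s, f = 0.25 * s^4), 1)
  expect_equal(res2$class, "cusp")
  expect_lt(max(abs(res2$controls)), 1e-8)
  expect_lt(res2$residual, 1e-8)

  # tiny additive noise on a fold stays a fold
  set.seed(42)
  res3 <- classify_germ(data.frame(s = s, f = s^3 + 1e-10 * rnorm(41)), 1)
  expect_equal(res3$class, "fold")

  # non-critical center is rejected with the gradient norm
  expect_error(classify_germ(data.frame(s = s, f = s + s^3), 1),
               "not a critical point")
  # missing columns
  expect_error(classify_germ(data.frame(x = s, f = s^3), 1), "columns")
  # non-polynomial beyond degree 6 at O(1) amplitude -> unclassified
  res4 <- classify_germ(data.frame(s = 2 * s, f = cos(8 * s) - 1), 1)
  expect_equal(res4$class, "unclassified")
})

test_that("cusp at (a,b) = (-1,0) survives 200/200 higher-order kicks", {
  rep <- perturbation_stability_test("cusp", controls = c(-1, 0),
                                     window = 1.5, degree_min = 5,
                                     degree_max = 8, amplitude = 1e-3,
                                     trials = 200, seed = 42)
  expect_equal(rep$preserved, 200L)
  expect_equal(nrow(rep$baseline), 3)            # s = -1, 0, 1
  expect_equal(rep$baseline$index, c(0L, 1L, 0L))  # min, max, min
})

test_that("stability degrades for violent perturbations, never for none", {
  rep0 <- perturbation_stability_test("cusp", c(-1, 0), window = 1.5,
                                      degree_min = 5, degree_max = 8,
                                      amplitude = 0, trials = 30,
                                      seed = 42)
  expect_equal(rep0$preserved, rep0$trials)
  rep_big <- perturbation_stability_test("cusp", c(-1, 0), window = 1.5,
                                         degree_min = 5, degree_max = 8,
                                         amplitude = 10, trials = 30,
                                         seed = 42)
  expect_lt(rep_big$preserved, rep_big$trials)

  # preserved fraction is nonincreasing along an amplitude ladder at a
  # fixed seed (same unit draws, scaled)
  ladder <- c(1e-3, 1e-1, 1, 10)
  fr <- vapply(ladder, function(a)
    perturbation_stability_test("cusp", c(-1, 0), window = 1.5,
                                degree_min = 5, degree_max = 8,
                                amplitude = a, trials = 40,
                                seed = 7)$preserved, integer(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("stability test argument guards", {
  expect_error(perturbation_stability_test("cusp", c(-1, 0),
                                           degree_min = 4, degree_max = 8,
                                           amplitude = 1e-3, trials = 5),
               "exceed the germ degree")
  expect_error(perturbation_stability_test("nope", c(-1, 0),
                                           degree_min = 5, degree_max = 8,
                                           amplitude = 1e-3, trials = 5),
               "registry")
  expect_error(perturbation_stability_test("elliptic_umbilic", c(0, 0, 0),
                                           degree_min = 5, degree_max = 8,
                                           amplitude = 1e-3, trials = 5),
               "one-state-variable")
  expect_error(perturbation_stability_test("cusp", c(-1),
                                           degree_min = 5, degree_max = 8,
                                           amplitude = 1e-3, trials = 5),
               "control")
})

test_that("stability reports are reproducible given the seed", {
  args <- list("cusp", c(-1, 0), window = 1.5, degree_min = 5,
               degree_max = 8, amplitude = 0.5, trials = 25, seed = 99)
  a <- do.call(perturbation_stability_test, args)
  b <- do.call(perturbation_stability_test, args)
  expect_identical(a$preserved, b$preserved)
})

test_that("boltzmann moments: parity, quartic closed form, harmonic limit", {
  # even potential: first moment vanishes
  expect_equal(unname(boltzmann_moments(cusp_germ(-1, 0), orders = 1)), 0,
               tolerance = 1e-10)
  # pure quartic V = theta^4/4 at kBT = 1:
  # <theta^2> = sqrt(4 kBT) Gamma(3/4) / Gamma(1/4)
  m2 <- boltzmann_moments(cusp_germ(0, 0), kBT = 1, orders = 2)
  expect_equal(unname(m2), 2 * gamma(0.75) / gamma(0.25),
               tolerance = 1e-6)
  # scaling in kBT: <theta^2> ~ (4 kBT)^(1/2) * Gamma ratio
  m2b <- boltzmann_moments(cusp_germ(0, 0), kBT = 2, orders = 2)
  expect_equal(unname(m2b), sqrt(8) * gamma(0.75) / gamma(0.25),
               tolerance = 1e-6)
  # stiff quadratic dominates: harmonic limit kBT / a within 1%
  m2c <- boltzmann_moments(cusp_germ(100, 0), kBT = 1, orders = 2)
  expect_equal(unname(m2c), 1 / 100, tolerance = 1e-2)
  # non-confining potential errors
  expect_error(boltzmann_moments(function(x) -x^2, orders = 2),
               "non-confining")
})

test_that("variance is nonnegative for assorted confining potentials", {
  pots <- list(cusp_germ(-2, 0.5), cusp_germ(3, -1),
               function(x) abs(x)^1.5, function(x) x^2 + sin(3 * x))
  for (p in pots) {
    m <- boltzmann_moments(p, kBT = 0.7, orders = 1:2)
    expect_gte(m[["m2"]], m[["m1"]]^2 - 1e-10)
  }
})

test_that("moment inversion round-trips and respects symmetry", {
  mm <- boltzmann_moments(cusp_germ(1, 0.2), orders = 1:3)
  rec <- recover_cusp_controls(mm)
  expect_equal(rec$a, 1, tolerance = 1e-3)
  expect_equal(rec$b, 0.2, tolerance = 1e-3)

  # symmetric moments force b = 0
  mm_sym <- boltzmann_moments(cusp_germ(2, 0), orders = 1:3)
  rec_sym <- recover_cusp_controls(mm_sym)
  expect_equal(rec_sym$b, 0, tolerance = 1e-6)
})

test_that("recovery under 1% noise: median error below 0.1", {
  exact <- boltzmann_moments(cusp_germ(2, 0), orders = 1:3)
  set.seed(7)
  errs <- replicate(100, {
    noisy <- exact * rnorm(3, 1, 0.01)
    fit <- recover_cusp_controls(noisy, start = c(1.5, 0))
    abs(fit$a - 2)
  })
  expect_lt(stats::median(errs), 0.1)
})
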