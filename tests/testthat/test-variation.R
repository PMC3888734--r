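test_that("action integral reproduces closed forms", {
  ch <- unit_oscillator()
  # rest at the potential minimum: L identically 0
  tr0 <- integrate_trajectory(free_chain(), 0, 0, 0, 1, 100)
  expect_equal(action_integral(free_chain(), tr0), 0)

  # constant Lagrangian: free motion at speed v has L = v^2/2
  trc <- integrate_trajectory(free_chain(), 0, 0.8, 0, 3, 60)
  expect_equal(action_integral(free_chain(), trc), 0.5 * 0.8^2 * 3,
               tolerance = 1e-12)

  # theta(t) = sin t on [0, pi/4]: S = sin(2t)/4 evaluated at pi/4 = 1/4
  trs <- analytic_trajectory(ch, function(t) sin(t), function(t) cos(t),
                             0, pi / 4, 400)
  expect_equal(action_integral(ch, trs), 0.25, tolerance = 1e-9)
  # odd interval counts exercise the 3/8 tail
  trs2 <- analytic_trajectory(ch, function(t) sin(t), function(t) cos(t),
                              0, pi / 4, 401)
  expect_equal(action_integral(ch, trs2), 0.25, tolerance = 1e-9)
})

test_that("EL residual separates stationary from corrupted paths", {
  ch <- unit_oscillator()
  tr <- integrate_trajectory(ch, 1, 0, 0, 4, 800)
  r0 <- el_residual(ch, tr)
  expect_lt(r0, 1e-4)
  # on an exactly sampled solution the residual is pure discretization
  # error and shrinks at second order under grid refinement
  ra <- el_residual(ch, analytic_trajectory(ch, cos, function(t) -sin(t),
                                            0, 4, 400))
  rb <- el_residual(ch, analytic_trajectory(ch, cos, function(t) -sin(t),
                                            0, 4, 800))
  expect_equal(ra / rb, 4, tolerance = 0.2)

  # corrupt one interior point
  trc <- tr
  trc$positions[400, 1] <- trc$positions[400, 1] + 0.1
  expect_gt(el_residual(ch, trc), 10 * r0)

  # free straight line is exactly stationary
  trf <- integrate_trajectory(free_chain(), 0.2, 0.5, 0, 2, 100)
  expect_lt(el_residual(free_chain(), trf), 1e-12)
})

test_that("second variation form matches direct quadrature and symmetry", {
  ch <- unit_oscillator()
  tr <- integrate_trajectory(ch, 1, 0, 0, 1, 200)
  form <- second_variation_form(ch, tr)
  expect_lt(max(abs(form$Q - t(form$Q))), 1e-12)

  # quadrature oracle on the same piecewise-linear xi: exact element
  # stiffness + trapezoid potential term
  set.seed(3)
  tt <- tr$time
  h <- tr$h
  H <- vapply(seq_along(tt), function(i)
    potential_hessian(ch, tr$positions[i, ], tt[i])[1, 1], numeric(1))
  for (rep in 1:5) {
    xi <- c(0, rnorm(length(tt) - 2), 0)
    direct <- sum((diff(xi) / h)^2 * h) -
      sum(h * xi[2:(length(tt) - 1)]^2 * H[2:(length(tt) - 1)])
    expect_equal(second_variation_value(form, xi), direct,
                 tolerance = 1e-10)
  }
  expect_error(second_variation_value(form, c(1, rep(0, length(tt) - 1))),
               "vanish")
})

test_that("free motion gives a positive form; V = 0 eigenvalues exact", {
  ch <- free_chain()
  tr <- integrate_trajectory(ch, 0, 0.3, 0, 2, 200)
  form <- second_variation_form(ch, tr)
  expect_gt(min(form$eigenvalues), 0)
  # xi = sin(pi t) on [0,1], m=1, V=0: integral pi^2/2
  trf <- integrate_trajectory(ch, 0, 0, 0, 1, 400)
  formf <- second_variation_form(ch, trf)
  xi <- sin(pi * trf$time)
  xi[c(1, length(xi))] <- 0
  expect_equal(second_variation_value(formf, xi), pi^2 / 2,
               tolerance = 1e-3)
})

test_that("harmonic spectrum matches Sturm-Liouville eigenvalues", {
  ch <- unit_oscillator()
  for (T1 in c(3.0, 3.3)) {
    n <- 600
    tr <- integrate_trajectory(ch, 1, 0, 0, T1, n)
    form <- second_variation_form(ch, tr)
    ev <- second_variation_eigenvalues(form)
    analytic <- (seq_len(4) * pi / T1)^2 - 1
    expect_equal(ev[1:4], analytic, tolerance = 1e-2)
    if (T1 < pi) expect_gt(min(ev), 0) else expect_lt(min(ev), 0)
  }
})

test_that("non-stationary trajectories are rejected with the residual", {
  ch <- unit_oscillator()
  bad <- analytic_trajectory(ch, function(t) t^2, function(t) 2 * t,
                             0, 2, 100)
  expect_error(second_variation_form(ch, bad), "residual")
  expect_error(find_conjugate_points(ch, bad), "residual")
})

test_that("conjugate points: harmonic focus, none for free/inverted", {
  ch <- unit_oscillator()
  tr <- integrate_trajectory(ch, 1, 0, 0, 4, 800)
  cp <- find_conjugate_points(ch, tr)
  expect_equal(nrow(cp), 1)
  expect_equal(cp$t_star, pi, tolerance = 2e-3)
  expect_equal(cp$multiplicity, 1L)

  cpj <- jacobi_conjugate_points(ch, tr)
  expect_equal(nrow(cpj), 1)
  expect_equal(cpj$t_star, pi, tolerance = 2e-3)

  trf <- integrate_trajectory(free_chain(), 0, 0.4, 0, 6, 600)
  expect_equal(nrow(find_conjugate_points(free_chain(), trf)), 0)
  expect_equal(nrow(jacobi_conjugate_points(free_chain(), trf)), 0)

  chi <- inverted_oscillator()
  tri <- integrate_trajectory(chi, 0.05, 0, 0, 4, 2000)
  expect_equal(nrow(find_conjugate_points(chi, tri)), 0)
  expect_equal(nrow(jacobi_conjugate_points(chi, tri)), 0)
})

test_that("jacobi route handles omega = 2 and multi-angle chains", {
  # V = 2 theta^2 (half_k with k = 4): omega = 2, focus at pi/2
  ch <- torsion_chain(1, 1, harmonic_spring(4, half_k = TRUE))
  tr <- integrate_trajectory(ch, 0.5, 0, 0, 2.5, 1000)
  cpj <- jacobi_conjugate_points(ch, tr)
  expect_equal(cpj$t_star[1], pi / 2, tolerance = 2e-3)
  cp <- find_conjugate_points(ch, tr)
  expect_equal(cp$t_star[1], pi / 2, tolerance = 2e-3)

  # 2-angle isotropic oscillator: the focus at pi has multiplicity 2
  ch2 <- unit_oscillator(2)
  tr2 <- integrate_trajectory(ch2, c(1, 0.5), c(0, 0), 0, 4, 800)
  cp2 <- find_conjugate_points(ch2, tr2)
  expect_equal(nrow(cp2), 1)
  expect_equal(cp2$t_star, pi, tolerance = 2e-3)
  expect_equal(cp2$multiplicity, 2L)
})

test_that("the two conjugate-point routes agree within 10 h", {
  systems <- list(
    list(ch = unit_oscillator(), q0 = 1, v0 = 0, t1 = 4, n = 400),
    list(ch = torsion_chain(1, 1, harmonic_spring(2, half_k = TRUE)),
         q0 = 0.5, v0 = 0.2, t1 = 3, n = 300),
    list(ch = torsion_chain(1, 2, cusp_potential(2, 0)), q0 = 0.05,
         v0 = 0, t1 = 8, n = 800))
  for (sys in systems) {
    tr <- integrate_trajectory(sys$ch, sys$q0, sys$v0, 0, sys$t1, sys$n)
    a <- find_conjugate_points(sys$ch, tr)
    b <- jacobi_conjugate_points(sys$ch, tr)
    expect_equal(nrow(a), nrow(b))
    if (nrow(a) > 0)
      expect_lt(max(abs(a$t_star - b$t_star)), 10 * tr$h)
  }
})

test_that("Morse index is nondecreasing and jumps by the multiplicity", {
  ch <- unit_oscillator()
  # long interval: conjugate points at pi and 2 pi
  tr <- integrate_trajectory(ch, 1, 0, 0, 7, 1400)
  cp <- find_conjugate_points(ch, tr)
  expect_equal(cp$t_star, c(pi, 2 * pi), tolerance = 3e-3)
  Hlist <- causticfold:::hessians_along(ch, tr)
  negcum <- causticfold:::sv_pivot_negcum(1, Hlist, tr$h,
                                          1e-8 / tr$h^2)
  expect_true(all(diff(negcum) >= 0))
  expect_equal(max(negcum), sum(cp$multiplicity))
})

test_that("before the first conjugate point the arc minimizes the action", {
  ch <- unit_oscillator()
  tr <- integrate_trajectory(ch, 1, 0, 0, 3, 600)  # 3 < pi
  S0 <- action_integral(ch, tr)
  set.seed(7)
  tt <- tr$time
  T1 <- diff(range(tt))
  for (rep in 1:10) {
    # random smooth admissible perturbation with analytic derivative
    a <- rnorm(1); b <- rnorm(1)
    xi <- a * sin(pi * tt / T1) + b * sin(2 * pi * tt / T1)
    xidot <- a * pi / T1 * cos(pi * tt / T1) +
      b * 2 * pi / T1 * cos(2 * pi * tt / T1)
    eps <- 0.01
    trp <- tr
    trp$positions <- tr$positions + eps * xi
    trp$velocities <- tr$velocities + eps * xidot
    expect_gte(action_integral(ch, trp), S0 - 1e-10)
  }
})

test_that("conjugate-point time converges at second order in h", {
  ch <- unit_oscillator()
  t_star <- function(n) {
    tr <- integrate_trajectory(ch, 1, 0, 0, 4, n)
    find_conjugate_points(ch, tr)$t_star[1]
  }
  e1 <- abs(t_star(200) - pi)
  e2 <- abs(t_star(400) - pi)
  e3 <- abs(t_star(800) - pi)
  # halving h divides the error by about 4
  expect_gt(e1 / e2, 2.5)
  expect_gt(e2 / e3, 2.5)
})
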