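test_that("family action surface: free-particle closed form and guards", {
  # members start at position u with the velocity adjusted per target is the
  # analytic S(u,x) = m (x-u)^2 / (2 dt) situation; check it as an analytic
  # surface, and check the trajectory-surface container on the same physics
  m <- 1.3; dt <- 2
  surf <- analytic_action_surface(
    function(u, ctl) m * (ctl[1] - u)^2 / (2 * dt),
    seq(-1, 1, length.out = 101),
    data.frame(x = seq(-0.5, 0.5, length.out = 11)))
  ii <- 2:100
  expect_equal(surf$d2Sdu2[ii, 1], rep(m / dt, 100 - 1), tolerance = 1e-8)
  expect_equal(nrow(detect_caustic(surf)), 0)  # strictly convex in u

  chf <- free_chain()
  fam <- shoot_family(chf, function(u) list(q0 = u, v0 = 0.5),
                      seq(-1, 1, length.out = 9), 0, 2, 100)
  sf <- family_action_surface(fam, chf)
  # identical Lagrangians: S independent of u, dS/du = 0
  expect_lt(max(abs(sf$dSdu[2:8, ])), 1e-12)
  expect_equal(nrow(detect_caustic(sf)), 0)

  expect_error(family_action_surface(
    shoot_family(chf, function(u) list(q0 = u, v0 = 0),
                 seq(-1, 1, length.out = 3), 0, 1, 100), chf),
    "at least 5")
})

test_that("harmonic focus family: caustic, focus tag, curvature flip", {
  fam <- harmonic_focus_family(theta0 = 1)
  ch <- fam$chain
  surf <- family_action_surface(fam, ch)
  ca <- detect_caustic(surf)
  expect_equal(nrow(ca), 1)
  expect_equal(ca$axis_value, pi, tolerance = 5e-3)
  expect_equal(attr(ca, "type"), "focus")
  expect_equal(as.numeric(ca$x[[1]]), -1, tolerance = 1e-2)

  # fixed-time slices: S(u) concave just before the focus, convex after
  # (closed form S_uu = sin t cos t for this family)
  j_lo <- which.min(abs(surf$t - 3.0))
  j_hi <- which.min(abs(surf$t - 3.3))
  expect_lt(surf$d2Sdu2[11, j_lo], 0)
  expect_gt(surf$d2Sdu2[11, j_hi], 0)
  expect_equal(surf$d2Sdu2[11, j_lo], sin(3) * cos(3), tolerance = 1e-3)

  sc <- saddle_check_beyond(surf, ca)
  expect_equal(sc$status, "confirmed")
  expect_equal(sc$n_neg_before + sc$n_pos_before, 1)
  expect_equal(sc$n_neg_after + sc$n_pos_after, 1)
  expect_true(sc$n_neg_before != sc$n_neg_after)
})

test_that("caustic agrees with envelope and with the conjugate point", {
  fam <- harmonic_focus_family(theta0 = 1)
  ch <- fam$chain
  surf <- family_action_surface(fam, ch)
  ca <- detect_caustic(surf)
  env <- envelope_points(fam)
  expect_gt(nrow(env), 0)
  # the envelope collapses onto the focus
  expect_lt(diff(range(env$t)), 5 * (fam$time[2] - fam$time[1]))
  expect_equal(mean(env$t), pi, tolerance = 5e-3)
  expect_equal(mean(env$x_1), -1, tolerance = 1e-2)
  expect_lt(abs(mean(env$t) - ca$axis_value), 5 * (fam$time[2] - fam$time[1]))

  # central trajectory's conjugate point sits at the family caustic time
  tr <- fam$trajectories[[which(fam$u == 0)]]
  cp <- find_conjugate_points(ch, tr)
  expect_lt(abs(cp$t_star[1] - ca$axis_value), 10 * tr$h)
})

test_that("analytic cusp family: caustic on the fold discriminant", {
  surf <- cusp_surface_fixture()
  ca <- detect_caustic(surf)
  expect_gt(nrow(ca), 8)
  xs <- do.call(rbind, ca$x)
  disc <- 4 * xs[, 1]^3 + 27 * xs[, 2]^2
  # grid tolerance: discriminant gradient across one x2 cell
  dx2 <- 1.6 / 160
  tol_grid <- 54 * max(abs(xs[, 2])) * dx2
  expect_lt(max(abs(disc)), tol_grid)
  # detection is two-sided in x2 for every x1 slice
  for (x1v in unique(xs[, 1]))
    expect_setequal(sign(xs[xs[, 1] == x1v, 2]), c(-1, 1))
})

test_that("detected caustics are stable under 2x grid refinement", {
  coarse <- cusp_surface_fixture(u_n = 201, x2_n = 81)
  fine <- cusp_surface_fixture(u_n = 401, x2_n = 161)
  xa <- do.call(rbind, detect_caustic(coarse)$x)
  xb <- do.call(rbind, detect_caustic(fine)$x)
  cell <- 1.6 / 80
  for (i in seq_len(nrow(xa))) {
    same <- xb[abs(xb[, 1] - xa[i, 1]) < 1e-9 &
                 sign(xb[, 2]) == sign(xa[i, 2]), , drop = FALSE]
    expect_gt(nrow(same), 0)
    expect_lt(min(abs(same[, 2] - xa[i, 2])), cell)
  }
})

test_that("saddle check on the cusp family: one direction flips", {
  surf <- cusp_surface_fixture(x1 = -1)
  ca <- detect_caustic(surf)
  sc <- saddle_check_beyond(surf, ca)
  confirmed <- sc$status == "confirmed"
  expect_true(all(confirmed | sc$status == "unconfirmable"))
  expect_gt(sum(confirmed), 0)
})

test_that("envelope: projectile-like two-angle family has a fold envelope", {
  # free motion in two angles launched at fixed speed and varying direction
  # from the origin: members x(t) = t cos u, y(t) = t sin u - no gravity in
  # a flat potential, so add a constant force via a linear coupled potential
  # V = g * theta2 (constant downward force on the second angle)
  g <- 1
  ch <- torsion_chain(2, 1, coupled_potential(
    V = function(q) g * q[2],
    dV = function(q) c(0, g),
    d2V = function(q) matrix(0, 2, 2)))
  v0 <- 1.5
  fam <- shoot_family(ch, function(u) list(q0 = c(0, 0),
                                           v0 = c(v0 * cos(u),
                                                  v0 * sin(u))),
                      seq(0.25, pi - 0.25, length.out = 41), 0, 2.2, 220)
  env <- envelope_points(fam)
  expect_gt(nrow(env), 10)
  # classical safety parabola: y = v0^2/(2g) - g x^2 / (2 v0^2)
  pred <- v0^2 / (2 * g) - g * env$x_1^2 / (2 * v0^2)
  expect_lt(stats::median(abs(env$x_2 - pred)), 0.05)
})

test_that("hessian determinant scan matches the 1-D caustic condition", {
  # quadratic field: constant Hessian, no zeros anywhere
  flagged <- hessian_determinant_scan(
    function(p) 0.5 * (p[1]^2 + p[2]^2),
    list(seq(-1, 1, length.out = 11), seq(-1, 1, length.out = 11)))
  expect_equal(nrow(flagged), 0)

  # cusp field at fixed x1 = -0.3 scanned in u: det vanishes on
  # u^2 = -x1/3 = 0.1
  x1 <- -0.3
  flagged1 <- hessian_determinant_scan(
    function(p) 0.25 * p[1]^4 + 0.5 * x1 * p[1]^2,
    list(seq(-1, 1, length.out = 201)), tol = 2e-2)
  expect_gt(nrow(flagged1), 0)
  expect_lt(max(abs(abs(flagged1$c1) - sqrt(0.1))), 0.02)

  expect_error(hessian_determinant_scan(function(p) p[1]^2,
                                        list(seq(-1, 1, length.out = 4))),
               "at least 5")
})

test_that("degenerate and boundary cases of the saddle check", {
  chf <- free_chain()
  fam <- shoot_family(chf, function(u) list(q0 = u, v0 = 0.5),
                      seq(-1, 1, length.out = 9), 0, 2, 100)
  surf <- family_action_surface(fam, chf)
  ca <- detect_caustic(surf)
  sc <- saddle_check_beyond(surf, ca)
  expect_equal(nrow(sc), 0)

  # caustic at the scan boundary is unconfirmable, not an error
  fam2 <- harmonic_focus_family(theta0 = 1, t1 = 3.15, n_steps = 630)
  surf2 <- family_action_surface(fam2, fam2$chain)
  ca2 <- detect_caustic(surf2)
  if (nrow(ca2) > 0) {
    sc2 <- saddle_check_beyond(surf2, ca2)
    expect_true(all(sc2$status == "unconfirmable"))
  }
})
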