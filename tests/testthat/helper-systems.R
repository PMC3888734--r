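# standard systems reused across the suite

# unit-frequency oscillator: V = theta^2/2 (half_k), m = 1, omega = 1
unit_oscillator <- function(n_angles = 1) {
  torsion_chain(n_angles, 1, harmonic_spring(1, half_k = TRUE))
}

free_chain <- function(m = 1) torsion_chain(1, m, harmonic_spring(0))

inverted_oscillator <- function() torsion_chain(1, 1, harmonic_spring(-0.5))

# build a Trajectory directly from closed-form position/velocity functions
analytic_trajectory <- function(chain, q_fun, v_fun, t0, t1, n_steps) {
  tt <- seq(t0, t1, length.out = n_steps + 1)
  as_mat <- function(f) {
    v <- vapply(tt, f, numeric(chain$n_angles))
    if (is.null(dim(v))) matrix(v, ncol = 1) else t(v)
  }
  causticfold:::new_trajectory(tt, as_mat(q_fun), as_mat(v_fun), chain,
                               "analytic")
}

# the standard harmonic focus family: theta(t) = theta0 cos t + u sin t
harmonic_focus_family <- function(theta0 = 1, u_n = 21, t1 = 4,
                                  n_steps = 800) {
  ch <- unit_oscillator()
  shoot_family(ch, function(u) list(q0 = theta0, v0 = u),
               seq(-2, 2, length.out = u_n), 0, t1, n_steps)
}

cusp_surface_fixture <- function(u_n = 401, x1 = seq(-1.2, -0.5,
                                                     length.out = 8),
                                 x2_n = 161) {
  u <- seq(-2, 2, length.out = u_n)
  ctr <- expand.grid(x2 = seq(-0.8, 0.8, length.out = x2_n), x1 = x1)
  ctr <- ctr[, c("x1", "x2")]
  analytic_action_surface(
    function(u, ctl) 0.25 * u^4 + 0.5 * ctl[1] * u^2 + ctl[2] * u,
    u, ctr)
}
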