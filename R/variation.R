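#' Action integral along a trajectory
#'
#' Evaluates \eqn{S = \int_{t_0}^{t_1} (T - V)\,dt} by composite Simpson
#' quadrature on the uniform grid (Simpson 3/8 absorbs an odd final
#' interval). Realized motions make this integral stationary.
#'
#' @param chain a [torsion_chain()] consistent with the trajectory.
#' @param traj a `Trajectory`.
#' @return the scalar action.
#' @examples
#' ch <- torsion_chain(1, 1, harmonic_spring(1, half_k = TRUE))
#' tr <- integrate_trajectory(ch, 1, 0, 0, pi / 4, 200)
#' action_integral(ch, tr)
#' @export
action_integral <- function(chain, traj) {
  stopifnot(inherits(chain, "TorsionChain"), inherits(traj, "Trajectory"))
  L <- lagrangian_values(chain, traj)
  simpson(L, traj$h)
}

lagrangian_values <- function(chain, traj) {
  vapply(seq_along(traj$time), function(i) {
    kinetic_energy(chain, traj$velocities[i, ]) -
      evaluate_potential(chain, traj$positions[i, ], traj$time[i])
  }, numeric(1))
}

# composite Simpson on a uniform grid; 3/8 rule on the last three intervals
# when their count is odd. N >= 2 intervals required.
simpson <- function(y, h) {
  N <- length(y) - 1
  if (N < 2) stop("Simpson quadrature needs at least 2 intervals",
                  call. = FALSE)
  if (N %% 2 == 0) {
    idx <- seq(1, N + 1)
    w <- rep(2, N + 1); w[seq(2, N, by = 2)] <- 4; w[c(1, N + 1)] <- 1
    return(h / 3 * sum(w * y))
  }
  if (N == 3) return(3 * h / 8 * (y[1] + 3 * y[2] + 3 * y[3] + y[4]))
  head_val <- simpson(y[1:(N - 2)], h)        # N-3 intervals, even
  tail_val <- 3 * h / 8 * (y[N - 2] + 3 * y[N - 1] + 3 * y[N] + y[N + 1])
  head_val + tail_val
}

# running (cumulative) action by trapezoid; used for family surfaces where a
# value is needed at every node
cumulative_action <- function(chain, traj) {
  L <- lagrangian_values(chain, traj)
  h <- traj$h
  c(0, cumsum((L[-length(L)] + L[-1]) / 2 * h))
}

#' Euler-Lagrange residual of a trajectory
#'
#' Max-norm of the discretized Euler-Lagrange operator
#' \eqn{M\ddot\theta + \nabla V} over interior grid nodes (second central
#' difference in time). For a trajectory produced by
#' [integrate_trajectory()] the residual vanishes at the discretization's
#' order as the step is refined; a path that is not a realized motion has a
#' large residual.
#'
#' @inheritParams action_integral
#' @return nonnegative scalar.
#' @export
el_residual <- function(chain, traj) {
  stopifnot(inherits(chain, "TorsionChain"), inherits(traj, "Trajectory"))
  q <- traj$positions
  N <- nrow(q) - 1
  if (N < 2) return(0)
  h <- traj$h
  m <- chain$inertias
  res <- 0
  for (i in 2:N) {
    acc <- (q[i + 1, ] - 2 * q[i, ] + q[i - 1, ]) / h^2
    r <- m * acc + potential_gradient(chain, q[i, ], traj$time[i])
    res <- max(res, max(abs(r)))
  }
  res
}

# ---- second variation ------------------------------------------------------

# Assemble the discretized second-variation form on [t0, T] with interior
# nodes 1..j of the trajectory grid and a (possibly shorter) final element of
# length h_last connecting node j to the pinned movable endpoint at T.
# Representation: piecewise-linear xi, exact element stiffness
# integral(m xi_dot^2) and mass-lumped (trapezoid) potential term
# integral(xi' HessV xi). Returns the dense symmetric matrix, node-major
# ordering ((node 1 angles), (node 2 angles), ...).
sv_matrix <- function(m, Hlist, h, j, h_last = h) {
  n <- length(m)
  dim_Q <- j * n
  Q <- matrix(0, dim_Q, dim_Q)
  idx <- function(i) ((i - 1) * n + 1):(i * n)
  for (i in seq_len(j)) {
    h_r <- if (i < j) h else h_last
    w <- (h + h_r) / 2
    A <- diag(m * (1 / h + 1 / h_r), n) - w * Hlist[[i + 1]]
    Q[idx(i), idx(i)] <- A
    if (i < j) {
      B <- diag(-m / h, n)
      Q[idx(i), idx(i + 1)] <- B
      Q[idx(i + 1), idx(i)] <- B
    }
  }
  Q
}

# count of negative pivots (= negative eigenvalues, Sylvester) of the block
# tridiagonal form via block LDL^T, computed without assembling the matrix
sv_neg_count <- function(m, Hlist, h, j, h_last = h, tol_zero = 0) {
  n <- length(m)
  if (n == 1) {
    mm <- m[1]
    neg <- 0L
    d_prev <- NA_real_
    for (i in seq_len(j)) {
      h_r <- if (i < j) h else h_last
      a <- mm * (1 / h + 1 / h_r) - (h + h_r) / 2 * Hlist[[i + 1]][1, 1]
      d <- if (i == 1) a else a - (mm / h)^2 / d_prev
      neg <- neg + (d < -tol_zero)
      d_prev <- d
    }
    return(neg)
  }
  D_prev <- NULL
  B <- diag(-m / h, n)
  neg <- 0L
  for (i in seq_len(j)) {
    h_r <- if (i < j) h else h_last
    w <- (h + h_r) / 2
    A <- diag(m * (1 / h + 1 / h_r), n) - w * Hlist[[i + 1]]
    D <- if (is.null(D_prev)) A else A - B %*% solve(D_prev, B)
    ev <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
    neg <- neg + sum(ev < -tol_zero)
    D_prev <- D
  }
  neg
}

# cumulative negative-pivot counts of the FULL uniform-grid form: because the
# grid is uniform, the form restricted to [t0, t_k] is the leading principal
# submatrix of the full form, so one pivot sweep yields the Morse index of
# every truncation. Element [j] is the index of the form with interior nodes
# 1..j (movable endpoint at t_{j+1}).
sv_pivot_negcum <- function(m, Hlist, h, tol_zero = 0) {
  n <- length(m)
  Nint <- length(Hlist) - 2
  negcum <- integer(Nint)
  if (n == 1) {
    mm <- m[1]
    Hv <- vapply(Hlist, function(M) M[1, 1], numeric(1))
    a <- 2 * mm / h - h * Hv[2:(Nint + 1)]
    b2 <- (mm / h)^2
    neg <- 0L
    d_prev <- NA_real_
    for (i in seq_len(Nint)) {
      d <- if (i == 1) a[1] else a[i] - b2 / d_prev
      neg <- neg + (d < -tol_zero)
      negcum[i] <- neg
      d_prev <- d
    }
    return(negcum)
  }
  B <- diag(-m / h, n)
  D_prev <- NULL
  neg <- 0L
  for (i in seq_len(Nint)) {
    A <- diag(2 * m / h, n) - h * Hlist[[i + 1]]
    D <- if (is.null(D_prev)) A else A - B %*% solve(D_prev, B)
    ev <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
    neg <- neg + sum(ev < -tol_zero)
    negcum[i] <- neg
    D_prev <- D
  }
  negcum
}

hessians_along <- function(chain, traj) {
  lapply(seq_along(traj$time), function(i)
    potential_hessian(chain, traj$positions[i, ], traj$time[i]))
}

check_stationary <- function(chain, traj, stationarity_tol) {
  r <- el_residual(chain, traj)
  if (r > stationarity_tol)
    stop("trajectory is not stationary: EL residual ", signif(r, 4),
         " exceeds threshold ", stationarity_tol,
         " (the second variation presumes an Euler-Lagrange curve)",
         call. = FALSE)
  invisible(r)
}

#' Discretized second variation of the action
#'
#' For a stationary trajectory \eqn{x_0(t)}, path perturbations
#' \eqn{x_\epsilon = x_0 + \epsilon\xi} with pinned ends
#' \eqn{\xi(t_0)=\xi(t_1)=0} have second variation
#' \deqn{\frac{d^2S}{d\epsilon^2}(0)
#'   = \int_{t_0}^{t_1} \big[\dot\xi^\top M \dot\xi
#'     - \xi^\top \mathrm{Hess}\,V(x_0(t))\,\xi\big]\,dt,}
#' the multi-angle Hessian generalization of the scalar
#' \eqn{-\xi^2 V'' + m\dot\xi^2} form. This function assembles the quadratic
#' form over interior grid values of piecewise-linear \eqn{\xi}
#' (finite elements, exact element stiffness, mass-lumped potential term):
#' a symmetric block-tridiagonal matrix `Q` with
#' \eqn{\xi^\top Q \xi} equal to the integral for such \eqn{\xi}.
#'
#' Eigenvalues of `Q` are reported sorted ascending; dividing by the grid
#' step (the lumped mass) approximates the Sturm-Liouville spectrum of the
#' Jacobi operator \eqn{-M\ddot\xi - \mathrm{Hess}V\,\xi}.
#'
#' @inheritParams action_integral
#' @param stationarity_tol maximum allowed Euler-Lagrange residual; the form
#'   is only meaningful on stationary curves.
#' @return a `SecondVariationForm`: list with `Q`, sorted `eigenvalues`,
#'   `h`, `n_angles`, `n_interior`, and the source trajectory.
#' @export
second_variation_form <- function(chain, traj, stationarity_tol = 1e-3) {
  stopifnot(inherits(chain, "TorsionChain"), inherits(traj, "Trajectory"))
  check_stationary(chain, traj, stationarity_tol)
  N <- length(traj$time) - 1
  if (N < 2) stop("need at least 2 time intervals", call. = FALSE)
  Hlist <- hessians_along(chain, traj)
  Q <- sv_matrix(chain$inertias, Hlist, traj$h, N - 1)
  Q <- (Q + t(Q)) / 2
  ev <- sort(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
  structure(list(Q = Q, eigenvalues = ev, h = traj$h,
                 n_angles = chain$n_angles, n_interior = N - 1,
                 trajectory = traj),
            class = "SecondVariationForm")
}

#' @export
print.SecondVariationForm <- function(x, ...) {
  cat(sprintf("<SecondVariationForm> dim %d (h=%g); smallest eigenvalues: %s\n",
              nrow(x$Q), x$h,
              paste(signif(utils::head(x$eigenvalues, 3), 4),
                    collapse = ", ")))
  invisible(x)
}

#' Apply a second-variation form to a variation function
#'
#' @param form a `SecondVariationForm`.
#' @param xi matrix `(N+1) x n_angles` (or vector for one angle) of
#'   variation values on the trajectory grid; endpoint rows must be zero.
#' @return the quadratic form value \eqn{\xi^\top Q \xi}.
#' @export
second_variation_value <- function(form, xi) {
  stopifnot(inherits(form, "SecondVariationForm"))
  if (is.null(dim(xi))) xi <- matrix(xi, ncol = 1)
  Np1 <- form$n_interior + 2
  if (nrow(xi) != Np1 || ncol(xi) != form$n_angles)
    stop("xi must be (N+1) x n_angles = ", Np1, " x ", form$n_angles,
         call. = FALSE)
  if (any(xi[1, ] != 0) || any(xi[Np1, ] != 0))
    stop("variation function must vanish at both endpoints", call. = FALSE)
  v <- as.numeric(t(xi[2:(Np1 - 1), , drop = FALSE]))
  drop(v %*% form$Q %*% v)
}

#' Operator-normalized eigenvalues of the second variation
#'
#' @param form a `SecondVariationForm`.
#' @return eigenvalues of `Q` divided by the lumped mass weight `h`,
#'   approximating the Jacobi-operator spectrum.
#' @export
second_variation_eigenvalues <- function(form) {
  stopifnot(inherits(form, "SecondVariationForm"))
  form$eigenvalues / form$h
}

#' Conjugate points by the sliding-endpoint eigenvalue scan
#'
#' Fix the start of a stationary arc and slide the movable endpoint forward:
#' at the conjugate point the second variation of the sub-arc first loses
#' positivity -- there the arc stops being a local minimum of the action and
#' becomes a saddle. The scan tracks the negative-eigenvalue count (Morse
#' index) of the restricted form via incremental block \eqn{LDL^\top}
#' factorization and refines each index jump between grid nodes by bisection
#' on a partial final element, to a tolerance of `h/100`.
#'
#' An eigenvalue is treated as zero when its magnitude is below
#' `1e-8 * max(m)/h^2` (the stiffness scale), preventing spurious caustics
#' from round-off.
#'
#' @inheritParams second_variation_form
#' @return data.frame with columns `t_star`, `multiplicity`, `method`
#'   (zero rows when the form stays positive on the whole interval).
#' @examples
#' ch <- torsion_chain(1, 1, harmonic_spring(1, half_k = TRUE))
#' tr <- integrate_trajectory(ch, 1, 0, 0, 4, 800)
#' find_conjugate_points(ch, tr)   # t_star close to pi
#' @export
find_conjugate_points <- function(chain, traj, stationarity_tol = 1e-3) {
  stopifnot(inherits(chain, "TorsionChain"), inherits(traj, "Trajectory"))
  check_stationary(chain, traj, stationarity_tol)
  m <- chain$inertias
  h <- traj$h
  tt <- traj$time
  N <- length(tt) - 1
  Hlist <- hessians_along(chain, traj)
  tol_zero <- 1e-8 * max(m) / h^2

  out <- data.frame(t_star = numeric(0), multiplicity = integer(0),
                    method = character(0))
  # negcum[j]: Morse index of the truncation with interior nodes 1..j,
  # i.e. movable endpoint at grid index j + 2
  negcum <- sv_pivot_negcum(m, Hlist, h, tol_zero)
  prev <- 0L
  for (e in 3:(N + 1)) {
    cur <- negcum[e - 2]
    if (cur > prev) {
      # index jumped crossing endpoint T in (tt[e-1], tt[e]]: bisection on a
      # truncation with interior nodes 1..e-2 and partial last element
      lo <- tt[e - 1]; hi <- tt[e]
      mult <- cur - prev
      ncT <- function(T)
        sv_neg_count(m, Hlist, h, e - 2, T - tt[e - 1], tol_zero)
      # at least the advertised h/100; h^2 so refinement never caps the
      # discretization's second-order convergence
      bis_tol <- min(h / 100, h^2)
      while (hi - lo > bis_tol) {
        mid <- (lo + hi) / 2
        if (ncT(mid) > prev) hi <- mid else lo <- mid
      }
      out <- rbind(out, data.frame(t_star = (lo + hi) / 2,
                                   multiplicity = mult,
                                   method = "eigenvalue_scan"))
      prev <- cur
    }
  }
  out
}

#' Conjugate points by Jacobi-field integration (independent oracle)
#'
#' Integrates the Jacobi equation
#' \eqn{M\ddot\xi = -\mathrm{Hess}\,V(x_0(t))\,\xi} with
#' \eqn{\xi(t_0) = 0,\ \dot\xi(t_0) = I} (RK4, trajectory step, Hessian
#' linearly interpolated between nodes) and reports the zeros of
#' \eqn{\det \xi(t)} on \eqn{(t_0, t_1]}. Conjugate points found this way
#' agree with the [find_conjugate_points()] eigenvalue scan; the two
#' routes are independent checks of one another.
#'
#' @inheritParams second_variation_form
#' @return data.frame with columns `t_star`, `multiplicity`, `method`.
#' @export
jacobi_conjugate_points <- function(chain, traj, stationarity_tol = 1e-3) {
  stopifnot(inherits(chain, "TorsionChain"), inherits(traj, "Trajectory"))
  check_stationary(chain, traj, stationarity_tol)
  n <- chain$n_angles
  m <- chain$inertias
  h <- traj$h
  tt <- traj$time
  N <- length(tt) - 1
  Hlist <- hessians_along(chain, traj)
  Hfun <- function(t) {
    s <- (t - tt[1]) / h
    i <- max(1, min(N, floor(s) + 1))   # element index
    w <- s - (i - 1)
    (1 - w) * Hlist[[i]] + w * Hlist[[i + 1]]
  }
  rhs <- function(t, Y, Ydot) list(Ydot, -(1 / m) * (Hfun(t) %*% Y))

  step_to <- function(t, Y, Ydot, dt) {
    k1 <- rhs(t, Y, Ydot)
    k2 <- rhs(t + dt / 2, Y + dt / 2 * k1[[1]], Ydot + dt / 2 * k1[[2]])
    k3 <- rhs(t + dt / 2, Y + dt / 2 * k2[[1]], Ydot + dt / 2 * k2[[2]])
    k4 <- rhs(t + dt, Y + dt * k3[[1]], Ydot + dt * k3[[2]])
    list(Y + dt / 6 * (k1[[1]] + 2 * k2[[1]] + 2 * k3[[1]] + k4[[1]]),
         Ydot + dt / 6 * (k1[[2]] + 2 * k2[[2]] + 2 * k3[[2]] + k4[[2]]))
  }

  Y <- matrix(0, n, n); Ydot <- diag(1, n)
  dets <- numeric(N + 1); dets[1] <- 0
  Ys <- vector("list", N + 1); Ys[[1]] <- Y
  Yds <- vector("list", N + 1); Yds[[1]] <- Ydot
  for (i in seq_len(N)) {
    st <- step_to(tt[i], Y, Ydot, h)
    Y <- st[[1]]; Ydot <- st[[2]]
    dets[i + 1] <- det(Y)
    Ys[[i + 1]] <- Y; Yds[[i + 1]] <- Ydot
  }
  det_scale <- max(abs(dets))
  if (det_scale == 0) det_scale <- 1

  out <- data.frame(t_star = numeric(0), multiplicity = integer(0),
                    method = character(0))
  for (i in 2:N) {
    d0 <- dets[i]; d1 <- dets[i + 1]
    hit <- (d0 > 0 && d1 < 0) || (d0 < 0 && d1 > 0) ||
      (abs(d1) < 1e-12 * det_scale && abs(d0) >= 1e-12 * det_scale)
    if (!hit) next
    # linear interpolation of the crossing; then rank drop at the crossing
    w <- if (d0 == d1) 0.5 else d0 / (d0 - d1)
    t_star <- tt[i] + w * h
    st <- step_to(tt[i], Ys[[i]], Yds[[i]], w * h)
    sv <- svd(st[[1]])$d
    mult <- max(1L, sum(sv < 1e-6 * max(sv, 1e-300)))
    out <- rbind(out, data.frame(t_star = t_star,
                                 multiplicity = mult,
                                 method = "jacobi_field"))
  }
  out
}
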