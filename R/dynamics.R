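#' Integrate the Euler-Lagrange equations of a torsion chain
#'
#' Realized motions are stationary points of the action, i.e. solutions of
#' \eqn{M\ddot\theta = -\nabla V(\theta, t)}. The default integrator is
#' velocity Verlet (symplectic, order 2), which keeps the energy error of
#' conservative systems bounded without secular drift -- important because
#' conjugate-point and caustic timings depend on phase accuracy. For
#' time-dependent schedules a classic fixed-step RK4 is available and is the
#' automatic choice when the potential carries a schedule.
#'
#' The time grid is uniform (no adaptive stepping) so that trajectory grids
#' align across a family and with the second-variation discretization.
#'
#' @param chain a [torsion_chain()].
#' @param q0,v0 initial angles and angle rates (length `n_angles`; scalars
#'   are broadcast).
#' @param t0,t1 start and end times, `t1 > t0`.
#' @param n_steps number of steps (at least 8); the grid has `n_steps + 1`
#'   nodes.
#' @param method `"verlet"` or `"rk4"`; default picks Verlet for
#'   time-independent potentials and RK4 otherwise.
#' @return a `Trajectory`: list with `time` (length `n_steps+1`), `positions`
#'   and `velocities` (`(n_steps+1) x n_angles` matrices), `h`, `method`, and
#'   the `chain`.
#' @examples
#' ch <- torsion_chain(1, 1, harmonic_spring(1, half_k = TRUE))
#' tr <- integrate_trajectory(ch, q0 = 1, v0 = 0, t0 = 0, t1 = 2 * pi,
#'                            n_steps = 2000)
#' tr$positions[nrow(tr$positions), ]  # back near 1 after one period
#' @export
integrate_trajectory <- function(chain, q0, v0, t0, t1, n_steps,
                                 method = NULL) {
  stopifnot(inherits(chain, "TorsionChain"))
  if (!(is.numeric(t0) && is.numeric(t1) && t1 > t0))
    stop("need t1 > t0", call. = FALSE)
  if (!is.numeric(n_steps) || n_steps < 8)
    stop("n_steps must be at least 8", call. = FALSE)
  n_steps <- as.integer(n_steps)
  n <- chain$n_angles
  if (length(q0) == 1) q0 <- rep(q0, n)
  if (length(v0) == 1) v0 <- rep(v0, n)
  check_angles(chain, q0); check_angles(chain, v0)
  if (is.null(method))
    method <- if (is_time_dependent(chain$potential)) "rk4" else "verlet"
  method <- match.arg(method, c("verlet", "rk4"))

  h <- (t1 - t0) / n_steps
  tt <- t0 + h * (0:n_steps)
  pos <- matrix(0, n_steps + 1, n)
  vel <- matrix(0, n_steps + 1, n)
  pos[1, ] <- q0; vel[1, ] <- v0
  minv <- 1 / chain$inertias
  accel <- function(q, t) -minv * potential_gradient(chain, q, t)

  q <- q0; v <- v0
  if (method == "verlet") {
    a <- accel(q, tt[1])
    for (i in seq_len(n_steps)) {
      q <- q + h * v + 0.5 * h^2 * a
      a_new <- accel(q, tt[i + 1])
      v <- v + 0.5 * h * (a + a_new)
      a <- a_new
      if (any(!is.finite(q)) || any(!is.finite(v)))
        stop("integration blew up (non-finite state) at t = ",
             signif(tt[i + 1], 6), call. = FALSE)
      pos[i + 1, ] <- q; vel[i + 1, ] <- v
    }
  } else {
    for (i in seq_len(n_steps)) {
      t <- tt[i]
      k1q <- v;               k1v <- accel(q, t)
      k2q <- v + 0.5 * h * k1v; k2v <- accel(q + 0.5 * h * k1q, t + 0.5 * h)
      k3q <- v + 0.5 * h * k2v; k3v <- accel(q + 0.5 * h * k2q, t + 0.5 * h)
      k4q <- v + h * k3v;       k4v <- accel(q + h * k3q, t + h)
      q <- q + h / 6 * (k1q + 2 * k2q + 2 * k3q + k4q)
      v <- v + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
      if (any(!is.finite(q)) || any(!is.finite(v)))
        stop("integration blew up (non-finite state) at t = ",
             signif(tt[i + 1], 6), call. = FALSE)
      pos[i + 1, ] <- q; vel[i + 1, ] <- v
    }
  }
  new_trajectory(tt, pos, vel, chain, method)
}

new_trajectory <- function(time, positions, velocities, chain, method) {
  h <- diff(time)
  # uniformity to relative tolerance 1e-12, plus the ulp floor of the
  # absolute times (long spans accumulate representation noise ~ eps * t)
  tol_h <- 1e-12 * max(abs(h)) +
    100 * .Machine$double.eps * max(abs(time))
  if (any(h <= 0) || (max(h) - min(h)) > tol_h)
    stop("trajectory time grid must be strictly increasing and uniform",
         call. = FALSE)
  if (!all(dim(positions) == c(length(time), chain$n_angles)) ||
      !all(dim(velocities) == dim(positions)))
    stop("positions/velocities shapes must be (N+1, n_angles)",
         call. = FALSE)
  structure(list(time = time, positions = positions,
                 velocities = velocities, h = h[1], method = method,
                 chain = chain),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory> %d angle(s), t in [%g, %g], %d nodes (h=%g, %s)\n",
              ncol(x$positions), x$time[1], x$time[length(x$time)],
              length(x$time), x$h, x$method))
  invisible(x)
}

#' Total energy along a trajectory
#'
#' @param traj a `Trajectory`.
#' @return numeric vector of `T + V` at each grid node.
#' @export
trajectory_energy <- function(traj) {
  stopifnot(inherits(traj, "Trajectory"))
  ch <- traj$chain
  vapply(seq_along(traj$time), function(i) {
    kinetic_energy(ch, traj$velocities[i, ]) +
      evaluate_potential(ch, traj$positions[i, ], traj$time[i])
  }, numeric(1))
}

#' Shoot a one-parameter family of trajectories
#'
#' All members start along a curve of initial states parameterized by a
#' scalar `u` and share one time grid; the family is the raw material for
#' the family action surface and for envelope/caustic detection.
#'
#' @param chain a [torsion_chain()].
#' @param initial_curve function of `u` returning `list(q0 = , v0 = )`.
#' @param u_grid numeric vector of at least 3 parameter values (uniform
#'   spacing recommended; required by the surface derivative stencils).
#' @param t0,t1,n_steps,method as in [integrate_trajectory()].
#' @return a `TrajectoryFamily`: list with `u`, `trajectories` (one
#'   `Trajectory` per `u`), `time`, `chain`, `initial_curve`.
#' @examples
#' ch <- torsion_chain(1, 1, harmonic_spring(1, half_k = TRUE))
#' fam <- shoot_family(ch, function(u) list(q0 = 1, v0 = u),
#'                     u_grid = seq(-2, 2, length.out = 9),
#'                     t0 = 0, t1 = 4, n_steps = 400)
#' @export
shoot_family <- function(chain, initial_curve, u_grid, t0, t1, n_steps,
                         method = NULL) {
  stopifnot(inherits(chain, "TorsionChain"), is.function(initial_curve))
  if (!is.numeric(u_grid) || length(u_grid) < 3)
    stop("u_grid needs at least 3 values (got ", length(u_grid), ")",
         call. = FALSE)
  trajs <- vector("list", length(u_grid))
  for (i in seq_along(u_grid)) {
    ic <- initial_curve(u_grid[i])
    if (!is.list(ic) || is.null(ic$q0) || is.null(ic$v0))
      stop("initial_curve(u) must return list(q0 = , v0 = )", call. = FALSE)
    trajs[[i]] <- tryCatch(
      integrate_trajectory(chain, ic$q0, ic$v0, t0, t1, n_steps, method),
      error = function(e)
        stop("family member u = ", signif(u_grid[i], 6), " failed: ",
             conditionMessage(e), call. = FALSE))
  }
  structure(list(u = u_grid, trajectories = trajs,
                 time = trajs[[1]]$time, chain = chain,
                 initial_curve = initial_curve),
            class = "TrajectoryFamily")
}

#' @export
print.TrajectoryFamily <- function(x, ...) {
  cat(sprintf("<TrajectoryFamily> %d members, u in [%g, %g]\n",
              length(x$u), min(x$u), max(x$u)))
  print(x$trajectories[[1]])
  invisible(x)
}

#' Terminal positions of a family
#'
#' @param family a `TrajectoryFamily`.
#' @return array `(n_u, n_nodes, n_angles)` of positions.
#' @export
family_positions <- function(family) {
  stopifnot(inherits(family, "TrajectoryFamily"))
  n_u <- length(family$u)
  nt <- length(family$time)
  na <- family$chain$n_angles
  arr <- array(0, c(n_u, nt, na))
  for (i in seq_len(n_u)) arr[i, , ] <- family$trajectories[[i]]$positions
  arr
}

#' Trajectory file I/O
#'
#' Trajectories are stored as CSV with mandatory header
#' `t, theta_0..theta_{n-1}, omega_0..omega_{n-1}` plus a JSON metadata
#' sidecar recording the integrator, step, and a content hash of the chain
#' configuration.
#'
#' @param traj a `Trajectory`.
#' @param csv_path path of the CSV file.
#' @param meta_path path of the JSON sidecar; default `csv_path` with the
#'   extension replaced by `.json`.
#' @param chain chain to attach on read (the sidecar stores only a summary).
#' @return `write_trajectory()` returns the paths invisibly;
#'   `read_trajectory()` a `Trajectory`.
#' @export
write_trajectory <- function(traj, csv_path, meta_path = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  n <- ncol(traj$positions)
  df <- data.frame(t = traj$time)
  for (j in seq_len(n)) df[[paste0("theta_", j - 1)]] <- traj$positions[, j]
  for (j in seq_len(n)) df[[paste0("omega_", j - 1)]] <- traj$velocities[, j]
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (is.null(meta_path)) meta_path <- sub("\\.[^.]*$", ".json", csv_path)
  meta <- list(format = "causticfold-trajectory-v1",
               integrator = traj$method, step = traj$h,
               n_angles = n, n_nodes = length(traj$time),
               chain_hash = chain_hash(traj$chain))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, meta = meta_path))
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(csv_path, chain, meta_path = NULL) {
  stopifnot(inherits(chain, "TorsionChain"))
  df <- utils::read.csv(csv_path)
  n <- chain$n_angles
  th_cols <- paste0("theta_", seq_len(n) - 1)
  om_cols <- paste0("omega_", seq_len(n) - 1)
  n_theta <- sum(grepl("^theta_", names(df)))
  if (!all(c("t", th_cols, om_cols) %in% names(df)) || n_theta != n)
    stop("trajectory CSV columns do not match a ", n,
         "-angle chain (found ", n_theta, " angle column(s))",
         call. = FALSE)
  method <- "unknown"
  if (is.null(meta_path)) meta_path <- sub("\\.[^.]*$", ".json", csv_path)
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$integrator)) method <- meta$integrator
  }
  new_trajectory(df$t,
                 as.matrix(df[, th_cols, drop = FALSE]),
                 as.matrix(df[, om_cols, drop = FALSE]),
                 chain, method)
}

# small FNV-1a hash over a canonical JSON rendering; stdlib-only provenance
# stamp, not cryptographic
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte touches only the low 8 bits
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    # 32-bit multiply by 16777619 without overflow: split into 16-bit halves
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

strip_functions <- function(x) {
  if (is.function(x)) return("<function>")
  if (is.list(x)) return(lapply(x, strip_functions))
  x
}

chain_hash <- function(chain) {
  desc <- list(n_angles = chain$n_angles, inertias = chain$inertias,
               kind = chain$potential$kind,
               params = strip_functions(chain$potential$params))
  fnv1a(jsonlite::toJSON(desc, auto_unbox = TRUE, digits = 12,
                         force = TRUE))
}
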