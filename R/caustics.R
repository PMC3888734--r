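#' Family action surface S(u, x)
#'
#' For a one-parameter family of stationary trajectories, the action from
#' the initial curve to the point reached at time t is a function
#' \eqn{S(u, x)} of the family parameter u and the terminal point x. Arcs
#' realizing a minimum to a given x solve \eqn{\partial S/\partial u = 0};
#' where additionally \eqn{\partial^2 S/\partial u^2 = 0} the point lies on
#' a caustic. This function tabulates the running action of every member at
#' every grid time (trapezoid accumulation) together with centered-difference
#' u-derivatives.
#'
#' @param family a `TrajectoryFamily` from [shoot_family()] with at least 5
#'   members (the derivative stencils need interior points).
#' @param chain the [torsion_chain()] of the family.
#' @param stationarity_tol maximum allowed Euler-Lagrange residual of the
#'   members.
#' @return a `FamilyActionSurface`: list with `u`, `axis = "time"`, `t`,
#'   `S` (`n_u x n_t`), `dSdu`, `d2Sdu2` (same shape, `NA` at boundary u),
#'   `positions` (terminal-position array) and `chain`.
#' @export
family_action_surface <- function(family, chain,
                                  stationarity_tol = 1e-3) {
  stopifnot(inherits(family, "TrajectoryFamily"),
            inherits(chain, "TorsionChain"))
  if (length(family$u) < 5)
    stop("need at least 5 u-samples for derivative stencils (got ",
         length(family$u), ")", call. = FALSE)
  du <- diff(family$u)
  if (any(du <= 0) || (max(du) - min(du)) > 1e-9 * max(abs(du)))
    stop("u grid must be strictly increasing and uniform", call. = FALSE)
  for (i in seq_along(family$u))
    check_stationary(chain, family$trajectories[[i]], stationarity_tol)
  S <- t(vapply(family$trajectories, function(tr)
    cumulative_action(chain, tr), numeric(length(family$time))))
  d <- u_derivatives(S, du[1])
  structure(list(u = family$u, axis = "time", t = family$time,
                 S = S, dSdu = d$first, d2Sdu2 = d$second,
                 positions = family_positions(family),
                 controls = NULL, chain = chain, family = family),
            class = "FamilyActionSurface")
}

u_derivatives <- function(S, du) {
  n_u <- nrow(S)
  first <- matrix(NA_real_, n_u, ncol(S))
  second <- matrix(NA_real_, n_u, ncol(S))
  ii <- 2:(n_u - 1)
  first[ii, ] <- (S[ii + 1, , drop = FALSE] - S[ii - 1, , drop = FALSE]) /
    (2 * du)
  second[ii, ] <- (S[ii + 1, , drop = FALSE] - 2 * S[ii, , drop = FALSE] +
                     S[ii - 1, , drop = FALSE]) / du^2
  list(first = first, second = second)
}

#' Analytic family action surface on a control grid
#'
#' Tabulates a closed-form family action \eqn{S(u; c_1, ..., c_d)} on a
#' tensor grid of controls, in the same container that
#' [family_action_surface()] produces for trajectory families, so that
#' [detect_caustic()] applies to both.
#'
#' @param S_fun function `(u, control-row)` returning the action; vectorized
#'   over `u`.
#' @param u_grid uniform increasing grid of the state parameter (>= 5
#'   values).
#' @param controls data.frame of control coordinates, one row per surface
#'   column (for grids, build with `expand.grid`; the *last* column must
#'   vary fastest, as `expand.grid` does for its first variable -- pass the
#'   scan coordinate first to `expand.grid`).
#' @return a `FamilyActionSurface` with `axis = "control"`.
#' @export
analytic_action_surface <- function(S_fun, u_grid, controls) {
  stopifnot(is.function(S_fun), is.data.frame(controls),
            length(u_grid) >= 5)
  du <- diff(u_grid)
  if (any(du <= 0) || (max(du) - min(du)) > 1e-9 * max(abs(du)))
    stop("u grid must be strictly increasing and uniform", call. = FALSE)
  S <- matrix(0, length(u_grid), nrow(controls))
  for (j in seq_len(nrow(controls)))
    S[, j] <- S_fun(u_grid, as.numeric(controls[j, ]))
  d <- u_derivatives(S, du[1])
  structure(list(u = u_grid, axis = "control", t = NULL,
                 S = S, dSdu = d$first, d2Sdu2 = d$second,
                 positions = NULL, controls = controls, chain = NULL,
                 family = NULL),
            class = "FamilyActionSurface")
}

#' @export
print.FamilyActionSurface <- function(x, ...) {
  cat(sprintf("<FamilyActionSurface> %d u-samples x %d %s columns\n",
              nrow(x$S), ncol(x$S),
              if (x$axis == "time") "time" else "control"))
  invisible(x)
}

# local quadratic fit of S_u(u) on the 5 grid points nearest u0; returns the
# discriminant of the fitted quadratic (> 0: two nearby roots, < 0: none)
# and its vertex (the root location at the fold)
quad_fit_su <- function(u, su, u0) {
  ok <- which(!is.na(su))
  if (length(ok) < 5) return(NULL)
  sel <- ok[order(abs(u[ok] - u0))][1:5]
  x <- u[sel] - u0
  fit <- stats::lsfit(cbind(x, x^2), su[sel])
  q0 <- fit$coefficients[1]; q1 <- fit$coefficients[2]
  q2 <- fit$coefficients[3]
  if (abs(q2) < 1e-300) return(NULL)
  list(disc = unname(q1^2 - 4 * q0 * q2),
       vertex = unname(u0 - q1 / (2 * q2)))
}

# stationary points in u of one surface column: linear-interpolated sign
# changes of dS/du, with the interpolated d2S/du2 at each root
column_roots <- function(u, su, suu) {
  ok <- which(!is.na(su))
  res <- list(u = numeric(0), suu = numeric(0))
  for (k in seq_len(length(ok) - 1)) {
    i <- ok[k]; j <- ok[k + 1]
    if (is.na(su[i]) || is.na(su[j])) next
    if (su[i] == 0) {
      res$u <- c(res$u, u[i]); res$suu <- c(res$suu, suu[i])
    } else if (su[i] * su[j] < 0) {
      w <- su[i] / (su[i] - su[j])
      res$u <- c(res$u, u[i] + w * (u[j] - u[i]))
      res$suu <- c(res$suu, (1 - w) * suu[i] + w * suu[j])
    }
  }
  res
}

#' Detect caustics on a family action surface
#'
#' A caustic point satisfies both \eqn{\partial S/\partial u = 0} and
#' \eqn{\partial^2 S/\partial u^2 = 0}. Scanning along the surface's second
#' axis (time, or the last control coordinate), the detector reports
#' \itemize{
#'   \item branch events: a stationary point whose curvature
#'     \eqn{S_{uu}} changes sign between adjacent columns (location
#'     interpolated to the zero of \eqn{S_{uu}}),
#'   \item fold events: the count of stationary points changes between
#'     adjacent columns (two roots merge and vanish; located at the
#'     midpoint, honest to grid resolution),
#'   \item degenerate columns: \eqn{S_u} and \eqn{S_{uu}} below tolerance
#'     for every u (the whole column is critical -- the focus situation).
#' }
#' A caustic whose spatial extent collapses below two grid cells is tagged
#' `"focus"`, otherwise `"fold"`.
#'
#' @param surface a `FamilyActionSurface`.
#' @param tol_first tolerance on \eqn{|S_u|}; default
#'   `1e-6 * diff(range(S))` per unit u.
#' @param tol_second tolerance on \eqn{|S_{uu}|}; default
#'   `1e-4 * median(|S_uu|)`.
#' @return a `CausticSet`: data.frame with columns `u`, `axis_value` (time
#'   or last control coordinate), `x` (terminal position / control
#'   location), `Su`, `Suu`, `event`, plus attribute `type`
#'   (`"focus"`, `"fold"` or `"none"`).
#' @export
detect_caustic <- function(surface, tol_first = NULL, tol_second = NULL) {
  stopifnot(inherits(surface, "FamilyActionSurface"))
  S <- surface$S
  empty_set <- function() {
    res <- data.frame(u = numeric(0), axis_value = numeric(0),
                      Su = numeric(0), Suu = numeric(0),
                      event = character(0))
    attr(res, "type") <- "none"
    class(res) <- c("CausticSet", class(res))
    res
  }
  # a surface with no u-dependence at all is a degenerate family (identical
  # or parallel members): stationarity in u is vacuous, no caustic
  u_variation <- max(apply(S, 2, function(col) diff(range(col))))
  if (u_variation <= 1e-10 * max(1, max(abs(S)))) return(empty_set())
  if (is.null(tol_first)) tol_first <- 1e-6 * diff(range(S))
  abs_suu <- abs(surface$d2Sdu2[!is.na(surface$d2Sdu2)])
  if (is.null(tol_second) && any(abs_suu > 0))
    tol_second <- 1e-4 * stats::median(abs_suu[abs_suu > 0])
  if (is.null(tol_second)) tol_second <- 1e-12
  u <- surface$u

  if (surface$axis == "time") {
    # the start column is trivially degenerate (S identically 0 at t0)
    slices <- list(2:ncol(S))
    axis_vals <- list(surface$t[-1])
  } else {
    # group columns by all controls except the last; scan along the last
    ctr <- surface$controls
    d <- ncol(ctr)
    key <- if (d == 1) rep("", nrow(ctr)) else
      apply(ctr[, -d, drop = FALSE], 1, paste, collapse = "|")
    slices <- split(seq_len(nrow(ctr)), key)
    axis_vals <- lapply(slices, function(ix) ctr[ix, d])
  }

  pts <- list()
  add_pt <- function(u_val, axis_val, col_idx, su, suu, event) {
    x <- caustic_location(surface, u_val, col_idx)
    # carry the sub-cell refinement of the scan coordinate into x
    if (surface$axis == "control") x[length(x)] <- axis_val
    pts[[length(pts) + 1]] <<- data.frame(
      u = u_val, axis_value = axis_val,
      x = I(list(x)), Su = su, Suu = suu, event = event)
  }

  for (sl in seq_along(slices)) {
    cols <- slices[[sl]]
    av <- axis_vals[[sl]]
    ord <- order(av)
    cols <- cols[ord]; av <- av[ord]
    prev_roots <- NULL
    for (kk in seq_along(cols)) {
      j <- cols[kk]
      su <- surface$dSdu[, j]; suu <- surface$d2Sdu2[, j]
      ii <- !is.na(su)
      if (all(abs(su[ii]) < tol_first) && all(abs(suu[ii]) < tol_second)) {
        # fully degenerate column: S independent of u to tolerance
        add_pt(NA_real_, av[kk], j, max(abs(su[ii])), max(abs(suu[ii])),
               "degenerate_column")
        prev_roots <- NULL
        next
      }
      roots <- column_roots(u, su, suu)
      # sub-tolerance curvature right at a root
      for (r in seq_along(roots$u))
        if (abs(roots$suu[r]) < tol_second)
          add_pt(roots$u[r], av[kk], j, 0, roots$suu[r], "flat_root")
      if (!is.null(prev_roots) && kk > 1) {
        jp <- cols[kk - 1]
        fold_this_transition <- FALSE
        # fold event: interior root count changed (roots drifting out
        # through the u-grid boundary are not folds)
        if (length(roots$u) != length(prev_roots$u)) {
          lost <- if (length(roots$u) < length(prev_roots$u))
            prev_roots else roots
          keep <- if (length(roots$u) < length(prev_roots$u))
            roots else prev_roots
          du_cell <- u[2] - u[1]
          interior_ok <- lost$u > u[1] + 2 * du_cell &
            lost$u < u[length(u)] - 2 * du_cell
          cand <- lost$u[interior_ok]
          # the merging pair is the lost roots away from surviving ones
          if (length(keep$u) > 0 && length(cand) > 0)
            cand <- cand[vapply(cand, function(z)
              min(abs(keep$u - z)), numeric(1)) > 2 * du_cell]
          if (length(cand) > 0) {
            # refine by local quadratic fit of S_u around the merging pair:
            # the fit's discriminant crosses zero at the fold
            u0 <- mean(cand)
            qa <- quad_fit_su(u, surface$dSdu[, jp], u0)
            qb <- quad_fit_su(u, surface$dSdu[, j], u0)
            axv <- (av[kk - 1] + av[kk]) / 2
            u_star <- u0
            if (!is.null(qa) && !is.null(qb) &&
                is.finite(qa$disc) && is.finite(qb$disc) &&
                qa$disc != qb$disc) {
              w <- qa$disc / (qa$disc - qb$disc)
              if (is.finite(w) && w >= 0 && w <= 1.5) {
                axv <- av[kk - 1] + w * (av[kk] - av[kk - 1])
                u_star <- (1 - w) * qa$vertex + w * qb$vertex
              }
            }
            add_pt(u_star, axv, j, 0, 0, "root_count_change")
            fold_this_transition <- TRUE
          }
        }
        # branch event: matched root with S_uu sign change (skipped when a
        # fold was already localized on this transition -- the nearest-root
        # matching jumps branches at a fold and would duplicate it poorly)
        if (!fold_this_transition) {
          for (r in seq_along(roots$u)) {
            if (length(prev_roots$u) == 0) break
            near <- which.min(abs(prev_roots$u - roots$u[r]))
            s0 <- prev_roots$suu[near]; s1 <- roots$suu[r]
            if (is.finite(s0) && is.finite(s1) && s0 * s1 < 0) {
              w <- s0 / (s0 - s1)
              add_pt((1 - w) * prev_roots$u[near] + w * roots$u[r],
                     (1 - w) * av[kk - 1] + w * av[kk],
                     if (w < 0.5) jp else j, 0, 0, "curvature_flip")
            }
          }
        }
      }
      prev_roots <- roots
    }
  }

  if (length(pts) == 0) return(empty_set())
  res <- do.call(rbind, pts)
  attr(res, "type") <- classify_caustic_extent(surface, res)
  class(res) <- c("CausticSet", class(res))
  res
}

# spatial location x of a caustic candidate: terminal positions for
# trajectory surfaces (interpolated in u), control coordinates otherwise
caustic_location <- function(surface, u_val, col_idx) {
  if (surface$axis == "control")
    return(as.numeric(surface$controls[col_idx, ]))
  P <- surface$positions[, col_idx, , drop = FALSE]
  dim(P) <- dim(surface$positions)[c(1, 3)]
  if (is.na(u_val)) return(colMeans(P))
  apply(P, 2, function(col) stats::approx(surface$u, col, u_val,
                                          rule = 2)$y)
}

classify_caustic_extent <- function(surface, res) {
  xs <- do.call(rbind, res$x)
  if (is.null(xs) || nrow(xs) < 1) return("none")
  if (surface$axis == "time") {
    # cell size: typical terminal-position change across one u step
    P <- surface$positions
    n_u <- dim(P)[1]
    cell <- stats::median(abs(P[-1, , , drop = FALSE] -
                                P[-n_u, , , drop = FALSE]))
    extent <- max(apply(xs, 2, function(c) diff(range(c))))
    if (extent < 2 * max(cell, 1e-12)) "focus" else "fold"
  } else {
    cell <- max(vapply(seq_len(ncol(surface$controls)), function(k) {
      vv <- sort(unique(surface$controls[, k]))
      if (length(vv) > 1) min(diff(vv)) else 0
    }, numeric(1)))
    extent <- max(apply(xs, 2, function(c) diff(range(c))))
    if (extent < 2 * max(cell, 1e-12)) "focus" else "fold"
  }
}

#' Geometric envelope of a trajectory family
#'
#' The envelope is the curve (or point) to which all member trajectories are
#' tangent: in the limit, where neighboring members intersect. For a
#' one-angle chain these are the zeros in u of \eqn{\partial x/\partial u};
#' for a two-angle chain, zeros of the tangency condition
#' \eqn{\partial x/\partial u \parallel \partial x/\partial t}
#' (vanishing cross product). The envelope coincides with the caustic of the
#' family action surface.
#'
#' @param family a `TrajectoryFamily` with at least 5 members.
#' @return data.frame with columns `t`, `u`, and `x_1` (and `x_2`) giving
#'   envelope samples; zero rows when the family has no envelope.
#' @export
envelope_points <- function(family) {
  stopifnot(inherits(family, "TrajectoryFamily"))
  if (length(family$u) < 5)
    stop("need at least 5 family members", call. = FALSE)
  P <- family_positions(family)          # (n_u, n_t, n_angles)
  n_a <- dim(P)[3]
  if (n_a > 2)
    stop("envelope construction supports 1- or 2-angle chains", call. = FALSE)
  u <- family$u
  tt <- family$time
  du <- u[2] - u[1]
  ht <- tt[2] - tt[1]
  n_u <- length(u)
  ii <- 2:(n_u - 1)
  # tangency field g(u, t) on interior u rows
  G <- matrix(0, length(ii), length(tt))
  for (k in seq_along(tt)) {
    if (n_a == 1) {
      G[, k] <- (P[ii + 1, k, 1] - P[ii - 1, k, 1]) / (2 * du)
    } else {
      dxu1 <- (P[ii + 1, k, 1] - P[ii - 1, k, 1]) / (2 * du)
      dxu2 <- (P[ii + 1, k, 2] - P[ii - 1, k, 2]) / (2 * du)
      kk <- max(2, min(length(tt) - 1, k))
      dxt1 <- (P[ii, kk + 1, 1] - P[ii, kk - 1, 1]) / (2 * ht)
      dxt2 <- (P[ii, kk + 1, 2] - P[ii, kk - 1, 2]) / (2 * ht)
      G[, k] <- dxu1 * dxt2 - dxu2 * dxt1
    }
  }
  out <- data.frame()
  add_env <- function(t_star, u_star, k_near) {
    row <- data.frame(t = t_star, u = u_star)
    for (a in seq_len(n_a))
      row[[paste0("x_", a)]] <-
        stats::approx(u, P[, k_near, a], u_star, rule = 2)$y
    out <<- rbind(out, row)
  }
  # sign changes along u at fixed t (fold-type envelopes)
  for (k in seq_along(tt)) {
    g <- G[, k]
    for (r in seq_len(length(g) - 1)) {
      if (g[r] * g[r + 1] < 0) {
        w <- g[r] / (g[r] - g[r + 1])
        add_env(tt[k], u[ii[r]] + w * du, k)
      }
    }
  }
  # sign changes along t at fixed u (focus-type: the whole family pinches)
  for (r in seq_along(ii)) {
    g <- G[r, ]
    for (k in seq(2, length(tt) - 1)) {
      if (g[k] * g[k + 1] < 0) {
        w <- g[k] / (g[k] - g[k + 1])
        add_env(tt[k] + w * ht, u[ii[r]], if (w < 0.5) k else k + 1)
      }
    }
  }
  out
}

#' Scan a higher-dimensional action field for vanishing Hessian determinant
#'
#' In more than one scan parameter the caustic condition
#' \eqn{\partial^2 S/\partial u^2 = 0} becomes the vanishing of the
#' determinant of the Hessian of the action field. The scan evaluates a
#' centered-difference Hessian on a tensor grid and reports the interior
#' points where \eqn{|\det H|} falls below `tol` times the median
#' \eqn{|\det H|} over the region.
#'
#' @param action_field function mapping a numeric point (length d >= 1) to a
#'   scalar action value.
#' @param region list of coordinate grids, one increasing numeric vector per
#'   dimension, each of length >= 5.
#' @param tol relative determinant tolerance (default `1e-3`).
#' @return data.frame of flagged points with their `det_H`; attribute
#'   `"median_abs_det"` records the scale used.
#' @export
hessian_determinant_scan <- function(action_field, region, tol = 1e-3) {
  stopifnot(is.function(action_field), is.list(region))
  d <- length(region)
  if (d < 1) stop("region must have dimension >= 1", call. = FALSE)
  for (g in region)
    if (length(g) < 5)
      stop("each region grid needs at least 5 points for the Hessian ",
           "stencil", call. = FALSE)
  hs <- vapply(region, function(g) g[2] - g[1], numeric(1))
  interior <- lapply(region, function(g) g[2:(length(g) - 1)])
  grid <- do.call(expand.grid, interior)
  names(grid) <- paste0("c", seq_len(d))
  dets <- vapply(seq_len(nrow(grid)), function(r) {
    x <- as.numeric(grid[r, ])
    H <- matrix(0, d, d)
    f0 <- action_field(x)
    for (i in seq_len(d)) {
      ei <- numeric(d); ei[i] <- hs[i]
      H[i, i] <- (action_field(x + ei) - 2 * f0 + action_field(x - ei)) /
        hs[i]^2
      if (i < d) for (j in (i + 1):d) {
        ej <- numeric(d); ej[j] <- hs[j]
        H[i, j] <- (action_field(x + ei + ej) - action_field(x + ei - ej) -
                      action_field(x - ei + ej) +
                      action_field(x - ei - ej)) / (4 * hs[i] * hs[j])
        H[j, i] <- H[i, j]
      }
    }
    det(H)
  }, numeric(1))
  scale <- stats::median(abs(dets))
  flagged <- grid[abs(dets) < tol * scale, , drop = FALSE]
  flagged$det_H <- dets[abs(dets) < tol * scale]
  attr(flagged, "median_abs_det") <- scale
  flagged
}

#' Signature check of the action just before and beyond a caustic
#'
#' Crossing a caustic, a stationary arc stops being a minimum: the second
#' variation goes from positive definite to indefinite, so the action
#' develops a saddle in the family parameter just beyond the caustic. For
#' each detected caustic this reports the inertia (positive/negative
#' curvature directions of S in u at its stationary points) a few columns
#' before and after the caustic location along the scan axis.
#'
#' @param surface the `FamilyActionSurface` the caustic was detected on;
#'   it must extend beyond the caustic along the scan axis for confirmation.
#' @param caustic a `CausticSet` from [detect_caustic()].
#' @param offset how many scan columns away from the caustic to probe
#'   (default 3).
#' @return data.frame with one row per caustic point: `axis_value`,
#'   `n_pos_before`, `n_neg_before`, `n_pos_after`, `n_neg_after`, and
#'   `status` (`"confirmed"`, `"no_flip"`, or `"unconfirmable"` when the
#'   caustic sits at the boundary of the scanned region).
#' @export
saddle_check_beyond <- function(surface, caustic, offset = 3) {
  stopifnot(inherits(surface, "FamilyActionSurface"),
            inherits(caustic, "CausticSet"))
  if (nrow(caustic) == 0)
    return(data.frame(axis_value = numeric(0),
                      n_pos_before = integer(0), n_neg_before = integer(0),
                      n_pos_after = integer(0), n_neg_after = integer(0),
                      status = character(0)))
  axis <- if (surface$axis == "time") surface$t else
    surface$controls[, ncol(surface$controls)]
  inertia_at <- function(j) {
    su <- surface$dSdu[, j]; suu <- surface$d2Sdu2[, j]
    roots <- column_roots(surface$u, su, suu)
    if (length(roots$u) == 0) return(c(pos = 0L, neg = 0L))
    c(pos = sum(roots$suu > 0), neg = sum(roots$suu < 0))
  }
  out <- data.frame()
  for (r in seq_len(nrow(caustic))) {
    av <- caustic$axis_value[r]
    j0 <- which.min(abs(axis - av))
    jb <- j0 - offset; ja <- j0 + offset
    if (jb < 1 || ja > length(axis)) {
      out <- rbind(out, data.frame(axis_value = av,
                                   n_pos_before = NA, n_neg_before = NA,
                                   n_pos_after = NA, n_neg_after = NA,
                                   status = "unconfirmable"))
      next
    }
    ib <- inertia_at(jb); ia <- inertia_at(ja)
    # confirmation: the definiteness pattern of S in u at its stationary
    # points changes across the caustic (a curvature direction flips sign)
    flipped <- (ib[["neg"]] > 0) != (ia[["neg"]] > 0) ||
      (ib[["pos"]] > 0) != (ia[["pos"]] > 0)
    out <- rbind(out, data.frame(axis_value = av,
                                 n_pos_before = ib[["pos"]],
                                 n_neg_before = ib[["neg"]],
                                 n_pos_after = ia[["pos"]],
                                 n_neg_after = ia[["neg"]],
                                 status = if (flipped) "confirmed"
                                          else "no_flip"))
  }
  out
}
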