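#' Torsional potential specifications
#'
#' A `PotentialSpec` describes the potential energy acting on each dihedral
#' angle of a chain. Built-in kinds are applied per angle and summed over the
#' chain; the `coupled` kind supplies arbitrary functions of the whole angle
#' vector for potentials with cross-terms between angles.
#'
#' Conventions in force throughout the package:
#' * the harmonic angular spring evaluates \eqn{V(\theta) = k\theta^2}; the
#'   textbook \eqn{\frac{1}{2}k\theta^2} convention is selected with
#'   `half_k = TRUE` and is never the silent default,
#' * the quartic cusp potential evaluates
#'   \eqn{V(\theta) = \frac{1}{4}\theta^4 + \frac{1}{2}a\theta^2 + b\theta}
#'   (linear control term); an alternative variant with a constant offset
#'   \eqn{+b} instead of \eqn{+b\theta} is selected with `linear = FALSE`,
#' * angles are radians on the real line (no \eqn{2\pi} wrapping),
#' * energies are in units of \eqn{k_B T} unless stated otherwise.
#'
#' An optional `time_dependence` function `g(t)` multiplies the potential,
#' `V(theta, t) = g(t) * V(theta)`.
#'
#' @param k spring coefficient (may be negative, e.g. an inverted spring).
#' @param half_k logical; if `TRUE` evaluate \eqn{\frac{1}{2}k\theta^2}.
#' @param k_plus,k_minus nonnegative one-sided stiffnesses of the asymmetric
#'   spring for \eqn{\theta \ge \theta_{ref}} and \eqn{\theta < \theta_{ref}}.
#' @param theta_ref rest angle of the asymmetric spring (radians).
#' @param a,b cusp control parameters (quadratic and linear controls).
#' @param linear logical; `TRUE` (canonical) gives the \eqn{+b\theta} linear
#'   term, `FALSE` the constant-offset \eqn{+b} variant.
#' @param time_dependence optional function `g(t)` multiplying the potential.
#' @param ... for [composite_potential()], `PotentialSpec` objects to sum.
#' @param V,dV,d2V for [custom_potential()], vectorized functions of a scalar
#'   angle giving the per-angle energy, force derivative and curvature.
#'   Missing derivatives fall back to central finite differences. For
#'   [coupled_potential()], functions of the full angle vector returning a
#'   scalar energy, gradient vector and Hessian matrix respectively.
#' @return an object of class `PotentialSpec`.
#' @examples
#' harmonic_spring(k = 2)                    # V = 2 theta^2
#' asymmetric_spring(k_plus = 1, k_minus = 4)
#' cusp_potential(a = -1, b = 0)             # double-well quartic
#' composite_potential(harmonic_spring(1), cusp_potential(1, 1))
#' @name PotentialSpec
NULL

new_potential_spec <- function(kind, params, time_dependence = NULL) {
  if (!is.null(time_dependence) && !is.function(time_dependence))
    stop("time_dependence must be a function g(t) or NULL", call. = FALSE)
  structure(list(kind = kind, params = params,
                 time_dependence = time_dependence),
            class = "PotentialSpec")
}

#' @rdname PotentialSpec
#' @export
harmonic_spring <- function(k, half_k = FALSE, time_dependence = NULL) {
  stopifnot(is.numeric(k), length(k) == 1, is.finite(k))
  new_potential_spec("harmonic_spring",
                     list(k = k, half_k = isTRUE(half_k)), time_dependence)
}

#' @rdname PotentialSpec
#' @export
asymmetric_spring <- function(k_plus, k_minus, theta_ref = 0,
                              time_dependence = NULL) {
  for (nm in c("k_plus", "k_minus")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop("asymmetric_spring: '", nm, "' must be a nonnegative number",
           call. = FALSE)
  }
  stopifnot(is.numeric(theta_ref), length(theta_ref) == 1)
  new_potential_spec("asymmetric_spring",
                     list(k_plus = k_plus, k_minus = k_minus,
                          theta_ref = theta_ref), time_dependence)
}

#' @rdname PotentialSpec
#' @export
cusp_potential <- function(a, b, linear = TRUE, time_dependence = NULL) {
  stopifnot(is.numeric(a), length(a) == 1, is.numeric(b), length(b) == 1)
  new_potential_spec("cusp",
                     list(a = a, b = b, linear = isTRUE(linear)),
                     time_dependence)
}

#' @rdname PotentialSpec
#' @export
composite_potential <- function(..., time_dependence = NULL) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "PotentialSpec"))
    parts <- parts[[1]]
  if (length(parts) == 0)
    stop("composite_potential needs at least one component", call. = FALSE)
  ok <- vapply(parts, inherits, logical(1), what = "PotentialSpec")
  if (!all(ok))
    stop("all components of a composite potential must be PotentialSpec",
         call. = FALSE)
  new_potential_spec("composite", list(parts = parts), time_dependence)
}

#' @rdname PotentialSpec
#' @export
custom_potential <- function(V, dV = NULL, d2V = NULL,
                             time_dependence = NULL) {
  stopifnot(is.function(V))
  new_potential_spec("custom", list(V = V, dV = dV, d2V = d2V),
                     time_dependence)
}

#' @rdname PotentialSpec
#' @export
coupled_potential <- function(V, dV = NULL, d2V = NULL,
                              time_dependence = NULL) {
  stopifnot(is.function(V))
  new_potential_spec("coupled", list(V = V, dV = dV, d2V = d2V),
                     time_dependence)
}

potential_kinds <- function() {
  c("harmonic_spring", "asymmetric_spring", "cusp", "composite", "custom",
    "coupled")
}

#' @export
print.PotentialSpec <- function(x, ...) {
  cat("<PotentialSpec>", x$kind, "\n")
  if (x$kind == "composite") {
    cat("  components:",
        paste(vapply(x$params$parts, `[[`, "", "kind"), collapse = " + "),
        "\n")
  } else if (x$kind %in% c("harmonic_spring", "asymmetric_spring", "cusp")) {
    p <- x$params
    cat("  ", paste(names(p), unlist(p), sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$time_dependence)) cat("  time-dependent schedule g(t)\n")
  invisible(x)
}

td_factor <- function(spec, t) {
  if (is.null(spec$time_dependence)) 1 else spec$time_dependence(t)
}

is_time_dependent <- function(spec) {
  if (!inherits(spec, "PotentialSpec")) return(FALSE)
  if (!is.null(spec$time_dependence)) return(TRUE)
  if (spec$kind == "composite")
    return(any(vapply(spec$params$parts, is_time_dependent, logical(1))))
  FALSE
}

# step used by finite-difference fallbacks for custom potentials
.fd_h <- 1e-5

#' Evaluate a per-angle potential, its derivative and curvature
#'
#' These low-level evaluators are vectorized over `theta` and return the
#' per-angle contribution; chain-level sums live in
#' [evaluate_potential()] and friends. `coupled` specs are not per-angle
#' and are rejected here.
#'
#' @param spec a [PotentialSpec] object.
#' @param theta numeric vector of angles (radians).
#' @param t time at which any schedule `g(t)` is evaluated.
#' @return numeric vector, same length as `theta`.
#' @export
potential_value <- function(spec, theta, t = 0) {
  stopifnot(inherits(spec, "PotentialSpec"))
  p <- spec$params
  v <- switch(spec$kind,
    harmonic_spring = (if (p$half_k) 0.5 else 1) * p$k * theta^2,
    asymmetric_spring = {
      d <- theta - p$theta_ref
      ifelse(d >= 0, p$k_plus, p$k_minus) * d^2
    },
    cusp = 0.25 * theta^4 + 0.5 * p$a * theta^2 +
      (if (p$linear) p$b * theta else p$b),
    composite = {
      out <- 0
      for (part in p$parts) out <- out + potential_value(part, theta, t)
      out
    },
    custom = p$V(theta),
    coupled = stop("coupled potentials have no per-angle value; ",
                   "use evaluate_potential() on the chain", call. = FALSE),
    stop("unknown potential kind: ", spec$kind, call. = FALSE)
  )
  td_factor(spec, t) * v
}

#' @rdname potential_value
#' @export
potential_deriv <- function(spec, theta, t = 0) {
  stopifnot(inherits(spec, "PotentialSpec"))
  p <- spec$params
  v <- switch(spec$kind,
    harmonic_spring = (if (p$half_k) 1 else 2) * p$k * theta,
    asymmetric_spring = {
      d <- theta - p$theta_ref
      2 * ifelse(d >= 0, p$k_plus, p$k_minus) * d
    },
    cusp = theta^3 + p$a * theta + (if (p$linear) p$b else 0),
    composite = {
      out <- 0
      for (part in p$parts) out <- out + potential_deriv(part, theta, t)
      out
    },
    custom = if (is.function(p$dV)) p$dV(theta) else
      (p$V(theta + .fd_h) - p$V(theta - .fd_h)) / (2 * .fd_h),
    coupled = stop("coupled potentials have no per-angle derivative",
                   call. = FALSE),
    stop("unknown potential kind: ", spec$kind, call. = FALSE)
  )
  td_factor(spec, t) * v
}

#' @rdname potential_value
#' @export
potential_deriv2 <- function(spec, theta, t = 0) {
  stopifnot(inherits(spec, "PotentialSpec"))
  p <- spec$params
  v <- switch(spec$kind,
    harmonic_spring = rep((if (p$half_k) 1 else 2) * p$k, length(theta)),
    asymmetric_spring = {
      # one-sided value at theta_ref itself: the k_plus branch (grid-aligned)
      d <- theta - p$theta_ref
      2 * ifelse(d >= 0, p$k_plus, p$k_minus)
    },
    cusp = 3 * theta^2 + p$a,
    composite = {
      out <- 0
      for (part in p$parts) out <- out + potential_deriv2(part, theta, t)
      out
    },
    custom = if (is.function(p$d2V)) p$d2V(theta) else
      (p$V(theta + .fd_h) - 2 * p$V(theta) + p$V(theta - .fd_h)) / .fd_h^2,
    coupled = stop("coupled potentials have no per-angle curvature",
                   call. = FALSE),
    stop("unknown potential kind: ", spec$kind, call. = FALSE)
  )
  td_factor(spec, t) * v
}

#' One-sided quadratic (asymmetric) angular spring energy
#'
#' The restoring force of a dihedral angle generally depends on the direction
#' of turning: the spring is stiffer on one side of its rest angle than the
#' other. This evaluates the C1-matched piecewise quadratic
#' \deqn{V(\theta) = k_+ (\theta-\theta_{ref})^2 \;(\theta \ge \theta_{ref}),
#'       \qquad k_- (\theta-\theta_{ref})^2 \;(\theta < \theta_{ref}).}
#' `V` and `V'` vanish at the rest angle from both sides; the curvature jumps
#' there.
#'
#' @param theta angle(s), radians; vectorized.
#' @param k_plus,k_minus nonnegative stiffnesses for the two sides.
#' @param theta_ref rest angle.
#' @return energy value(s).
#' @examples
#' asymmetric_spring_energy(1, k_plus = 1, k_minus = 4)   # 1
#' asymmetric_spring_energy(-1, k_plus = 1, k_minus = 4)  # 4
#' @export
asymmetric_spring_energy <- function(theta, k_plus, k_minus, theta_ref = 0) {
  spec <- asymmetric_spring(k_plus, k_minus, theta_ref)
  potential_value(spec, theta)
}

#' The cusp germ: quartic action with two control parameters
#'
#' The canonical degenerate critical point of the framework is the cusp
#' \deqn{S(s) = \tfrac{1}{4}s^4 + \tfrac{1}{2}a s^2 + b s,}
#' with state variable `s` and controls `(a, b)`. At `a = b = 0` the origin
#' is a degenerate critical point: value, first and second derivative all
#' vanish. Its critical points are the real roots of \eqn{s^3 + as + b}; the
#' count changes from 3 to 1 across the fold curve \eqn{4a^3 + 27b^2 = 0}.
#'
#' `cusp_action_value()`, `cusp_action_deriv()` and `cusp_action_deriv2()`
#' evaluate \eqn{S}, \eqn{S'} and \eqn{S''}; `cusp_critical_points()` returns
#' the sorted real critical points.
#'
#' @param a quadratic control parameter.
#' @param b linear control parameter.
#' @param germ a `CuspGerm` object.
#' @param s state value(s); vectorized.
#' @return `cusp_germ()` returns a `CuspGerm`; the evaluators return
#'   numeric vectors; `cusp_critical_points()` a sorted numeric vector.
#' @examples
#' g <- cusp_germ(a = -1, b = 0)
#' cusp_critical_points(g)       # -1 0 1
#' cusp_action_value(g, 1)       # -1/4
#' @export
cusp_germ <- function(a, b) {
  stopifnot(is.numeric(a), length(a) == 1, is.finite(a),
            is.numeric(b), length(b) == 1, is.finite(b))
  structure(list(a = a, b = b), class = "CuspGerm")
}

#' @rdname cusp_germ
#' @export
cusp_action_value <- function(germ, s) {
  stopifnot(inherits(germ, "CuspGerm"))
  0.25 * s^4 + 0.5 * germ$a * s^2 + germ$b * s
}

#' @rdname cusp_germ
#' @export
cusp_action_deriv <- function(germ, s) {
  stopifnot(inherits(germ, "CuspGerm"))
  s^3 + germ$a * s + germ$b
}

#' @rdname cusp_germ
#' @export
cusp_action_deriv2 <- function(germ, s) {
  stopifnot(inherits(germ, "CuspGerm"))
  3 * s^2 + germ$a
}

#' @rdname cusp_germ
#' @export
cusp_critical_points <- function(germ) {
  stopifnot(inherits(germ, "CuspGerm"))
  r <- polyroot(c(germ$b, germ$a, 0, 1))
  re <- Re(r)[abs(Im(r)) < 1e-9 * pmax(1, Mod(r))]
  sort(re)
}

#' @export
print.CuspGerm <- function(x, ...) {
  cat(sprintf("<CuspGerm> S(s) = s^4/4 + (%g/2) s^2 + (%g) s\n", x$a, x$b))
  invisible(x)
}
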