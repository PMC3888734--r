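#' Torsion-angle chains
#'
#' A `TorsionChain` is the mechanical system under study: `n_angles` dihedral
#' angles with diagonal rotational inertia and a torsional potential. Kinetic
#' energy is \eqn{T = \frac{1}{2}\sum_i I_i \dot\theta_i^2}; the inertia
#' metric is diagonal by construction (the field convention when no coupling
#' tensor is specified).
#'
#' @param n_angles positive integer, number of dihedral angles.
#' @param inertias strictly positive inertia per angle; a scalar is
#'   broadcast to all angles.
#' @param potential a [PotentialSpec].
#' @return a validated `TorsionChain`.
#' @examples
#' torsion_chain(1, 1, harmonic_spring(1))
#' torsion_chain(3, c(1, 2, 3), cusp_potential(-1, 0))
#' @export
torsion_chain <- function(n_angles, inertias, potential) {
  if (!is.numeric(n_angles) || length(n_angles) != 1 ||
      n_angles != round(n_angles) || n_angles < 1)
    stop("n_angles must be a positive integer (got ",
         deparse(n_angles), ")", call. = FALSE)
  n_angles <- as.integer(n_angles)
  if (missing(inertias) || is.null(inertias))
    stop("inertias is missing; supply a positive scalar or vector",
         call. = FALSE)
  if (!is.numeric(inertias) || any(!is.finite(inertias)))
    stop("inertias must be finite numeric", call. = FALSE)
  if (length(inertias) == 1) inertias <- rep(inertias, n_angles)
  if (length(inertias) != n_angles)
    stop("inertias has length ", length(inertias),
         " but n_angles is ", n_angles, call. = FALSE)
  if (any(inertias <= 0))
    stop("inertias must be strictly positive (offending index ",
         which(inertias <= 0)[1], ")", call. = FALSE)
  if (!inherits(potential, "PotentialSpec"))
    stop("potential must be a PotentialSpec; see harmonic_spring(), ",
         "asymmetric_spring(), cusp_potential(), composite_potential()",
         call. = FALSE)
  structure(list(n_angles = n_angles, inertias = inertias,
                 potential = potential),
            class = "TorsionChain")
}

#' @export
print.TorsionChain <- function(x, ...) {
  cat("<TorsionChain>", x$n_angles, "angle(s), inertias",
      paste(signif(x$inertias, 4), collapse = " "), "\n")
  print(x$potential)
  invisible(x)
}

#' Build a chain from a parsed configuration mapping
#'
#' Accepts the nested list produced by [read_run_config()] (sections
#' `chain` and `potential`) or an equivalent hand-built list. The potential
#' section requires a `kind` plus the coefficients of that kind.
#'
#' @param config a list with elements `chain` (fields `n_angles`,
#'   `inertias`) and `potential` (field `kind` plus kind-specific
#'   coefficients: `k`/`half_k`; `k_plus`/`k_minus`/`theta_ref`;
#'   `a`/`b`/`linear`).
#' @return a [torsion_chain()].
#' @export
build_chain <- function(config) {
  if (is.null(config$chain))
    stop("config is missing the [chain] section", call. = FALSE)
  ch <- config$chain
  if (is.null(ch$n_angles))
    stop("config field chain.n_angles is missing", call. = FALSE)
  if (is.null(ch$inertias))
    stop("config field chain.inertias is missing", call. = FALSE)
  pot <- potential_from_config(config$potential)
  torsion_chain(ch$n_angles, ch$inertias, pot)
}

potential_from_config <- function(pc) {
  if (is.null(pc))
    stop("config is missing the [potential] section", call. = FALSE)
  if (is.null(pc$kind))
    stop("config field potential.kind is missing", call. = FALSE)
  kind <- pc$kind
  allowed <- c("harmonic_spring", "asymmetric_spring", "cusp")
  if (!kind %in% allowed)
    stop("unknown potential kind '", kind, "'; allowed kinds: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  switch(kind,
    harmonic_spring = harmonic_spring(
      k = need_num(pc, "k"),
      half_k = isTRUE(pc$half_k)),
    asymmetric_spring = asymmetric_spring(
      k_plus = need_num(pc, "k_plus"),
      k_minus = need_num(pc, "k_minus"),
      theta_ref = if (is.null(pc$theta_ref)) 0 else pc$theta_ref),
    cusp = cusp_potential(
      a = need_num(pc, "a"), b = need_num(pc, "b"),
      linear = if (is.null(pc$linear)) TRUE else isTRUE(pc$linear))
  )
}

need_num <- function(lst, field) {
  v <- lst[[field]]
  if (is.null(v) || !is.numeric(v))
    stop("config field potential.", field, " is missing or non-numeric",
         call. = FALSE)
  v
}

check_angles <- function(chain, angles) {
  if (!is.numeric(angles) || length(angles) != chain$n_angles)
    stop("angle vector has length ", length(angles),
         " but the chain has ", chain$n_angles, " angle(s)", call. = FALSE)
  invisible(angles)
}

#' Chain energies and derivatives
#'
#' `evaluate_potential()` returns the total potential energy of the chain at
#' an angle configuration; `potential_gradient()` and `potential_hessian()`
#' its gradient vector and Hessian matrix (diagonal for per-angle
#' potentials, full for `coupled` specs); `kinetic_energy()` the quadratic
#' form \eqn{\frac{1}{2}\dot\theta^\top M \dot\theta}.
#'
#' @param chain a [torsion_chain()].
#' @param angles numeric vector of length `n_angles` (radians).
#' @param rates angle rates, same length.
#' @param t time (relevant only for scheduled potentials).
#' @return scalar energy, gradient vector, or Hessian matrix.
#' @export
evaluate_potential <- function(chain, angles, t = 0) {
  stopifnot(inherits(chain, "TorsionChain"))
  check_angles(chain, angles)
  spec <- chain$potential
  if (spec$kind == "coupled")
    return(td_factor(spec, t) * spec$params$V(angles))
  sum(potential_value(spec, angles, t))
}

#' @rdname evaluate_potential
#' @export
potential_gradient <- function(chain, angles, t = 0) {
  stopifnot(inherits(chain, "TorsionChain"))
  check_angles(chain, angles)
  spec <- chain$potential
  if (spec$kind == "coupled") {
    g <- if (is.function(spec$params$dV)) spec$params$dV(angles)
         else num_grad(spec$params$V, angles)
    return(td_factor(spec, t) * g)
  }
  potential_deriv(spec, angles, t)
}

#' @rdname evaluate_potential
#' @export
potential_hessian <- function(chain, angles, t = 0) {
  stopifnot(inherits(chain, "TorsionChain"))
  check_angles(chain, angles)
  spec <- chain$potential
  if (spec$kind == "coupled") {
    H <- if (is.function(spec$params$d2V)) spec$params$d2V(angles)
         else num_hess(spec$params$V, angles)
    return(td_factor(spec, t) * H)
  }
  diag(potential_deriv2(spec, angles, t), nrow = chain$n_angles)
}

#' @rdname evaluate_potential
#' @export
kinetic_energy <- function(chain, rates) {
  stopifnot(inherits(chain, "TorsionChain"))
  check_angles(chain, rates)
  0.5 * sum(chain$inertias * rates^2)
}

num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

num_hess <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  f0 <- f(x)
  for (i in seq_len(n)) {
    ei <- numeric(n); ei[i] <- h
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < n) for (j in (i + 1):n) {
      ej <- numeric(n); ej[j] <- h
      H[i, j] <- (f(x + ei + ej) - f(x + ei - ej) -
                    f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
      H[j, i] <- H[i, j]
    }
  }
  H
}
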