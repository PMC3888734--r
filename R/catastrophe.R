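#' Registry of the seven elementary catastrophe normal forms
#'
#' Degenerate critical points of a generic family with at most four control
#' parameters are right-equivalent to one of exactly seven polynomial germs
#' (Thom's theorem): four of corank 1 (fold, cusp, swallowtail, butterfly)
#' and three of corank 2 (the umbilics). Each registry entry carries the
#' germ polynomial, its state dimension, control dimension, corank, germ
#' degree, and evaluators for the germ, its gradient, its Hessian, and the
#' standard universal unfolding.
#'
#' Germ polynomials used (standard conventions):
#' \describe{
#'   \item{fold}{\eqn{s^3}, 1 control}
#'   \item{cusp}{\eqn{s^4}, 2 controls}
#'   \item{swallowtail}{\eqn{s^5}, 3 controls}
#'   \item{butterfly}{\eqn{s^6}, 4 controls}
#'   \item{hyperbolic umbilic}{\eqn{s_1^3 + s_2^3}, 3 controls}
#'   \item{elliptic umbilic}{\eqn{s_1^3 - 3 s_1 s_2^2}, 3 controls}
#'   \item{parabolic umbilic}{\eqn{s_1^2 s_2 + s_2^4}, 4 controls}
#' }
#'
#' @return list of 7 `NormalFormEntry` objects, each with fields `name`,
#'   `state_dim`, `control_dim`, `corank`, `germ_degree`, `germ(s)`,
#'   `grad(s)`, `hess(s)`, `unfolding(s, controls)`.
#' @examples
#' length(normal_form_registry())            # 7
#' normal_form_registry()[["cusp"]]$germ(2)  # 16
#' @export
normal_form_registry <- function() {
  entry <- function(name, state_dim, control_dim, corank, germ_degree,
                    germ, grad, hess, unfolding) {
    structure(list(name = name, state_dim = state_dim,
                   control_dim = control_dim, corank = corank,
                   germ_degree = germ_degree, germ = germ, grad = grad,
                   hess = hess, unfolding = unfolding),
              class = "NormalFormEntry")
  }
  reg <- list(
    fold = entry("fold", 1, 1, 1, 3,
      function(s) s^3,
      function(s) 3 * s^2,
      function(s) matrix(6 * s, 1, 1),
      function(s, ctl) s^3 + ctl[1] * s),
    cusp = entry("cusp", 1, 2, 1, 4,
      function(s) s^4,
      function(s) 4 * s^3,
      function(s) matrix(12 * s^2, 1, 1),
      function(s, ctl) s^4 + ctl[1] * s^2 + ctl[2] * s),
    swallowtail = entry("swallowtail", 1, 3, 1, 5,
      function(s) s^5,
      function(s) 5 * s^4,
      function(s) matrix(20 * s^3, 1, 1),
      function(s, ctl) s^5 + ctl[1] * s^3 + ctl[2] * s^2 + ctl[3] * s),
    butterfly = entry("butterfly", 1, 4, 1, 6,
      function(s) s^6,
      function(s) 6 * s^5,
      function(s) matrix(30 * s^4, 1, 1),
      function(s, ctl) s^6 + ctl[1] * s^4 + ctl[2] * s^3 +
        ctl[3] * s^2 + ctl[4] * s),
    hyperbolic_umbilic = entry("hyperbolic_umbilic", 2, 3, 2, 3,
      function(s) s[1]^3 + s[2]^3,
      function(s) c(3 * s[1]^2, 3 * s[2]^2),
      function(s) diag(c(6 * s[1], 6 * s[2])),
      function(s, ctl) s[1]^3 + s[2]^3 + ctl[1] * s[1] * s[2] +
        ctl[2] * s[1] + ctl[3] * s[2]),
    elliptic_umbilic = entry("elliptic_umbilic", 2, 3, 2, 3,
      function(s) s[1]^3 - 3 * s[1] * s[2]^2,
      function(s) c(3 * s[1]^2 - 3 * s[2]^2, -6 * s[1] * s[2]),
      function(s) matrix(c(6 * s[1], -6 * s[2], -6 * s[2], -6 * s[1]),
                         2, 2),
      function(s, ctl) s[1]^3 - 3 * s[1] * s[2]^2 +
        ctl[1] * (s[1]^2 + s[2]^2) + ctl[2] * s[1] + ctl[3] * s[2]),
    parabolic_umbilic = entry("parabolic_umbilic", 2, 4, 2, 4,
      function(s) s[1]^2 * s[2] + s[2]^4,
      function(s) c(2 * s[1] * s[2], s[1]^2 + 4 * s[2]^3),
      function(s) matrix(c(2 * s[2], 2 * s[1], 2 * s[1], 12 * s[2]^2),
                         2, 2),
      function(s, ctl) s[1]^2 * s[2] + s[2]^4 + ctl[1] * s[1]^2 +
        ctl[2] * s[2]^2 + ctl[3] * s[1] + ctl[4] * s[2])
  )
  reg
}

#' @export
print.NormalFormEntry <- function(x, ...) {
  cat(sprintf("<NormalFormEntry> %s: state dim %d, %d control(s), corank %d\n",
              x$name, x$state_dim, x$control_dim, x$corank))
  invisible(x)
}

# ---- classification --------------------------------------------------------

# monomial design matrix of the full jet up to `degree` in 1 or 2 variables
jet_terms <- function(state_dim, degree) {
  if (state_dim == 1) {
    data.frame(i = 0:degree, j = 0)
  } else {
    g <- expand.grid(i = 0:degree, j = 0:degree)
    g[g$i + g$j <= degree, ]
  }
}

fit_jet <- function(samples, state_dim, degree = 6) {
  if (state_dim == 1) {
    X <- as.matrix(samples[, "s", drop = FALSE])
  } else {
    X <- as.matrix(samples[, c("s1", "s2")])
  }
  f <- samples$f
  terms <- jet_terms(state_dim, degree)
  D <- matrix(0, nrow(X), nrow(terms))
  for (k in seq_len(nrow(terms)))
    D[, k] <- X[, 1]^terms$i[k] *
      (if (state_dim == 2) X[, 2]^terms$j[k] else 1)
  fit <- stats::lsfit(D, f, intercept = FALSE)
  coef <- fit$coefficients
  resid <- sqrt(mean(fit$residuals^2))
  list(terms = terms, coef = coef, resid = resid,
       scale = max(abs(f), 1e-300))
}

jet_coef <- function(jet, i, j = 0) {
  k <- which(jet$terms$i == i & jet$terms$j == j)
  if (length(k) == 0) 0 else unname(jet$coef[k])
}

# evaluate the fitted jet polynomial at points (rows of X)
jet_eval <- function(jet, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  out <- numeric(nrow(X))
  for (k in seq_len(nrow(jet$terms)))
    out <- out + jet$coef[k] * X[, 1]^jet$terms$i[k] *
      (if (ncol(X) == 2) X[, 2]^jet$terms$j[k] else 1)
  out
}

classify_1d_jet <- function(coefs_by_degree, window, coef_tol) {
  # coefs_by_degree: named c3..c6 of the reduced 1-D jet
  for (deg in 3:6) {
    ck <- coefs_by_degree[[paste0("c", deg)]]
    if (abs(ck) * window^deg > coef_tol) {
      return(switch(as.character(deg),
                    "3" = "fold", "4" = "cusp",
                    "5" = "swallowtail", "6" = "butterfly"))
    }
  }
  "unclassified"
}

#' Classify a locally sampled action against the elementary normal forms
#'
#' Fits a polynomial jet of degree at most 6 to samples of a smooth scalar
#' function around a critical point at the origin, decides the corank from
#' the Hessian eigenvalues (an eigenvalue is "zero" when its magnitude is
#' below `1e-6` of the largest), and matches the degenerate part to a
#' registry germ after scale normalization. A full-rank Hessian yields
#' `"morse"` (a nondegenerate critical point -- no catastrophe); corank 1 is
#' resolved by the leading degree of the jet restricted to the null
#' direction; corank 2 by the real-factor structure of the cubic part
#' (three factors: elliptic umbilic, one: hyperbolic umbilic, repeated +
#' quartic term: parabolic umbilic).
#'
#' @param samples data.frame with columns `s` (or `s1`, `s2`) and `f`
#'   holding function values on a grid around the origin.
#' @param state_dim 1 or 2.
#' @param grad_tol tolerance for the gradient at the center; larger values
#'   raise an error ("center not critical").
#' @param resid_tol relative jet-fit residual above which the sample is
#'   `"unclassified"` (non-polynomial behavior beyond degree 6).
#' @return list with `class` (`"morse"`, a registry germ name, or
#'   `"unclassified"`), `corank`, `controls` (fitted sub-leading
#'   coefficients of the reduced jet), `residual`, and `jet`.
#' @examples
#' s <- seq(-0.5, 0.5, length.out = 41)
#' classify_germ(data.frame(s = s, f = 0.25 * s^4), 1)$class  # "cusp"
#' @export
classify_germ <- function(samples, state_dim, grad_tol = 1e-6,
                          resid_tol = 1e-6) {
  stopifnot(is.data.frame(samples), state_dim %in% c(1, 2))
  need <- if (state_dim == 1) c("s", "f") else c("s1", "s2", "f")
  if (!all(need %in% names(samples)))
    stop("samples must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  jet <- fit_jet(samples, state_dim)
  window <- if (state_dim == 1) max(abs(samples$s)) else
    max(abs(c(samples$s1, samples$s2)))
  fscale <- max(jet$scale, 1e-300)
  coef_tol <- 1e-8 * fscale

  # gradient at the center from the linear jet coefficients
  grad <- if (state_dim == 1) jet_coef(jet, 1) else
    c(jet_coef(jet, 1, 0), jet_coef(jet, 0, 1))
  gnorm <- sqrt(sum(grad^2)) * window / fscale
  if (gnorm > grad_tol)
    stop("center is not a critical point: scaled gradient norm ",
         signif(gnorm, 4), " exceeds ", grad_tol, call. = FALSE)

  rel_resid <- jet$resid / fscale
  if (rel_resid > resid_tol)
    return(list(class = "unclassified", corank = NA_integer_,
                controls = numeric(0), residual = rel_resid, jet = jet))

  H <- if (state_dim == 1) matrix(2 * jet_coef(jet, 2), 1, 1) else
    matrix(c(2 * jet_coef(jet, 2, 0), jet_coef(jet, 1, 1),
             jet_coef(jet, 1, 1), 2 * jet_coef(jet, 0, 2)), 2, 2)
  eh <- eigen(H, symmetric = TRUE)
  # an eigenvalue counts as zero below 1e-6 of the curvature scale; the
  # scale floor fscale/window^2 keeps noise-level quadratic coefficients of
  # a genuinely degenerate germ from masquerading as full rank
  hscale <- max(abs(eh$values), fscale / window^2)
  corank <- sum(abs(eh$values) < 1e-6 * hscale)

  if (corank == 0)
    return(list(class = "morse", corank = 0L,
                controls = numeric(0), residual = rel_resid, jet = jet))

  if (state_dim == 1 || corank == 1) {
    # restrict the jet to the null direction and classify the 1-D tail
    if (state_dim == 1) {
      cs <- list(c3 = jet_coef(jet, 3), c4 = jet_coef(jet, 4),
                 c5 = jet_coef(jet, 5), c6 = jet_coef(jet, 6))
    } else {
      v <- eh$vectors[, which.min(abs(eh$values))]
      xs <- seq(-window, window, length.out = 25)
      fv <- jet_eval(jet, cbind(xs * v[1], xs * v[2]))
      j1 <- fit_jet(data.frame(s = xs, f = fv), 1)
      cs <- list(c3 = jet_coef(j1, 3), c4 = jet_coef(j1, 4),
                 c5 = jet_coef(j1, 5), c6 = jet_coef(j1, 6))
    }
    cls <- classify_1d_jet(cs, window, coef_tol)
    lead_deg <- match(cls, c("fold", "cusp", "swallowtail", "butterfly")) + 2
    ctl <- numeric(0)
    if (!is.na(lead_deg) && state_dim == 1) {
      lead <- cs[[paste0("c", lead_deg)]]
      # normalize scale so the germ is monic; report the unfolding
      # coefficients (degrees 1..lead-2; the degree lead-1 term is
      # removable by translation)
      low <- vapply(seq_len(lead_deg - 2),
                    function(d) jet_coef(jet, d), numeric(1))
      ctl <- low / abs(lead)
      names(ctl) <- paste0("a", seq_len(lead_deg - 2))
    }
    return(list(class = cls, corank = 1L, controls = ctl,
                residual = rel_resid, jet = jet))
  }

  # corank 2: cubic part c30 x^3 + c21 x^2 y + c12 x y^2 + c03 y^3
  a <- jet_coef(jet, 3, 0); b <- jet_coef(jet, 2, 1)
  cc <- jet_coef(jet, 1, 2); d <- jet_coef(jet, 0, 3)
  cubic_scale <- max(abs(c(a, b, cc, d)))
  if (cubic_scale * window^3 > coef_tol) {
    disc <- 18 * a * b * cc * d - 4 * b^3 * d + b^2 * cc^2 -
      4 * a * cc^3 - 27 * a^2 * d^2
    disc_rel <- disc / cubic_scale^4
    if (disc_rel > 1e-8)
      return(list(class = "elliptic_umbilic", corank = 2L,
                  controls = numeric(0), residual = rel_resid, jet = jet))
    if (disc_rel < -1e-8)
      return(list(class = "hyperbolic_umbilic", corank = 2L,
                  controls = numeric(0), residual = rel_resid, jet = jet))
    # repeated-factor cubic: parabolic umbilic needs a quartic term
    quart <- max(abs(c(jet_coef(jet, 4, 0), jet_coef(jet, 3, 1),
                       jet_coef(jet, 2, 2), jet_coef(jet, 1, 3),
                       jet_coef(jet, 0, 4))))
    if (quart * window^4 > coef_tol)
      return(list(class = "parabolic_umbilic", corank = 2L,
                  controls = numeric(0), residual = rel_resid, jet = jet))
  }
  list(class = "unclassified", corank = 2L, controls = numeric(0),
       residual = rel_resid, jet = jet)
}

# ---- structural stability --------------------------------------------------

# Horner evaluation of an ascending-power coefficient vector, vectorized
poly_eval <- function(coefs, x) {
  out <- rep(coefs[length(coefs)], length(x))
  for (k in (length(coefs) - 1):1) out <- out * x + coefs[k]
  out
}

poly_deriv <- function(coefs) {
  n <- length(coefs)
  if (n <= 1) return(0)
  coefs[-1] * seq_len(n - 1)
}

# all critical points of a polynomial on [-window, window] by dense
# sign-change scanning of the derivative plus uniroot polish; returns
# locations and Morse indices (0 = minimum, 1 = maximum in 1-D)
critical_points_poly <- function(coefs, window, n_scan = 4001) {
  dc <- poly_deriv(coefs)
  d2c <- poly_deriv(dc)
  xs <- seq(-window, window, length.out = n_scan)
  g <- poly_eval(dc, xs)
  hit <- which(g[-n_scan] * g[-1] < 0)
  roots <- vapply(hit, function(i)
    stats::uniroot(function(z) poly_eval(dc, z), c(xs[i], xs[i + 1]),
                   tol = 1e-13)$root, numeric(1))
  roots <- sort(unique(c(roots, xs[g == 0])))
  if (length(roots) == 0)
    return(data.frame(s = numeric(0), index = integer(0)))
  data.frame(s = roots, index = as.integer(poly_eval(d2c, roots) < 0))
}

#' Perturbation stability of a normal form
#'
#' The defining property of the elementary catastrophes is that, for fixed
#' control values, perturbations by higher-order polynomials in the state
#' variable do not change the local shape of the action. "Shape unchanged"
#' is operationalized as preservation of the critical-point count and their
#' Morse indices inside a window -- a numerically decidable surrogate for
#' right-equivalence. Each trial adds a random polynomial with degrees in
#' `[degree_min, degree_max]` and coefficients uniform in
#' `[-amplitude, amplitude]` and re-enumerates the critical points by dense
#' root-finding.
#'
#' For a fixed `seed` the trial draws are unit-coefficient polynomials
#' scaled by `amplitude`, so preserved fractions along an amplitude ladder
#' compare the same perturbation shapes.
#'
#' @param form a registry entry name (e.g. `"cusp"`) or `NormalFormEntry`
#'   of corank 1 (one state variable).
#' @param controls fixed control values (length `control_dim`); keep them
#'   away from the bifurcation set so a margin exists.
#' @param window state-space radius in which critical points are counted.
#' @param degree_min,degree_max perturbation polynomial degrees; must
#'   exceed the germ degree (testing lower orders tests unfolding terms,
#'   not the stability claim).
#' @param amplitude maximum coefficient magnitude.
#' @param trials number of random perturbations.
#' @param seed RNG seed (explicit parameter, never global state).
#' @return a `StabilityReport`: list with `trials`, `preserved`,
#'   `baseline` (unperturbed critical points), `degree_min`, `degree_max`,
#'   `amplitude`, `seed`.
#' @examples
#' rep <- perturbation_stability_test("cusp", controls = c(-1, 0),
#'   window = 1.5, degree_min = 5, degree_max = 8,
#'   amplitude = 1e-3, trials = 20, seed = 42)
#' rep$preserved / rep$trials
#' @export
perturbation_stability_test <- function(form, controls, window = 1.5,
                                        degree_min, degree_max,
                                        amplitude, trials = 200,
                                        seed = 1) {
  if (is.character(form)) {
    reg <- normal_form_registry()
    if (!form %in% names(reg))
      stop("unknown normal form '", form, "'; registry entries: ",
           paste(names(reg), collapse = ", "), call. = FALSE)
    form <- reg[[form]]
  }
  stopifnot(inherits(form, "NormalFormEntry"))
  if (form$state_dim != 1)
    stop("perturbation_stability_test supports one-state-variable forms ",
         "(corank 1); '", form$name, "' has state dimension ",
         form$state_dim, call. = FALSE)
  if (length(controls) != form$control_dim)
    stop("'", form$name, "' needs ", form$control_dim, " control(s)",
         call. = FALSE)
  if (degree_min <= form$germ_degree)
    stop("degree_min (", degree_min, ") must exceed the germ degree (",
         form$germ_degree, "): the stability claim concerns higher-order ",
         "perturbations", call. = FALSE)
  stopifnot(degree_max >= degree_min, amplitude >= 0, trials >= 1)

  # ascending-power coefficient vector of the unfolded polynomial
  g <- form$germ_degree
  base_coefs <- numeric(g + 1)
  base_coefs[g + 1] <- 1
  # unfolding terms of the corank-1 forms: s^{g-2}, s^{g-3}, ..., s^1
  for (i in seq_len(form$control_dim))
    base_coefs[g - 1 - i + 1] <- base_coefs[g - 1 - i + 1] + controls[i]
  baseline <- critical_points_poly(base_coefs, window)

  degs <- degree_min:degree_max
  preserved <- 0L
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  unit_draws <- matrix(stats::runif(trials * length(degs), -1, 1),
                       trials, length(degs))
  for (tr in seq_len(trials)) {
    co <- amplitude * unit_draws[tr, ]
    coefs <- c(base_coefs, numeric(degree_max + 1 - length(base_coefs)))
    coefs[degs + 1] <- coefs[degs + 1] + co
    cp <- critical_points_poly(coefs, window)
    same <- nrow(cp) == nrow(baseline) &&
      all(cp$index == baseline$index)
    if (same) preserved <- preserved + 1L
  }
  structure(list(trials = trials, preserved = preserved,
                 baseline = baseline, degree_min = degree_min,
                 degree_max = degree_max, amplitude = amplitude,
                 seed = seed, form = form$name, controls = controls,
                 window = window),
            class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  cat(sprintf(paste0("<StabilityReport> %s, controls (%s): %d/%d trials ",
                     "preserved (degrees %d-%d, amplitude %g, seed %d)\n"),
              x$form, paste(signif(x$controls, 4), collapse = ", "),
              x$preserved, x$trials, x$degree_min, x$degree_max,
              x$amplitude, x$seed))
  invisible(x)
}

# ---- Boltzmann moments -----------------------------------------------------

#' Boltzmann moments of a one-variable potential
#'
#' Equilibrium moments \eqn{\langle\theta^k\rangle =
#' \int \theta^k e^{-V/k_BT} d\theta / \int e^{-V/k_BT} d\theta} by
#' adaptive quadrature. The integration window is grown until the Boltzmann
#' weight at its ends falls below `1e-16` of its maximum; a potential whose
#' weight does not decay (non-confining) raises an integrability error.
#'
#' @param potential a function `V(theta)` (vectorized), a [PotentialSpec],
#'   or a [cusp_germ()].
#' @param kBT thermal energy (default 1: energies in units of kBT).
#' @param orders integer vector of moment orders.
#' @return named numeric vector of moments, names `m<k>`.
#' @examples
#' boltzmann_moments(cusp_germ(0, 0), orders = 2)  # 2*gamma(3/4)/gamma(1/4)
#' @export
boltzmann_moments <- function(potential, kBT = 1, orders = c(1, 2)) {
  stopifnot(kBT > 0)
  V <- potential_as_function(potential)
  # grow the window until the weight at its ends is < 1e-16 of its maximum
  # over the window; a weight maximized at the boundary signals a
  # non-confining potential (tail test)
  L <- 1
  repeat {
    xs <- seq(-L, L, length.out = 513)
    vs <- V(xs)
    vmin <- min(vs)
    edge <- exp(-(max(vs[1], vs[513]) - vmin) / kBT)
    boundary_max <- which.min(vs) %in% c(1, 513)
    if (!boundary_max && edge < 1e-16) break
    L <- L * 1.5
    if (L > 1e4)
      stop("potential appears non-confining: Boltzmann weight does not ",
           "decay within |theta| <= 1e4", call. = FALSE)
  }
  w <- function(x) exp(-(V(x) - vmin) / kBT)
  quad <- function(f) {
    r <- tryCatch(stats::integrate(f, -L, L, rel.tol = 1e-10,
                                   subdivisions = 1000L),
                  error = function(e)
                    stats::integrate(f, -L, L, rel.tol = 1e-8,
                                     subdivisions = 1000L))
    r$value
  }
  Z <- quad(w)
  out <- vapply(orders, function(k) quad(function(x) x^k * w(x)) / Z,
                numeric(1))
  names(out) <- paste0("m", orders)
  out
}

potential_as_function <- function(potential) {
  if (is.function(potential)) return(potential)
  if (inherits(potential, "CuspGerm"))
    return(function(x) cusp_action_value(potential, x))
  if (inherits(potential, "PotentialSpec"))
    return(function(x) potential_value(potential, x))
  stop("potential must be a function, PotentialSpec or CuspGerm",
       call. = FALSE)
}

#' Recover cusp controls from measured moments
#'
#' Inverts [boltzmann_moments()] of the cusp potential
#' \eqn{V = \frac{1}{4}\theta^4 + \frac{1}{2}a\theta^2 + b\theta} over
#' `(a, b)` by least squares on the first three moments. The quartic term
#' keeps the potential confining for any controls, so the forward map is
#' always defined.
#'
#' @param moments numeric vector of measured
#'   \eqn{\langle\theta\rangle, \langle\theta^2\rangle,
#'   \langle\theta^3\rangle} (in that order).
#' @param kBT thermal energy used when the moments were generated.
#' @param start optional starting values `c(a, b)`.
#' @return list with `a`, `b`, `residual` (root-mean-square relative moment
#'   mismatch), and the optimizer `convergence` code.
#' @export
recover_cusp_controls <- function(moments, kBT = 1, start = c(1, 0)) {
  stopifnot(length(moments) == 3, kBT > 0)
  scale <- pmax(abs(moments), 0.05)
  obj <- function(p) {
    mm <- boltzmann_moments(cusp_germ(p[1], p[2]), kBT, orders = 1:3)
    sum(((mm - moments) / scale)^2)
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  if (fit$convergence != 0)
    stop("moment inversion did not converge (code ", fit$convergence,
         ", objective ", signif(fit$value, 4), ")", call. = FALSE)
  list(a = fit$par[1], b = fit$par[2],
       residual = sqrt(fit$value / 3), convergence = fit$convergence)
}
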