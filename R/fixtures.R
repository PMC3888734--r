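#' Seeded fixture generator
#'
#' Generates every synthetic input the test surface needs, with the analytic
#' ground truth embedded in the manifest so that tests never hard-code the
#' same number in two places. Catalog:
#' \describe{
#'   \item{free_particle}{flat potential, members start at position `u`
#'     with a common velocity; parallel lines, no caustic.}
#'   \item{harmonic_focus}{unit-frequency spring (`half_k` convention,
#'     k = 1, m = 1), all members start at `theta0` with velocity `u`; every
#'     member refocuses at `(t, x) = (pi, -theta0)` -- the classical kinetic
#'     focus.}
#'   \item{inverted_harmonic}{V = -theta^2/2; Jacobi fields grow like sinh,
#'     no conjugate point ever.}
#'   \item{cusp_family}{closed-form family action
#'     \eqn{S(u; x_1, x_2) = u^4/4 + x_1 u^2/2 + x_2 u} sampled on a stated
#'     control grid; the caustic is the fold curve
#'     \eqn{4x_1^3 + 27x_2^2 = 0}.}
#'   \item{zeeman_toy}{one-angle chain with the double-well cusp potential
#'     (a = -1, b = 0), the torsional analogue of the Zeeman catastrophe
#'     machine; manifest records the critical points -1, 0, 1.}
#'   \item{germ_samples}{exact samples of each registry germ on a small
#'     grid, for classifier tests.}
#'   \item{noisy_moments}{Boltzmann moments of a cusp potential with
#'     multiplicative noise, for parameter-recovery studies.}
#' }
#'
#' Re-running a fixture with the same spec and seed reproduces byte-identical
#' files; the manifest records content hashes.
#'
#' @param name catalog name.
#' @param params named list overriding catalog defaults (see the manifest
#'   of a default run for the parameter names).
#' @param seed RNG seed (only `noisy_moments` consumes randomness, but the
#'   seed is always recorded).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly; written as `manifest.json` alongside
#'   the fixture files.
#' @examples
#' \donttest{
#' td <- tempfile(); dir.create(td)
#' m <- generate_fixture("harmonic_focus", out_dir = td)
#' m$analytic$focus_time   # pi
#' }
#' @export
generate_fixture <- function(name, params = list(), seed = 1,
                             out_dir = ".") {
  catalog <- c("free_particle", "harmonic_focus", "inverted_harmonic",
               "cusp_family", "zeeman_toy", "germ_samples",
               "noisy_moments")
  if (!name %in% catalog)
    stop("unknown fixture '", name, "'; catalog: ",
         paste(catalog, collapse = ", "), call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  gen <- switch(name,
    free_particle = fixture_free_particle,
    harmonic_focus = fixture_harmonic_focus,
    inverted_harmonic = fixture_inverted_harmonic,
    cusp_family = fixture_cusp_family,
    zeeman_toy = fixture_zeeman_toy,
    germ_samples = fixture_germ_samples,
    noisy_moments = fixture_noisy_moments)
  res <- gen(params, seed, out_dir)
  manifest <- list(fixture = name, seed = seed,
                   params = res$params, analytic = res$analytic,
                   files = lapply(res$files, function(f)
                     list(path = basename(f),
                          hash = fnv1a(paste(readLines(f, warn = FALSE),
                                             collapse = "\n")))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

with_defaults <- function(params, defaults) {
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0)
    stop("unknown fixture parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  utils::modifyList(defaults, params)
}

write_family_csv <- function(family, out_dir, stem) {
  files <- character(0)
  for (i in seq_along(family$u)) {
    f <- file.path(out_dir, sprintf("%s_u%03d.csv", stem, i))
    write_trajectory(family$trajectories[[i]], f)
    files <- c(files, f, sub("\\.csv$", ".json", f))
  }
  files
}

fixture_free_particle <- function(params, seed, out_dir) {
  p <- with_defaults(params, list(u_min = -1, u_max = 1, u_n = 9,
                                  v0 = 0.5, t0 = 0, t1 = 2,
                                  n_steps = 200, m = 1))
  chain <- torsion_chain(1, p$m, harmonic_spring(0))
  fam <- shoot_family(chain, function(u) list(q0 = u, v0 = p$v0),
                      seq(p$u_min, p$u_max, length.out = p$u_n),
                      p$t0, p$t1, p$n_steps)
  cfg <- structure(list(
    chain = list(n_angles = 1, inertias = p$m),
    potential = list(kind = "harmonic_spring", k = 0, half_k = FALSE),
    time = list(t0 = p$t0, t1 = p$t1, n_steps = p$n_steps),
    family = list(u_min = p$u_min, u_max = p$u_max, u_n = p$u_n,
                  vary = "position", v0 = p$v0)), class = "RunConfig")
  cfg_path <- file.path(out_dir, "config.txt")
  write_run_config(cfg, cfg_path)
  files <- c(cfg_path, write_family_csv(fam, out_dir, "free_particle"))
  list(params = p, files = files,
       analytic = list(caustic = "none",
                       member_form = "theta(t) = u + v0 * t"))
}

fixture_harmonic_focus <- function(params, seed, out_dir) {
  p <- with_defaults(params, list(theta0 = 1, u_min = -2, u_max = 2,
                                  u_n = 21, t0 = 0, t1 = 4,
                                  n_steps = 800, m = 1, k = 1))
  chain <- torsion_chain(1, p$m, harmonic_spring(p$k, half_k = TRUE))
  fam <- shoot_family(chain, function(u) list(q0 = p$theta0, v0 = u),
                      seq(p$u_min, p$u_max, length.out = p$u_n),
                      p$t0, p$t1, p$n_steps)
  cfg <- structure(list(
    chain = list(n_angles = 1, inertias = p$m),
    potential = list(kind = "harmonic_spring", k = p$k, half_k = TRUE),
    time = list(t0 = p$t0, t1 = p$t1, n_steps = p$n_steps),
    family = list(u_min = p$u_min, u_max = p$u_max, u_n = p$u_n,
                  vary = "velocity", q0 = p$theta0)), class = "RunConfig")
  cfg_path <- file.path(out_dir, "config.txt")
  write_run_config(cfg, cfg_path)
  files <- c(cfg_path, write_family_csv(fam, out_dir, "harmonic_focus"))
  omega <- sqrt(p$k / p$m)
  list(params = p, files = files,
       analytic = list(focus_time = pi / omega,
                       focus_position = -p$theta0,
                       member_form = "theta(t) = theta0 cos(wt) + (u/w) sin(wt)"))
}

fixture_inverted_harmonic <- function(params, seed, out_dir) {
  p <- with_defaults(params, list(q0 = 0.1, v0 = 0, t0 = 0, t1 = 3,
                                  n_steps = 600, m = 1))
  chain <- torsion_chain(1, p$m, harmonic_spring(-0.5))
  traj <- integrate_trajectory(chain, p$q0, p$v0, p$t0, p$t1, p$n_steps)
  f <- file.path(out_dir, "inverted_harmonic.csv")
  write_trajectory(traj, f)
  cfg <- structure(list(
    chain = list(n_angles = 1, inertias = p$m),
    potential = list(kind = "harmonic_spring", k = -0.5, half_k = FALSE),
    time = list(t0 = p$t0, t1 = p$t1, n_steps = p$n_steps)),
    class = "RunConfig")
  cfg_path <- file.path(out_dir, "config.txt")
  write_run_config(cfg, cfg_path)
  list(params = p, files = c(cfg_path, f, sub("\\.csv$", ".json", f)),
       analytic = list(conjugate_points = "none",
                       jacobi_field = "sinh(t), no interior zeros"))
}

fixture_cusp_family <- function(params, seed, out_dir) {
  p <- with_defaults(params, list(u_min = -2, u_max = 2, u_n = 401,
                                  x1_min = -1.2, x1_max = -0.5, x1_n = 8,
                                  x2_min = -0.8, x2_max = 0.8, x2_n = 161))
  u <- seq(p$u_min, p$u_max, length.out = p$u_n)
  ctr <- expand.grid(x2 = seq(p$x2_min, p$x2_max, length.out = p$x2_n),
                     x1 = seq(p$x1_min, p$x1_max, length.out = p$x1_n))
  ctr <- ctr[, c("x1", "x2")]
  df <- do.call(rbind, lapply(seq_len(nrow(ctr)), function(j)
    data.frame(x1 = ctr$x1[j], x2 = ctr$x2[j], u = u,
               S = 0.25 * u^4 + 0.5 * ctr$x1[j] * u^2 + ctr$x2[j] * u)))
  f <- file.path(out_dir, "cusp_family.csv")
  utils::write.csv(df, f, row.names = FALSE)
  list(params = p, files = f,
       analytic = list(surface = "S = u^4/4 + x1 u^2/2 + x2 u",
                       discriminant = "4 x1^3 + 27 x2^2 = 0"))
}

fixture_zeeman_toy <- function(params, seed, out_dir) {
  p <- with_defaults(params, list(a = -1, b = 0, m = 1))
  cfg <- structure(list(
    chain = list(n_angles = 1, inertias = p$m),
    potential = list(kind = "cusp", a = p$a, b = p$b, linear = TRUE)),
    class = "RunConfig")
  cfg_path <- file.path(out_dir, "config.txt")
  write_run_config(cfg, cfg_path)
  germ <- cusp_germ(p$a, p$b)
  list(params = p, files = cfg_path,
       analytic = list(critical_points = cusp_critical_points(germ),
                       toy_action = "S(theta) = theta^4/4 + a theta^2/2 + b theta",
                       constant_offset_variant = "S(theta) = theta^4/4 + a theta^2/2 + b"))
}

fixture_germ_samples <- function(params, seed, out_dir) {
  p <- with_defaults(params, list(window = 0.5, n_1d = 41, n_2d = 21))
  reg <- normal_form_registry()
  files <- character(0)
  for (nm in names(reg)) {
    e <- reg[[nm]]
    if (e$state_dim == 1) {
      s <- seq(-p$window, p$window, length.out = p$n_1d)
      df <- data.frame(s = s, f = vapply(s, e$germ, numeric(1)))
    } else {
      g <- expand.grid(s1 = seq(-p$window, p$window, length.out = p$n_2d),
                       s2 = seq(-p$window, p$window, length.out = p$n_2d))
      df <- data.frame(g, f = apply(g, 1, function(r) e$germ(r)))
    }
    f <- file.path(out_dir, paste0("germ_", nm, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    files <- c(files, f)
  }
  list(params = p, files = files,
       analytic = list(expected_class = as.list(stats::setNames(
         names(reg), names(reg)))))
}

fixture_noisy_moments <- function(params, seed, out_dir) {
  p <- with_defaults(params, list(a = 2, b = 0, kBT = 1,
                                  noise_sd = 0.01, n_replicates = 100))
  exact <- boltzmann_moments(cusp_germ(p$a, p$b), p$kBT, orders = 1:3)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  noise <- matrix(stats::rnorm(p$n_replicates * 3, 1, p$noise_sd),
                  p$n_replicates, 3)
  df <- data.frame(replicate = seq_len(p$n_replicates),
                   m1 = exact[1] * noise[, 1],
                   m2 = exact[2] * noise[, 2],
                   m3 = exact[3] * noise[, 3])
  f <- file.path(out_dir, "noisy_moments.csv")
  utils::write.csv(df, f, row.names = FALSE)
  list(params = p, files = f,
       analytic = list(a = p$a, b = p$b, kBT = p$kBT,
                       exact_moments = as.numeric(exact)))
}
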