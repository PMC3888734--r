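#' Run an end-to-end caustic-detection scenario
#'
#' Executes the pipeline the framework proposes for locating caustics along
#' a folding path: shoot a family of stationary trajectories, tabulate the
#' family action surface, detect caustics, check the action signature just
#' beyond each one, and (optionally) classify the local action around
#' detected caustics against the elementary normal forms. The JSON report
#' records the caustic list, signature checks, classifications and
#' provenance (config hash, seed, package version); timestamps live in a
#' separate field so reports are otherwise deterministic.
#'
#' @param config a `RunConfig` (from [read_run_config()]) or a path to a
#'   config file. Sections `chain`, `potential`, `time` and `family` are
#'   required; `detection`, `output` and `run` are optional.
#' @param out_path path for the JSON report; default from the config's
#'   `output` section, else no file is written.
#' @param log_level `"quiet"`, `"info"` or `"debug"`; `key=value` lines go
#'   to stderr.
#' @return the report list, invisibly.
#' @export
run_scenario <- function(config, out_path = NULL, log_level = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  for (sec in c("chain", "potential", "time", "family"))
    if (is.null(config[[sec]]))
      stop("config is missing the [", sec, "] section", call. = FALSE)
  if (is.null(log_level))
    log_level <- if (!is.null(config$run$log_level))
      config$run$log_level else "info"
  logf <- function(level, ...) {
    if (log_level == "quiet") return(invisible())
    if (level == "debug" && log_level != "debug") return(invisible())
    message("causticfold ", paste0(..., collapse = " "))
  }
  seed <- if (!is.null(config$run$seed)) config$run$seed else 1

  stage <- "build_chain"
  report <- list(version = as.character(utils::packageVersion("causticfold")),
                 seed = seed, config_hash = NULL,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  result <- tryCatch({
    chain <- build_chain(config)
    report$config_hash <- chain_hash(chain)
    logf("info", "stage=build_chain n_angles=", chain$n_angles)

    stage <- "shoot_family"
    fm <- config$family
    for (k in c("u_min", "u_max", "u_n"))
      if (is.null(fm[[k]]))
        stop("config field family.", k, " is missing", call. = FALSE)
    vary <- if (is.null(fm$vary)) "velocity" else fm$vary
    q0 <- if (is.null(fm$q0)) 0 else fm$q0
    v0 <- if (is.null(fm$v0)) 0 else fm$v0
    curve <- if (vary == "velocity")
      function(u) list(q0 = q0, v0 = u)
    else function(u) list(q0 = u, v0 = v0)
    tm <- config$time
    fam <- shoot_family(chain, curve,
                        seq(fm$u_min, fm$u_max, length.out = fm$u_n),
                        tm$t0, tm$t1, tm$n_steps,
                        method = tm$method)
    logf("info", "stage=shoot_family members=", length(fam$u))

    stage <- "family_action_surface"
    det <- config$detection
    st_tol <- if (!is.null(det$stationarity_tol)) det$stationarity_tol
              else 1e-3
    surf <- family_action_surface(fam, chain, stationarity_tol = st_tol)

    stage <- "detect_caustic"
    ca <- detect_caustic(surf, tol_first = det$tol_first,
                         tol_second = det$tol_second)
    logf("info", "stage=detect_caustic n_caustics=", nrow(ca),
         " type=", attr(ca, "type"))

    stage <- "saddle_check_beyond"
    sc <- saddle_check_beyond(surf, ca)

    stage <- "classify"
    classifications <- list()
    if (isTRUE(det$classify) && nrow(ca) > 0) {
      for (r in seq_len(nrow(ca))) {
        if (is.na(ca$u[r])) next
        j <- which.min(abs(surf$t - ca$axis_value[r]))
        s_loc <- surf$u - ca$u[r]
        keep <- abs(s_loc) <= diff(range(surf$u)) / 4
        # recentre the column so the stationary point sits at the origin
        Sj <- surf$S[keep, j]
        samp <- data.frame(s = s_loc[keep],
                           f = Sj - min(Sj))
        cl <- tryCatch(classify_germ(samp, 1, grad_tol = 1e-2,
                                     resid_tol = 1e-2),
                       error = function(e) list(class = "unclassified",
                                                error = conditionMessage(e)))
        classifications[[length(classifications) + 1]] <-
          list(axis_value = ca$axis_value[r], class = cl$class)
      }
    }

    caustics <- if (nrow(ca) == 0) list() else lapply(seq_len(nrow(ca)),
      function(r) list(t = ca$axis_value[r], u = ca$u[r],
                       x = as.numeric(ca$x[[r]]), event = ca$event[r]))
    list(caustics = caustics, caustic_type = attr(ca, "type"),
         no_caustic_detected = nrow(ca) == 0,
         saddle_checks = if (nrow(sc) == 0) list() else
           lapply(seq_len(nrow(sc)), function(r) as.list(sc[r, ])),
         classifications = classifications)
  }, error = function(e) {
    stop("scenario failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  report <- c(report, result)

  if (is.null(out_path) && !is.null(config$output$report))
    out_path <- config$output$report
  if (!is.null(out_path)) {
    jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    logf("info", "stage=report path=", out_path)
  }
  invisible(report)
}
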