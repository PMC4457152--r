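#' Load a simulation configuration from YAML or JSON
#'
#' The schema mirrors \code{\link{simulation_config}}: keys \code{variant},
#' \code{alpha}, \code{beta}, \code{gamma}, \code{K}, \code{L},
#' \code{max_mcs}, \code{sample_every}, \code{relaxation_mcs}, \code{seed},
#' \code{replicates}, \code{init} (with \code{mode}, \code{weights},
#' \code{blocks}). Missing keys take the package defaults (K = 0.5,
#' alpha = 0.5); unknown keys are rejected with the offending name.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \code{\link{simulation_config}}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("variant", "alpha", "beta", "gamma", "K", "L", "max_mcs",
             "sample_every", "relaxation_mcs", "seed", "replicates", "init")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(raw$variant)) stop("config key 'variant' is required",
                                 call. = FALSE)
  if (is.null(raw$beta) || is.null(raw$gamma)) {
    stop("config keys 'beta' and 'gamma' are required", call. = FALSE)
  }
  init <- raw$init %||% list(mode = "uniform_random")
  if (!is.null(init$weights)) init$weights <- unlist(init$weights)
  simulation_config(
    variant = raw$variant,
    alpha = raw$alpha %||% 0.5, beta = raw$beta, gamma = raw$gamma,
    L = raw$L %||% 100, K = raw$K %||% 0.5,
    max_mcs = raw$max_mcs %||% 1000,
    sample_every = raw$sample_every %||% 1,
    relaxation_mcs = raw$relaxation_mcs,
    seed = raw$seed %||% 1,
    init = init,
    replicates = raw$replicates %||% 1
  )
}

config_as_list <- function(config) {
  list(variant = config$variant,
       alpha = config$params$alpha, beta = config$params$beta,
       gamma = config$params$gamma, fine = config$params$fine,
       K = config$K, L = config$L, max_mcs = config$max_mcs,
       sample_every = config$sample_every,
       relaxation_mcs = config$relaxation_mcs,
       seed = config$seed, replicates = config$replicates,
       init = config$init)
}

#' Write a simulation time series as CSV with a JSON manifest
#'
#' The CSV has columns \code{mcs} and \code{f_O, f_C, f_L, f_M, f_H} (only
#' those present in the variant), '.' decimal point, no locale dependence.
#' A JSON sidecar (\code{<path>.manifest.json}) records the fully resolved
#' configuration, replicate, seed and package version, so every output file
#' is traceable to one manifest.
#'
#' @param ts a \code{sim_timeseries}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_timeseries_csv <- function(ts, path) {
  df <- data.frame(mcs = ts$mcs, ts$fractions, check.names = FALSE)
  names(df) <- c("mcs", paste0("f_", colnames(ts$fractions)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  manifest <- list(
    config = config_as_list(ts$config),
    replicate = ts$replicate,
    effective_seed = ts$config$seed + ts$replicate - 1L,
    extinct_mcs = as.list(ts$extinct_mcs),
    absorbed_at = ts$absorbed_at,
    package_version = as.character(utils::packageVersion("crimelattice")),
    output = basename(path))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write a phase diagram as tidy CSV plus a JSON summary
#'
#' One CSV row per grid point: the swept parameter value, the surviving-set
#' string (e.g. \code{"O+C+P"}), per-strategy mean stationary fractions and
#' the unresolved flag. The JSON summary holds the ordered phase sequence
#' and the transition list.
#'
#' @param diagram a \code{phase_diagram}.
#' @param path output CSV path; the summary goes to
#'   \code{<path>.summary.json}.
#' @return The path, invisibly.
#' @export
write_phase_csv <- function(diagram, path) {
  fr <- do.call(rbind, lapply(diagram$points, `[[`, "fractions"))
  df <- data.frame(diagram$values, phase = diagram$phases,
                   fr, unresolved = diagram$unresolved,
                   check.names = FALSE)
  names(df)[1] <- diagram$axis
  names(df)[2 + seq_len(ncol(fr))] <- paste0("f_", colnames(fr))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  summary <- list(axis = diagram$axis,
                  phase_sequence = phase_sequence(diagram),
                  n_transitions = nrow(diagram$transitions),
                  transitions = diagram$transitions)
  jsonlite::write_json(summary, paste0(path, ".summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
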