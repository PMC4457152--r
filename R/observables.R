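#' Test a trajectory for stationarity
#'
#' A trajectory is called stationary once the time averages of the strategy
#' fractions stop changing: for every strategy, the means over two
#' consecutive non-overlapping windows of \code{window} MCS differ by at
#' most \code{tol}. The onset is the first sampled MCS at which the
#' criterion holds (the end of the second window).
#'
#' @param ts a \code{sim_timeseries}.
#' @param window window length in MCS.
#' @param tol absolute tolerance on the per-strategy window means.
#' @return List with \code{stationary} (TRUE/FALSE, or NA when the series is
#'   shorter than two windows — inconclusive, distinct from FALSE),
#'   \code{onset_mcs} (first sampled MCS at which the criterion holds, NA
#'   unless stationary) and \code{stationary_since} (start of the certified
#'   stationary stretch, \code{onset_mcs - 2 * window}: the two agreeing
#'   windows cover that interval, so the fractions had stopped drifting from
#'   that time on — the natural measure of the MCS needed to reach the
#'   stationary state, free of the detector's two-window confirmation lag).
#' @export
is_stationary <- function(ts, window = 100, tol = 0.01) {
  mcs <- ts$mcs
  f <- ts$fractions
  span <- mcs[length(mcs)] - mcs[1L]
  if (span < 2 * window) {
    return(list(stationary = NA, onset_mcs = NA_real_,
                stationary_since = NA_real_))
  }
  # candidate onsets: every sampled time t with t >= first + 2*window
  for (i in seq_along(mcs)) {
    t2 <- mcs[i]
    if (t2 - mcs[1L] < 2 * window) next
    w2 <- mcs > t2 - window & mcs <= t2
    w1 <- mcs > t2 - 2 * window & mcs <= t2 - window
    if (!any(w1) || !any(w2)) next
    m1 <- colMeans(f[w1, , drop = FALSE])
    m2 <- colMeans(f[w2, , drop = FALSE])
    if (all(abs(m1 - m2) <= tol)) {
      return(list(stationary = TRUE, onset_mcs = t2,
                  stationary_since = t2 - 2 * window))
    }
  }
  list(stationary = FALSE, onset_mcs = NA_real_, stationary_since = NA_real_)
}

# time-averaged fractions over the final averaging window of one run
stationary_window_mean <- function(ts) {
  keep <- ts$mcs >= ts$config$relaxation_mcs
  if (!any(keep)) keep <- seq_along(ts$mcs) == length(ts$mcs)
  colMeans(ts$fractions[keep, , drop = FALSE])
}

#' Classify a parameter point by its surviving strategies
#'
#' Runs \code{replicates} independent simulations and decides, by majority
#' vote across replicates, which strategies survive in the stationary state.
#' In a single replicate a strategy survives if its final site count is
#' positive and its time-averaged stationary fraction exceeds
#' \code{eps_extinct} (a noise floor against single stray sites on finite
#' lattices). On a tie the number of replicates is doubled once; a
#' persistent tie or no stationary replicate flags the point unresolved.
#'
#' @param config a \code{\link{simulation_config}}; its \code{replicates}
#'   field sets the default replicate count.
#' @param replicates number of replicates (overrides the config).
#' @param eps_extinct extinction threshold on the time-averaged fraction.
#' @param window,tol stationarity criterion, see \code{\link{is_stationary}}.
#' @return A \code{phase_point}: list with \code{params}, \code{surviving}
#'   (character vector), \code{fractions} (mean stationary fractions across
#'   replicates), \code{onset_mcs} (median over stationary replicates),
#'   \code{agreement} (replicates voting with the majority),
#'   \code{unresolved} flag.
#' @export
classify_point <- function(config, replicates = config$replicates,
                           eps_extinct = 1e-3, window = 100, tol = 0.01) {
  vote <- function(n_rep, seed0) {
    surv <- NULL; fr <- NULL; onset <- numeric(0)
    for (r in seq_len(n_rep)) {
      ts <- run_simulation(config, replicate = seed0 + r - 1L)
      st <- is_stationary(ts, window = window, tol = tol)
      fmean <- stationary_window_mean(ts)
      final_counts <- strategy_counts(ts$final_state)
      alive <- final_counts > 0 & fmean > eps_extinct
      surv <- rbind(surv, alive)
      fr <- rbind(fr, fmean)
      if (isTRUE(st$stationary)) onset <- c(onset, st$onset_mcs)
    }
    list(surv = surv, fr = fr, onset = onset)
  }
  v <- vote(replicates, 1L)
  if (length(v$onset) == 0) {
    return(structure(list(params = config$params, surviving = character(0),
                          fractions = colMeans(v$fr), onset_mcs = NA_real_,
                          agreement = 0L, unresolved = TRUE,
                          config = config),
                     class = "phase_point"))
  }
  tally <- colSums(v$surv)
  tie <- any(tally * 2 == replicates)
  if (tie) {
    extra <- vote(replicates, replicates + 1L)
    v$surv <- rbind(v$surv, extra$surv)
    v$fr <- rbind(v$fr, extra$fr)
    v$onset <- c(v$onset, extra$onset)
    tally <- colSums(v$surv)
    replicates <- nrow(v$surv)
  }
  unresolved <- any(tally * 2 == replicates)
  majority <- tally * 2 > replicates
  labels <- colnames(v$surv) %||% strategy_set(config$variant)
  surviving <- strategy_set(config$variant)[majority]
  # fractions averaged over replicates agreeing with the majority set
  agree <- apply(v$surv, 1, function(a) all(a == majority))
  fr_use <- if (any(agree)) v$fr[agree, , drop = FALSE] else v$fr
  structure(list(params = config$params, surviving = as.character(surviving),
                 fractions = colMeans(fr_use),
                 onset_mcs = stats::median(v$onset),
                 agreement = sum(agree), unresolved = unresolved,
                 config = config),
            class = "phase_point")
}

#' @export
print.phase_point <- function(x, ...) {
  cat("phase_point:",
      if (x$unresolved) "[UNRESOLVED]" else paste(x$surviving, collapse = "+"),
      sprintf("(alpha=%.2f beta=%.2f gamma=%.2f)",
              x$params$alpha, x$params$beta, x$params$gamma), "\n")
  cat("fractions:",
      paste(sprintf("%s=%.3f", names(x$fractions), x$fractions),
            collapse = " "), "\n")
  invisible(x)
}

#' Sweep one payoff parameter and enumerate phase transitions
#'
#' Classifies every grid value along one parameter axis and records a phase
#' transition wherever the surviving-strategy set changes between
#' consecutive resolved grid points. The reported transition location is
#' the midpoint of the two grid values; unresolved points are excluded from
#' transition counting and flagged.
#'
#' @param axis parameter name: \code{"beta"}, \code{"gamma"} or
#'   \code{"alpha"}.
#' @param values strictly increasing numeric grid, length >= 2.
#' @param base_config a \code{\link{simulation_config}} providing all other
#'   settings; each grid point reuses its seed policy.
#' @param replicates replicates per point.
#' @param ... passed to \code{\link{classify_point}}.
#' @return A \code{phase_diagram}: list with \code{axis}, \code{values},
#'   \code{points} (list of \code{phase_point}), \code{phases} (surviving-set
#'   strings), \code{transitions} (data.frame: location, from, to),
#'   \code{unresolved} (logical vector).
#' @export
sweep_phase <- function(axis = c("beta", "gamma", "alpha"), values,
                        base_config, replicates = base_config$replicates,
                        ...) {
  axis <- match.arg(axis)
  stopifnot(length(values) >= 2, all(diff(values) > 0))
  points <- vector("list", length(values))
  for (i in seq_along(values)) {
    p <- base_config$params
    p[[axis]] <- values[i]
    cfg <- base_config
    cfg$params <- payoff_params(p$alpha, p$beta, p$gamma, p$fine)
    points[[i]] <- classify_point(cfg, replicates = replicates, ...)
  }
  phases <- vapply(points, function(p) paste(p$surviving, collapse = "+"),
                   character(1))
  unresolved <- vapply(points, `[[`, logical(1), "unresolved")
  trans <- data.frame(location = numeric(0), from = character(0),
                      to = character(0))
  res_idx <- which(!unresolved)
  for (k in seq_along(res_idx)[-1]) {
    i <- res_idx[k - 1L]; j <- res_idx[k]
    if (phases[i] != phases[j]) {
      trans <- rbind(trans, data.frame(
        location = (values[i] + values[j]) / 2,
        from = phases[i], to = phases[j]))
    }
  }
  structure(list(axis = axis, values = values, points = points,
                 phases = phases, transitions = trans,
                 unresolved = unresolved),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("phase_diagram along", x$axis, "with", length(x$values), "points\n")
  seq_str <- rle(x$phases)$values
  cat("phase sequence:", paste(seq_str, collapse = " -> "), "\n")
  cat(nrow(x$transitions), "transitions")
  if (any(x$unresolved)) cat(" |", sum(x$unresolved), "unresolved points")
  cat("\n")
  invisible(x)
}

#' Ordered sequence of distinct phases along a sweep
#' @param diagram a \code{phase_diagram}.
#' @param drop_unresolved exclude unresolved grid points first.
#' @return Character vector of surviving-set strings in grid order with
#'   consecutive duplicates collapsed.
#' @export
phase_sequence <- function(diagram, drop_unresolved = TRUE) {
  ph <- diagram$phases
  if (drop_unresolved) ph <- ph[!diagram$unresolved]
  rle(ph)$values
}

#' Two-strategy invasion experiment
#'
#' Starts from two half-lattice vertical blocks of the given strategies so
#' that the motion of the single interface decides the outcome, runs the
#' dynamics (which never reintroduces absent strategies), and classifies the
#' stationary survivor set over replicates.
#'
#' @param s_a,s_b strategy labels, both valid for the variant.
#' @param config a \code{\link{simulation_config}} for the variant and
#'   parameters; its init spec is replaced by the two-block state.
#' @param replicates replicates for the majority vote.
#' @param ... passed to \code{\link{classify_point}}.
#' @return List with \code{outcome} (\code{"a_wins"}, \code{"b_wins"},
#'   \code{"coexistence"} or \code{"inconclusive"}) and the underlying
#'   \code{phase_point}.
#' @export
pairwise_invasion <- function(s_a, s_b, config,
                              replicates = config$replicates, ...) {
  labels <- strategy_set(config$variant)
  stopifnot(s_a %in% labels, s_b %in% labels, s_a != s_b)
  cfg <- config
  cfg$init <- list(mode = "blocks",
                   blocks = list(list(strategy = s_a, width = 0.5),
                                 list(strategy = s_b, width = 0.5)))
  pt <- classify_point(cfg, replicates = replicates, ...)
  outcome <- if (pt$unresolved) {
    "inconclusive"
  } else if (setequal(pt$surviving, s_a)) {
    "a_wins"
  } else if (setequal(pt$surviving, s_b)) {
    "b_wins"
  } else {
    "coexistence"
  }
  list(outcome = outcome, point = pt)
}

#' Mean stationary fraction of one strategy
#'
#' Time-averages the strategy's fraction over each replicate's
#' post-relaxation window, then averages across replicates.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param strategy strategy label.
#' @param replicates number of replicates.
#' @return List with \code{mean}, \code{se} (standard error across
#'   replicates), and the per-replicate values.
#' @export
stationary_fraction <- function(config, strategy,
                                replicates = config$replicates) {
  labels <- strategy_set(config$variant)
  stopifnot(strategy %in% labels)
  vals <- vapply(seq_len(replicates), function(r) {
    ts <- run_simulation(config, replicate = r)
    stationary_window_mean(ts)[[strategy]]
  }, numeric(1))
  list(mean = mean(vals),
       se = if (replicates > 1) stats::sd(vals) / sqrt(replicates) else 0,
       values = vals)
}
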