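#' Fermi strategy-adoption probability
#'
#' Probability that the focal player x adopts the strategy of neighbor y:
#' \code{W = 1 / (1 + exp((pi_x - pi_y) / K))}. Better-performing neighbors
#' are readily imitated; imitating a worse-performing neighbor remains
#' possible at finite K, modelling imperfect information. The exponent is
#' clamped at |700| so extreme payoff differences saturate to 0 or 1 without
#' overflow.
#'
#' @param pi_x,pi_y accumulated payoffs of the focal player and the neighbor.
#' @param K strategy-adoption noise, > 0 (payoff units). The standard value
#'   is 0.5.
#' @return Adoption probability in (0, 1) (up to floating-point saturation).
#' @export
#' @examples
#' fermi_probability(0, 0, 0.5)      # 0.5
#' fermi_probability(-2, 0, 0.5)     # ~0.982
fermi_probability <- function(pi_x, pi_y, K) {
  if (any(K <= 0)) stop("K must be strictly positive", call. = FALSE)
  if (!all(is.finite(pi_x), is.finite(pi_y))) {
    stop("payoffs must be finite", call. = FALSE)
  }
  d <- pmin(pmax((pi_x - pi_y) / K, -700), 700)
  1 / (1 + exp(d))
}

#' Accumulated payoff of a lattice site
#'
#' Sums the focal player's pairwise payoff against each of its four von
#' Neumann neighbors on the periodic lattice.
#'
#' @param state a \code{lattice_state}.
#' @param site 0-based \code{c(row, col)}.
#' @param matrix payoff matrix for the state's variant.
#' @return Total payoff (numeric scalar).
#' @export
site_payoff <- function(state, site, matrix) {
  nb <- neighbors(site, state$L)
  s <- state$grid[site[1L] + 1L, site[2L] + 1L]
  pi <- 0
  for (i in 1:4) {
    so <- state$grid[nb[i, 1L] + 1L, nb[i, 2L] + 1L]
    pi <- pi + matrix[s, so]
  }
  pi
}

#' One elementary Monte Carlo step (reference implementation)
#'
#' Literal transcription of the update protocol: draw a site x uniformly,
#' compute its payoff fresh from the current grid, draw one of its four
#' neighbors y uniformly, compute y's payoff fresh, then let x adopt y's
#' strategy with the Fermi probability. Exactly three uniform draws are
#' consumed (site, neighbor, acceptance) in that order, matching the
#' compiled kernel draw for draw; self-imitation is an accepted no-op.
#' At most one site changes.
#'
#' @param state a \code{lattice_state}.
#' @param matrix payoff matrix (label dimnames; row = focal).
#' @param K adoption noise, > 0.
#' @return The updated \code{lattice_state}.
#' @export
elementary_step <- function(state, matrix, K) {
  L <- state$L
  N <- L * L
  m <- unname(matrix)
  idx <- floor(stats::runif(1) * N)        # 0-based column-major linear index
  row <- idx %% L
  col <- idx %/% L
  pix <- site_payoff(state, c(row, col), m)
  k <- floor(stats::runif(1) * 4) + 1L     # 1=up 2=down 3=left 4=right
  nb <- neighbors(c(row, col), L)[k, ]
  piy <- site_payoff(state, nb, m)
  u <- stats::runif(1)
  if (u < fermi_probability(pix, piy, K)) {
    state$grid[row + 1L, col + 1L] <- state$grid[nb[1L] + 1L, nb[2L] + 1L]
  }
  state
}

#' Simulation configuration
#'
#' @param variant game variant, see \code{\link{strategy_set}}.
#' @param params a \code{\link{payoff_params}} object (or alpha/beta/gamma
#'   given individually).
#' @param L lattice side length, >= 4.
#' @param K adoption noise, default 0.5.
#' @param max_mcs Monte Carlo step budget (one MCS = L^2 elementary steps).
#' @param sample_every MCS between fraction samples, >= 1.
#' @param relaxation_mcs burn-in discarded before averaging, < max_mcs.
#' @param seed integer RNG seed; replicate r runs with seed + r - 1.
#' @param init initial-state spec: list with \code{mode} and, as needed,
#'   \code{weights} or \code{blocks} (see \code{\link{init_state}}).
#' @param replicates number of independent runs.
#' @param alpha,beta,gamma used only when \code{params} is missing.
#' @return A \code{sim_config} list.
#' @export
simulation_config <- function(variant, params = NULL, L = 100, K = 0.5,
                              max_mcs = 1000, sample_every = 1,
                              relaxation_mcs = NULL, seed = 1,
                              init = list(mode = "uniform_random"),
                              replicates = 1,
                              alpha = 0.5, beta = NULL, gamma = NULL) {
  variant <- match_variant(variant)
  if (is.null(params)) {
    if (is.null(beta) || is.null(gamma)) {
      stop("either 'params' or both 'beta' and 'gamma' must be given",
           call. = FALSE)
    }
    params <- payoff_params(alpha, beta, gamma)
  }
  if (K <= 0) stop("K must be strictly positive", call. = FALSE)
  if (is.null(relaxation_mcs)) relaxation_mcs <- max(0, max_mcs - 200)
  if (max_mcs < relaxation_mcs || relaxation_mcs < 0) {
    stop("need max_mcs >= relaxation_mcs >= 0", call. = FALSE)
  }
  if (sample_every < 1) stop("sample_every must be >= 1", call. = FALSE)
  if (!is.null(init$weights)) {
    bad <- setdiff(names(init$weights), strategy_set(variant))
    if (length(bad)) {
      stop("init weights name strategies outside the variant: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(variant = variant, params = params, L = as.integer(L),
                 K = K, max_mcs = as.integer(max_mcs),
                 sample_every = as.integer(sample_every),
                 relaxation_mcs = as.integer(relaxation_mcs),
                 seed = as.integer(seed), init = init,
                 replicates = as.integer(replicates)),
            class = "sim_config")
}

make_initial_state <- function(config) {
  init <- config$init
  init_state(config$variant, config$L,
             mode = init$mode %||% "uniform_random",
             weights = init$weights, blocks = init$blocks, seed = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a Monte Carlo simulation
#'
#' Performs \code{max_mcs} sweeps of \code{L^2} elementary Fermi-imitation
#' steps each, sampling per-strategy fractions every \code{sample_every}
#' MCS. Reproducible: the replicate's seed fixes the initial state and the
#' whole trajectory. Extinction events (a strategy's count reaching zero)
#' are recorded with their MCS time.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param replicate replicate number (>= 1); the RNG is seeded with
#'   \code{config$seed + replicate - 1}.
#' @param engine \code{"kernel"} (compiled, default) or \code{"reference"}
#'   (literal pure-R transcription of the update protocol; identical
#'   trajectories for identical seeds, used for validation).
#' @param stop_on_absorb stop early once the lattice is homogeneous
#'   (absorbing state).
#' @return A \code{sim_timeseries}: list with \code{mcs} (sampled times),
#'   \code{fractions} (samples x strategies matrix), \code{counts},
#'   \code{final_state}, \code{extinct_mcs}, \code{absorbed_at}.
#' @export
run_simulation <- function(config, replicate = 1,
                           engine = c("kernel", "reference"),
                           stop_on_absorb = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + replicate - 1L)
  state <- make_initial_state(config)
  m <- build_payoff_matrix(config$params, config$variant)

  if (engine == "kernel") {
    res <- .mc_run_cpp(state$grid - 1L, unname(m), config$K,
                       config$max_mcs, config$sample_every, stop_on_absorb)
    final <- lattice_state(res$grid + 1L, config$variant)
    counts <- res$sample_counts
    mcs <- as.numeric(res$sample_mcs)
    extinct <- setNames(as.integer(res$extinct_mcs), state$labels)
    absorbed <- res$absorbed_at
  } else {
    res <- run_reference(state, m, config$K, config$max_mcs,
                         config$sample_every, stop_on_absorb)
    final <- res$state
    counts <- res$sample_counts
    mcs <- res$sample_mcs
    extinct <- res$extinct_mcs
    absorbed <- res$absorbed_at
  }
  colnames(counts) <- state$labels
  structure(list(mcs = mcs,
                 counts = counts,
                 fractions = counts / config$L^2,
                 final_state = final,
                 extinct_mcs = extinct,
                 absorbed_at = absorbed,
                 config = config, replicate = replicate),
            class = "sim_timeseries")
}

#' Advance an existing lattice state by a number of Monte Carlo steps
#'
#' Runs the compiled Fermi-imitation kernel on the given state and returns
#' the updated state. Uses the current global RNG stream (seed it with
#' \code{set.seed} for reproducibility); useful for checkpointed runs such
#' as interface-motion snapshot series.
#'
#' @param state a \code{lattice_state}.
#' @param params a \code{\link{payoff_params}}.
#' @param K adoption noise, > 0.
#' @param mcs number of Monte Carlo steps to advance.
#' @return The updated \code{lattice_state}.
#' @export
advance_state <- function(state, params, K, mcs) {
  if (K <= 0) stop("K must be strictly positive", call. = FALSE)
  m <- build_payoff_matrix(params, state$variant)
  res <- .mc_run_cpp(state$grid - 1L, unname(m), K, as.integer(mcs), 0L, FALSE)
  lattice_state(res$grid + 1L, state$variant)
}

# Plain-R sweep loop around elementary_step(); same draw order as the
# compiled kernel, so seeded trajectories agree exactly.
run_reference <- function(state, m, K, max_mcs, sample_every, stop_on_absorb) {
  L <- state$L
  N <- L * L
  S <- length(state$labels)
  n_samples <- 1L + if (sample_every > 0) max_mcs %/% sample_every else 0L
  samp <- matrix(0L, n_samples, S)
  samp_mcs <- numeric(n_samples)
  cnt <- tabulate(state$grid, nbins = S)
  samp[1L, ] <- cnt
  isamp <- 1L
  extinct <- setNames(rep(NA_integer_, S), state$labels)
  extinct[cnt == 0L] <- 0L
  absorbed <- NA_integer_
  sweep_done <- 0L
  for (sweep in seq_len(max_mcs)) {
    for (step in seq_len(N)) {
      prev <- state$grid
      state <- elementary_step(state, m, K)
      changed <- which(state$grid != prev)
      if (length(changed)) {
        old <- prev[changed]; new <- state$grid[changed]
        cnt[old] <- cnt[old] - 1L
        cnt[new] <- cnt[new] + 1L
        if (cnt[old] == 0L && is.na(extinct[old])) extinct[old] <- sweep
      }
    }
    sweep_done <- sweep
    if (sample_every > 0 && sweep %% sample_every == 0L &&
        isamp < n_samples) {
      isamp <- isamp + 1L
      samp[isamp, ] <- cnt
      samp_mcs[isamp] <- sweep
    }
    if (stop_on_absorb && any(cnt == N)) break
  }
  if (any(cnt == N)) absorbed <- sweep_done
  list(state = state,
       sample_mcs = samp_mcs[seq_len(isamp)],
       sample_counts = samp[seq_len(isamp), , drop = FALSE],
       extinct_mcs = extinct, absorbed_at = absorbed)
}

#' @export
print.sim_timeseries <- function(x, ...) {
  n <- nrow(x$fractions)
  cat("sim_timeseries:", x$config$variant, "L =", x$config$L,
      "| sampled", n, "times up to MCS", x$mcs[n], "\n")
  f <- x$fractions[n, ]
  cat("final fractions:",
      paste(sprintf("%s=%.3f", colnames(x$fractions), f), collapse = " "), "\n")
  invisible(x)
}
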