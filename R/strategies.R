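#' Strategy sets of the spatial inspection game
#'
#' Three game variants are supported:
#' \describe{
#'   \item{\code{three_strategy}}{ordinary people \code{O}, criminals \code{C},
#'     and uniform punishers \code{P} bearing the full punishment cost.}
#'   \item{\code{five_strategy}}{\code{O}, \code{C}, and three punisher classes
#'     \code{L}, \code{M}, \code{H} committing 1/3, 2/3 and the full
#'     punishment effort, respectively. \code{H} behaves identically to
#'     \code{P} of the three-strategy game.}
#'   \item{\code{minimal_CLM}}{the five-strategy payoff structure restricted
#'     to \code{C}, \code{L} and \code{M}; used to study interface motion
#'     between criminal and punisher domains.}
#' }
#'
#' @param variant one of \code{"three_strategy"}, \code{"five_strategy"},
#'   \code{"minimal_CLM"}.
#' @return Character vector of strategy labels, with a \code{"rank"} attribute
#'   giving each strategy's punisher commitment fraction (0 for \code{O} and
#'   \code{C}; 1/3, 2/3, 1 for \code{L}, \code{M}, \code{H}/\code{P}).
#' @export
#' @examples
#' strategy_set("minimal_CLM")
strategy_set <- function(variant) {
  variant <- match_variant(variant)
  labels <- switch(variant,
    three_strategy = c("O", "C", "P"),
    five_strategy  = c("O", "C", "L", "M", "H"),
    minimal_CLM    = c("C", "L", "M")
  )
  attr(labels, "rank") <- strategy_rank(labels)
  labels
}

#' @rdname strategy_set
#' @export
game_variants <- function() c("three_strategy", "five_strategy", "minimal_CLM")

match_variant <- function(variant) {
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% game_variants()) {
    stop("unknown game variant: ", paste(variant, collapse = ","),
         " (expected one of ", paste(game_variants(), collapse = ", "), ")",
         call. = FALSE)
  }
  variant
}

# commitment fraction r of each strategy label
strategy_rank <- function(labels) {
  r <- c(O = 0, C = 0, L = 1 / 3, M = 2 / 3, H = 1, P = 1)
  unname(r[labels])
}

is_punisher <- function(labels) labels %in% c("L", "M", "H", "P")

#' Payoff parameters of the inspection game
#'
#' Bundles the three payoff parameters: the punishment cost \code{alpha}
#' borne by a fully committed punisher in every interaction, the
#' temptation/loss \code{beta} (the criminal's gain from an ordinary victim
#' and, symmetrically, the victim's loss), and the reward \code{gamma}
#' collected by a fully committed punisher when facing a criminal. The
#' punishment fine imposed on a criminal facing a full punisher is normalized
#' to 1; punishers of rank r impose the fine, pay the cost and collect the
#' reward scaled by r.
#'
#' @param alpha punishment cost, dimensionless payoff units, >= 0.
#' @param beta temptation to crime / victim loss, >= 0.
#' @param gamma reward for punishing criminals, >= 0.
#' @param fine normalized punishment fine, fixed at 1.
#' @return An object of class \code{payoff_params}.
#' @export
payoff_params <- function(alpha = 0.5, beta, gamma, fine = 1) {
  vals <- c(alpha = alpha, beta = beta, gamma = gamma, fine = fine)
  if (!all(is.finite(vals))) {
    stop("payoff parameters must be finite numbers", call. = FALSE)
  }
  if (alpha < 0 || beta < 0 || gamma < 0) {
    stop("alpha, beta and gamma must be non-negative", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, fine = fine),
            class = "payoff_params")
}

#' Build the pairwise payoff matrix of a game variant
#'
#' Returns the focal-vs-opponent payoff table. With commitment rank r
#' (1/3 for L, 2/3 for M, 1 for H and P, 0 otherwise) the entries are:
#' ordinary people get \code{-beta} against a criminal and 0 otherwise;
#' a criminal gets \code{beta} against an ordinary victim, 0 against another
#' criminal, and \code{beta - r * fine} against a punisher of rank r;
#' a punisher of rank r gets \code{r * (gamma - alpha)} against a criminal
#' and pays the inspection cost \code{-r * alpha} in every other interaction.
#' Payoffs are per pairwise interaction and are summed over the four lattice
#' neighbors by the dynamics.
#'
#' @param params a \code{\link{payoff_params}} object.
#' @param variant game variant name, see \code{\link{strategy_set}}.
#' @return Numeric matrix with strategy labels as dimnames; rows are the
#'   focal player, columns the opponent.
#' @export
#' @examples
#' build_payoff_matrix(payoff_params(0.5, 0.8, 0.8), "three_strategy")
build_payoff_matrix <- function(params, variant) {
  stopifnot(inherits(params, "payoff_params"))
  labels <- strategy_set(variant)
  rank <- attr(labels, "rank")
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(focal = as.character(labels),
                                       opponent = as.character(labels)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- pair_entry(labels[i], rank[i], labels[j], rank[j], params)
    }
  }
  m
}

pair_entry <- function(sf, rf, so, ro, p) {
  if (sf == "O") {
    if (so == "C") -p$beta else 0
  } else if (sf == "C") {
    if (so == "O") p$beta
    else if (so == "C") 0
    else p$beta - ro * p$fine
  } else {
    # punisher of rank rf: reward net of cost vs C, inspection cost otherwise
    if (so == "C") rf * (p$gamma - p$alpha) else -rf * p$alpha
  }
}

#' Look up the payoff of a focal strategy against an opponent
#'
#' @param matrix payoff matrix from \code{\link{build_payoff_matrix}}.
#' @param focal,opponent strategy labels present in the matrix.
#' @return The focal player's per-interaction payoff.
#' @export
pair_payoff <- function(matrix, focal, opponent) {
  labels <- rownames(matrix)
  if (!(focal %in% labels) || !(opponent %in% labels)) {
    stop("strategy not in this variant: ",
         paste(setdiff(c(focal, opponent), labels), collapse = ", "),
         call. = FALSE)
  }
  matrix[focal, opponent]
}

#' Write a payoff matrix as CSV
#'
#' Plain CSV with a header row and a leading label column, for inspection
#' and golden-file comparisons.
#'
#' @param matrix payoff matrix.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_payoff_csv <- function(matrix, path) {
  df <- data.frame(strategy = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
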