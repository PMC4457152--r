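#' Periodic von Neumann neighbors of a lattice site
#'
#' Sites are 0-based \code{(row, col)} pairs on an \code{L x L} torus,
#' row-major. Neighbors are returned in the fixed order up, down, left,
#' right, which the Monte Carlo engine relies on for reproducibility.
#'
#' @param site integer vector \code{c(row, col)}, 0-based.
#' @param L lattice side length, >= 4.
#' @return 4 x 2 integer matrix of neighbor coordinates.
#' @export
#' @examples
#' neighbors(c(0, 0), 4)
neighbors <- function(site, L) {
  stopifnot(length(site) == 2L, L >= 4)
  r <- site[1L]; c <- site[2L]
  if (r < 0 || r >= L || c < 0 || c >= L) {
    stop("site out of range for L = ", L, call. = FALSE)
  }
  rbind(
    up    = c((r - 1) %% L, c),
    down  = c((r + 1) %% L, c),
    left  = c(r, (c - 1) %% L),
    right = c(r, (c + 1) %% L)
  )
}

#' Generate an initial lattice configuration
#'
#' Three modes are supported. \code{uniform_random} assigns each site an
#' independent uniform draw over the variant's strategies (the standard
#' starting condition). \code{weighted_random} uses the given per-strategy
#' probabilities. \code{blocks} tiles the lattice with vertical stripes in
#' the listed order, the prepared initial state used to study the motion of
#' interfaces between strategy domains.
#'
#' @param variant game variant, see \code{\link{strategy_set}}.
#' @param L lattice side length, >= 4.
#' @param mode \code{"uniform_random"}, \code{"weighted_random"} or
#'   \code{"blocks"}.
#' @param weights named numeric vector of per-strategy probabilities
#'   (\code{weighted_random} only); normalized internally.
#' @param blocks list of \code{list(strategy =, width =)} entries with stripe
#'   width fractions summing to 1 (\code{blocks} only). Defaults to
#'   equal-width stripes over the variant's strategies.
#' @param seed optional integer; when given the global RNG is seeded so the
#'   configuration is reproducible.
#' @return A \code{lattice_state}: list with integer matrix \code{grid}
#'   (1-based strategy indices), \code{labels}, \code{variant}, \code{L}.
#' @export
init_state <- function(variant, L,
                       mode = c("uniform_random", "weighted_random", "blocks"),
                       weights = NULL, blocks = NULL, seed = NULL) {
  mode <- match.arg(mode)
  labels <- strategy_set(variant)
  n <- length(labels)
  stopifnot(L >= 4)
  if (!is.null(seed)) set.seed(seed)

  if (mode == "uniform_random") {
    codes <- sample.int(n, L * L, replace = TRUE)
    grid <- matrix(codes, nrow = L, ncol = L)
  } else if (mode == "weighted_random") {
    if (is.null(weights) || is.null(names(weights))) {
      stop("weighted_random mode needs a named 'weights' vector", call. = FALSE)
    }
    bad <- setdiff(names(weights), labels)
    if (length(bad)) {
      stop("weights name strategies outside the variant: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(weights < 0) || sum(weights) <= 0) {
      stop("weights must be non-negative with positive sum", call. = FALSE)
    }
    p <- setNames(numeric(n), labels)
    p[names(weights)] <- weights
    p <- p / sum(p)
    codes <- sample.int(n, L * L, replace = TRUE, prob = p)
    grid <- matrix(codes, nrow = L, ncol = L)
  } else {
    if (is.null(blocks)) {
      blocks <- lapply(labels, function(s) list(strategy = s, width = 1 / n))
    }
    strat <- vapply(blocks, `[[`, character(1), "strategy")
    width <- vapply(blocks, `[[`, numeric(1), "width")
    bad <- setdiff(strat, labels)
    if (length(bad)) {
      stop("block strategies outside the variant: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (abs(sum(width) - 1) > 1e-8) {
      stop("block stripe widths must sum to 1", call. = FALSE)
    }
    # vertical stripes: column bands left to right
    edges <- round(cumsum(c(0, width)) * L)
    grid <- matrix(0L, nrow = L, ncol = L)
    for (b in seq_along(strat)) {
      cols <- seq.int(edges[b] + 1L, edges[b + 1L])
      grid[, cols] <- match(strat[b], labels)
    }
  }
  lattice_state(grid, variant)
}

lattice_state <- function(grid, variant) {
  labels <- strategy_set(variant)
  structure(list(grid = grid, labels = as.character(labels),
                 variant = variant, L = nrow(grid)),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cat("lattice_state:", x$L, "x", x$L, x$variant, "\n")
  f <- strategy_counts(x) / x$L^2
  cat("fractions:", paste(sprintf("%s=%.3f", names(f), f), collapse = " "), "\n")
  invisible(x)
}

#' Per-strategy site counts of a lattice state
#' @param state a \code{lattice_state}.
#' @return Named integer vector over the variant's strategies.
#' @export
strategy_counts <- function(state) {
  tab <- tabulate(state$grid, nbins = length(state$labels))
  setNames(tab, state$labels)
}

#' Write a lattice snapshot as plain text
#'
#' One character per site (the strategy label), one lattice row per line.
#'
#' @param state a \code{lattice_state}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_snapshot_txt <- function(state, path) {
  ch <- matrix(state$labels[state$grid], nrow = state$L)
  writeLines(apply(ch, 1, paste0, collapse = ""), path)
  invisible(path)
}

#' Read a plain-text lattice snapshot
#' @param path file written by \code{\link{write_snapshot_txt}}.
#' @param variant game variant of the snapshot.
#' @return A \code{lattice_state}.
#' @export
read_snapshot_txt <- function(path, variant) {
  lines <- readLines(path)
  labels <- strategy_set(variant)
  grid <- t(vapply(strsplit(lines, ""),
                   function(ch) match(ch, labels), integer(nchar(lines[1]))))
  if (anyNA(grid)) stop("snapshot contains strategies outside the variant",
                        call. = FALSE)
  lattice_state(grid, variant)
}

# color convention: red = C, light blue = L, dark blue = M; O grey, H/P navy
strategy_colors <- function(labels) {
  pal <- c(O = "#BDBDBD", C = "#D62728", L = "#9ECAE1",
           M = "#2171B5", H = "#08306B", P = "#08306B")
  pal[labels]
}

#' Write a lattice snapshot as a PNG raster
#'
#' One pixel per site, using the domain color convention (red criminals,
#' light blue mild punishers L, dark blue M, near-black blue H/P, grey O).
#' Requires the \pkg{png} package.
#'
#' @param state a \code{lattice_state}.
#' @param path output PNG path.
#' @param scale integer pixel size per site.
#' @return The path, invisibly.
#' @export
write_snapshot_png <- function(state, path, scale = 2L) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG snapshots", call. = FALSE)
  }
  cols <- grDevices::col2rgb(strategy_colors(state$labels)) / 255
  L <- state$L
  img <- array(0, dim = c(L, L, 3))
  for (k in 1:3) img[, , k] <- matrix(cols[k, state$grid], nrow = L)
  if (scale > 1L) {
    idx <- rep(seq_len(L), each = scale)
    img <- img[idx, idx, , drop = FALSE]
  }
  png::writePNG(img, path)
  invisible(path)
}
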