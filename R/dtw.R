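## Dynamic time warping over multivariate standardized streams.

#' Pointwise local distance between two frames
#'
#' Euclidean distance over the standardized gyroscope axes; the elementary
#' cost that the warping path accumulates.
#'
#' @param x_frame,y_frame numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
local_distance <- function(x_frame, y_frame) {
  if (length(x_frame) != length(y_frame)) {
    stop("frame dimension mismatch: ", length(x_frame), " vs ",
         length(y_frame), call. = FALSE)
  }
  sqrt(sum((x_frame - y_frame)^2))
}

as_frame_matrix <- function(x) {
  if (inherits(x, "clean_segment")) x <- x$frames
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1)
  storage.mode(x) <- "double"
  x
}

normalize_cost <- function(acc, rule, n_pairs, n, m) {
  switch(rule,
         aligned_pairs = acc / n_pairs,
         reference_length = acc / n,
         query_length = acc / m,
         sum_lengths = acc / (n + m))
}

new_warp_result <- function(path, acc, pattern, n, m) {
  nd <- normalize_cost(acc, pattern$normalization_rule, nrow(path), n, m)
  structure(list(path = path, accumulated_cost = acc,
                 normalized_distance = nd, pattern_id = pattern$id,
                 N = n, M = m), class = "warp_result")
}

#' Align two sequences by dynamic time warping
#'
#' Finds the minimum accumulated-cost alignment path under a step
#' pattern's local continuity constraints, with both endpoints anchored at
#' `(1, 1)` and `(N, M)`. The default normalized distance is the
#' accumulated cost divided by the number of aligned index pairs on the
#' optimal path, i.e. the average pairwise distance at each aligned data
#' point. Ties between equal-cost productions are broken toward the plain
#' diagonal transition, so the output is deterministic.
#'
#' @param x,y sequences: numeric vectors, frame matrices (rows = time),
#'   or [preprocess_pair()] clean segments.
#' @param pattern a [rj_step_pattern()].
#' @param window optional Sakoe-Chiba band half-width (maximum `|i - j|`);
#'   `NULL` (default) imposes no global constraint beyond the pattern's
#'   own slope bounds.
#' @return an object of class `warp_result` with elements `path` (two-
#'   column matrix of 1-based aligned indices), `accumulated_cost`,
#'   `normalized_distance`, `pattern_id`, `N`, `M`.
#' @export
dtw_align <- function(x, y, pattern = rj_step_pattern(6, "c"),
                      window = NULL) {
  x <- as_frame_matrix(x); y <- as_frame_matrix(y)
  if (nrow(x) == 0 || nrow(y) == 0) stop("empty input sequence",
                                         call. = FALSE)
  if (ncol(x) != ncol(y)) stop("frame dimension mismatch", call. = FALSE)
  validate_step_pattern(pattern)
  ord <- production_order(pattern)
  pat <- step_pattern_matrix(
    structure(list(chains = pattern$chains[ord]), class = "step_pattern"))
  res <- .dtw_core(x, y, pat, if (is.null(window)) -1L else as.integer(window))
  if (!isTRUE(res$feasible)) {
    stop("no feasible alignment path for lengths N=", nrow(x), ", M=",
         nrow(y), " under pattern ", pattern$id,
         " (length ratio outside the pattern's slope bounds",
         if (!is.null(window)) " or window too narrow", ")", call. = FALSE)
  }
  path <- cbind(i = res$index1, j = res$index2)
  new_warp_result(path, res$accumulated_cost, pattern, nrow(x), nrow(y))
}

#' Exact DTW by exhaustive path enumeration
#'
#' Independent oracle for [dtw_align()]: recursively enumerates every
#' legal production sequence from `(N, M)` back to `(1, 1)` and keeps the
#' cheapest (ties broken toward the diagonal-first production, mirroring
#' the dynamic program). Exponential: only for tiny inputs.
#'
#' @inheritParams dtw_align
#' @return a `warp_result`, identical in contract to [dtw_align()].
#' @export
brute_force_dtw <- function(x, y, pattern = rj_step_pattern(6, "c")) {
  x <- as_frame_matrix(x); y <- as_frame_matrix(y)
  n <- nrow(x); m <- nrow(y)
  if (n == 0 || m == 0) stop("empty input sequence", call. = FALSE)
  if (n > 10 || m > 10) stop("brute force limited to N, M <= 10",
                             call. = FALSE)
  validate_step_pattern(pattern)
  ord <- production_order(pattern)
  chains <- pattern$chains[ord]
  d <- function(i, j) local_distance(x[i, ], y[j, ])

  solve <- function(i, j) {
    if (i == 1 && j == 1) {
      return(list(cost = d(1, 1), cells = matrix(c(1, 1), ncol = 2)))
    }
    best <- NULL
    for (ch in chains) {
      di <- sum(ch$moves[, 1]); dj <- sum(ch$moves[, 2])
      pi <- i - di; pj <- j - dj
      if (pi < 1 || pj < 1) next
      sub <- solve(pi, pj)
      if (is.null(sub)) next
      ## walk the chain from the production start up to (i, j)
      ci <- pi; cj <- pj
      step_cost <- 0
      cells <- NULL
      for (s in seq_len(nrow(ch$moves))) {
        ci <- ci + ch$moves[s, 1]; cj <- cj + ch$moves[s, 2]
        if (ch$weights[s] != 0) step_cost <- step_cost +
            ch$weights[s] * d(ci, cj)
        cells <- rbind(cells, c(ci, cj))
      }
      cand <- sub$cost + step_cost
      if (is.null(best) || cand < best$cost) {
        best <- list(cost = cand, cells = rbind(sub$cells, cells))
      }
    }
    best
  }

  res <- solve(n, m)
  if (is.null(res)) {
    stop("no feasible alignment path for lengths N=", n, ", M=", m,
         " under pattern ", pattern$id,
         " (length ratio outside the pattern's slope bounds)", call. = FALSE)
  }
  path <- res$cells
  colnames(path) <- c("i", "j")
  new_warp_result(path, res$cost, pattern, n, m)
}

#' Maximum time offset along a warping path
#'
#' The largest `|i - j|` over the aligned index pairs: how far the
#' alignment locally shifts one sequence against the other.
#'
#' @param result a `warp_result`.
#' @return integer.
#' @export
max_path_offset <- function(result) {
  max(abs(result$path[, 1] - result$path[, 2]))
}

#' @export
print.warp_result <- function(x, ...) {
  cat("DTW alignment (", x$pattern_id, "): N=", x$N, ", M=", x$M,
      ", aligned pairs=", nrow(x$path), "\n", sep = "")
  cat("  accumulated cost:", format(x$accumulated_cost), "\n")
  cat("  normalized distance:", format(x$normalized_distance), "\n")
  invisible(x)
}
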