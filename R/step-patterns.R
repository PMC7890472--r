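## Rabiner-Juang local continuity constraints for dynamic time warping.
##
## A step pattern is a set of composite productions; each production is a
## chain of elementary moves (di, dj) walked to reach cell (i, j), with a
## non-negative weight per move. The seven canonical types differ in which
## productions are allowed (and hence in the admissible local slope); the
## four slope weightings assign the per-move weights:
##   a: min(di, dj)   b: max(di, dj)   c: di   d: di + dj
## The smoothed variant spreads each production's total weight evenly over
## its moves. Weighting c weights by the reference-axis displacement only,
## which makes the accumulated cost direction-dependent even for patterns
## whose geometry is mirror-symmetric (see the coordination module for how
## scores are symmetrized).

## Productions per type, each a chain of elementary (di, dj) moves.
rj_type_chains <- function(type) {
  mv <- function(...) matrix(c(...), ncol = 2, byrow = TRUE)
  switch(type,
    ## I: unconstrained slope (0..Inf)
    list(mv(1, 0), mv(1, 1), mv(0, 1)),
    ## II: slope 0..Inf but off-diagonal moves only after a diagonal
    list(mv(1, 1, 1, 0), mv(1, 1), mv(1, 1, 0, 1)),
    ## III: single-jump productions, slope 1/2..2 (Itakura-like)
    list(mv(2, 1), mv(1, 1), mv(1, 2)),
    ## IV: slope 1/2..2, two-move chains
    list(mv(1, 1, 1, 0), mv(1, 2, 1, 0), mv(1, 1), mv(1, 2)),
    ## V: slope 1/3..3, diagonal-first chains
    list(mv(1, 1, 1, 0, 1, 0), mv(1, 1, 1, 0), mv(1, 1),
         mv(1, 1, 0, 1), mv(1, 1, 0, 1, 0, 1)),
    ## VI: slope 2/3..3/2
    list(mv(1, 1, 1, 1, 1, 0), mv(1, 1), mv(1, 1, 1, 1, 0, 1)),
    ## VII: slope 1/3..3, reference axis always advances
    list(mv(1, 1, 1, 0, 1, 0), mv(1, 2, 1, 0, 1, 0), mv(1, 3, 1, 0, 1, 0),
         mv(1, 1, 1, 0), mv(1, 2, 1, 0), mv(1, 3, 1, 0),
         mv(1, 1), mv(1, 2), mv(1, 3)))
}

rj_move_weight <- function(di, dj, weighting) {
  switch(weighting,
         a = pmin(di, dj),
         b = pmax(di, dj),
         c = di,
         d = di + dj)
}

#' Construct a Rabiner-Juang step pattern
#'
#' Builds one of the seven canonical local continuity constraints with one
#' of the four slope weightings, optionally smoothed. Type VI with
#' weighting c (`rj_step_pattern(6, "c")`) is the pipeline default: its
#' productions (3,2), (1,1), (2,3) permit only moderate local compression
#' or stretching (slope between 2/3 and 3/2) and are mirror-symmetric, so
#' neither sequence is structurally privileged as "leading".
#'
#' @param type integer 1..7.
#' @param weighting slope weighting, one of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param smoothed logical; spread each production's total weight evenly
#'   over its elementary moves.
#' @param normalization how [dtw_align()] turns accumulated cost into a
#'   normalized distance: `"aligned_pairs"` (default; divide by the number
#'   of aligned index pairs on the optimal path), `"reference_length"`,
#'   `"query_length"`, or `"sum_lengths"`.
#' @return an object of class `step_pattern`.
#' @export
rj_step_pattern <- function(type, weighting = c("c", "a", "b", "d"),
                            smoothed = FALSE,
                            normalization = c("aligned_pairs",
                                              "reference_length",
                                              "query_length",
                                              "sum_lengths")) {
  weighting <- match.arg(as.character(weighting[1]),
                         c("a", "b", "c", "d"))
  normalization <- match.arg(normalization)
  if (!is.numeric(type) || length(type) != 1 || !(type %in% 1:7)) {
    stop("undefined Rabiner-Juang combination; valid: type in 1..7, ",
         "weighting in {a, b, c, d}", call. = FALSE)
  }
  chains_mv <- rj_type_chains(type)
  chains <- lapply(chains_mv, function(m) {
    w <- rj_move_weight(m[, 1], m[, 2], weighting)
    if (smoothed) w <- rep(sum(w) / nrow(m), nrow(m))
    list(moves = m, weights = w)
  })
  id <- paste0("RJ-", as.roman(type), "-", weighting,
               if (smoothed) "-s" else "")
  p <- structure(list(id = id, type = type, weighting = weighting,
                      smoothed = smoothed, chains = chains,
                      normalization_rule = normalization),
                 class = "step_pattern")
  validate_step_pattern(p)
  p
}

validate_step_pattern <- function(p) {
  if (!length(p$chains)) stop("step pattern has no productions", call. = FALSE)
  for (ch in p$chains) {
    if (!nrow(ch$moves)) stop("empty production chain", call. = FALSE)
    if (any(ch$moves < 0) || any(ch$weights < 0)) {
      stop("negative displacement or weight in step pattern", call. = FALSE)
    }
    if (sum(ch$moves) == 0) {
      stop("production with zero total displacement", call. = FALSE)
    }
  }
  ## at least one production must advance both indices, otherwise no path
  ## from (1,1) to (N,M) exists for N,M > 1
  adv <- vapply(p$chains,
                function(ch) sum(ch$moves[, 1]) > 0 && sum(ch$moves[, 2]) > 0,
                TRUE)
  if (!any(adv)) stop("pattern admits no complete path", call. = FALSE)
  invisible(p)
}

## Flat matrix encoding for the C++ core (and compact tests):
## rows (chain id, di, dj, weight); weight -1 marks the production's start
## cell offset, subsequent rows give the weighted cost cells ending at (0,0).
step_pattern_matrix <- function(p) {
  rows <- NULL
  for (k in seq_along(p$chains)) {
    ch <- p$chains[[k]]
    DI <- sum(ch$moves[, 1]); DJ <- sum(ch$moves[, 2])
    rows <- rbind(rows, c(k, DI, DJ, -1))
    ci <- DI; cj <- DJ
    for (s in seq_len(nrow(ch$moves))) {
      ci <- ci - ch$moves[s, 1]; cj <- cj - ch$moves[s, 2]
      rows <- rbind(rows, c(k, ci, cj, ch$weights[s]))
    }
  }
  dimnames(rows) <- list(NULL, c("chain", "di", "dj", "weight"))
  rows
}

## Productions ordered so the plain diagonal (if present) is tried first;
## ties in the DP are then broken toward the diagonal transition.
production_order <- function(p) {
  diag_first <- vapply(p$chains, function(ch) {
    nrow(ch$moves) == 1 && all(ch$moves[1, ] == c(1, 1))
  }, TRUE)
  order(!diag_first)
}

#' @export
print.step_pattern <- function(x, ...) {
  cat("Step pattern", x$id, "\n")
  for (k in seq_along(x$chains)) {
    ch <- x$chains[[k]]
    cat(sprintf("  production %d: (%d,%d) via %s\n", k,
                sum(ch$moves[, 1]), sum(ch$moves[, 2]),
                paste(sprintf("(%d,%d)x%g", ch$moves[, 1], ch$moves[, 2],
                              ch$weights), collapse = " ")))
  }
  cat("  normalization:", x$normalization_rule, "\n")
  invisible(x)
}
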