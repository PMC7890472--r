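## Coordination scores: inverted normalized DTW distances per body part and
## the dyad-by-task aggregate.

PART_PAIRS <- list(
  head   = c("head", "head"),
  torso  = c("torso", "torso"),
  handLL = c("left_wrist", "left_wrist"),
  handRR = c("right_wrist", "right_wrist"),
  handLR = c("left_wrist", "right_wrist"),
  handRL = c("right_wrist", "left_wrist"))

## parts entering the aggregate (cross-hand pairings are exploratory and
## never aggregated)
MAIN_PARTS <- c("head", "torso", "handLL", "handRR")

## the missing-part rule: the aggregate is the mean of whatever
## main-analysis part scores are available, never an imputation
aggregate_parts <- function(part_scores, main = MAIN_PARTS) {
  v <- part_scores[main]
  v <- v[!is.na(v)]
  if (!length(v)) NA_real_ else mean(v)
}

## fast closed-interval row slice of a time-sorted stream
slice_stream <- function(st, lo, hi) {
  idx <- findInterval(c(lo - 0.5, hi + 0.5), st$t_ms)
  if (idx[2] <= idx[1]) return(st[0, , drop = FALSE])
  rows <- (idx[1] + 1L):idx[2]
  fast_df(list(t_ms = st$t_ms[rows], gx = st$gx[rows],
               gy = st$gy[rows], gz = st$gz[rows]))
}

#' Coordination score for one stream pair
#'
#' Minus one times the normalized DTW distance, so that greater scores
#' mean more coordination and identical streams score 0 (the maximum).
#' With `orientation = "symmetric"` (the default) the distance is the mean
#' over both alignment orientations, making the score exactly invariant to
#' which interactant is treated as the reference sequence; `"xy"` uses the
#' single canonical orientation.
#'
#' @param pair list with clean segments `a` and `b` (as returned by
#'   [preprocess_pair()]), or a list of two frame matrices.
#' @param pattern a [rj_step_pattern()].
#' @param orientation `"symmetric"` or `"xy"`.
#' @param metric `"euclidean"` (one multivariate alignment over the three
#'   axes, the default) or `"per_axis"` (each axis warped independently,
#'   normalized distances summed).
#' @return negative (or zero) scalar score.
#' @export
score_part <- function(pair, pattern = rj_step_pattern(6, "c"),
                       orientation = c("symmetric", "xy"),
                       metric = c("euclidean", "per_axis")) {
  orientation <- match.arg(orientation)
  metric <- match.arg(metric)
  a <- as_frame_matrix(pair[[1]]); b <- as_frame_matrix(pair[[2]])
  nd <- function(x, y) {
    if (metric == "euclidean") {
      dtw_align(x, y, pattern)$normalized_distance
    } else {
      sum(vapply(seq_len(ncol(x)), function(k) {
        dtw_align(x[, k], y[, k], pattern)$normalized_distance
      }, 0))
    }
  }
  d_ab <- nd(a, b)
  if (orientation == "xy") return(-d_ab)
  -(d_ab + nd(b, a)) / 2
}

#' Score one dyad on one task
#'
#' Screens and warps every available body-site pairing for the task and
#' returns per-part coordination scores plus the aggregate: the arithmetic
#' mean of the available main-analysis parts (head, torso, same-label left
#' and right hand). A part whose streams are absent or whose segment fails
#' screening (e.g. a frozen sensor) is recorded as missing, never imputed;
#' the aggregate is the mean of whatever main parts remain.
#'
#' @param session a [dyad_session()].
#' @param task task label.
#' @param pattern a [rj_step_pattern()].
#' @param hand_mode `"same_label"` (main analysis: left-left and
#'   right-right), `"cross"` (exploratory left-right and right-left), or
#'   `"both"`.
#' @param valid_range sensor range for [remove_impossible_values()].
#' @param orientation see [score_part()].
#' @param ... further screening parameters passed to the preprocessing
#'   steps.
#' @return an object of class `coordination_score`: list with `dyad_id`,
#'   `task`, `part_scores` (named numeric, `NA` = missing) and
#'   `aggregate`.
#' @export
score_dyad_task <- function(session, task, pattern = rj_step_pattern(6, "c"),
                            hand_mode = c("same_label", "cross", "both"),
                            valid_range = c(-1200, 1200),
                            orientation = c("symmetric", "xy"), ...) {
  hand_mode <- match.arg(hand_mode)
  orientation <- match.arg(orientation)
  wanted <- switch(hand_mode,
                   same_label = c("head", "torso", "handLL", "handRR"),
                   cross = c("head", "torso", "handLR", "handRL"),
                   both = names(PART_PAIRS))
  iv <- marker_intervals(session$markers)
  iv <- iv[iv$task == task, ]
  if (nrow(iv) == 0) stop("no markers for task '", task, "'", call. = FALSE)
  ## slice each stream once for this task; parts share the slices
  slices <- lapply(session$streams, slice_stream, iv$start, iv$end)
  scores <- stats::setNames(rep(NA_real_, length(PART_PAIRS)),
                            names(PART_PAIRS))
  for (part in wanted) {
    sites <- PART_PAIRS[[part]]
    ai <- slices[[stream_name("interviewer", sites[1])]]
    bi <- slices[[stream_name("interviewee", sites[2])]]
    if (is.null(ai) || is.null(bi)) next
    if (nrow(ai) == 0 || nrow(bi) == 0) next
    sc <- tryCatch({
      pr <- preprocess_stream_pair(
        ai, bi, valid_range,
        meta_a = list(site = sites[1], role = "interviewer", task = task),
        meta_b = list(site = sites[2], role = "interviewee", task = task),
        ...)
      score_part(pr, pattern, orientation)
    }, error = function(e) {
      warning("part '", part, "' (task '", task, "') excluded: ",
              conditionMessage(e), call. = FALSE)
      NA_real_
    })
    scores[part] <- sc
  }
  if (all(is.na(scores[wanted]))) {
    stop("no body-part score available for dyad '", session$dyad_id,
         "', task '", task, "'", call. = FALSE)
  }
  main <- if (hand_mode == "cross") c("head", "torso") else MAIN_PARTS
  structure(list(dyad_id = session$dyad_id, task = task,
                 part_scores = scores,
                 aggregate = aggregate_parts(scores, main)),
            class = "coordination_score")
}

#' Long-format coordination score table for a set of sessions
#'
#' One row per dyad x task, in deterministic order (dyads in input order,
#' tasks in difficulty order), carrying the condition labels, the six
#' possible part scores and the aggregate. This is the input to the
#' statistics layer.
#'
#' @param sessions list of [dyad_session()] objects.
#' @inheritParams score_dyad_task
#' @return data frame.
#' @export
score_table <- function(sessions, pattern = rj_step_pattern(6, "c"),
                        hand_mode = c("same_label", "cross", "both"),
                        valid_range = c(-1200, 1200),
                        orientation = c("symmetric", "xy"), ...) {
  hand_mode <- match.arg(hand_mode)
  orientation <- match.arg(orientation)
  rows <- list()
  for (s in sessions) {
    iv <- marker_intervals(s$markers)
    tasks <- intersect(difficulty_coding()$levels, iv$task)
    for (tk in tasks) {
      cs <- score_dyad_task(s, tk, pattern, hand_mode, valid_range,
                            orientation, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        dyad_id = s$dyad_id, task = tk,
        order_variant = s$conditions$order_variant %||% NA_character_,
        attention_instruction =
          s$conditions$attention_instruction %||% NA_character_,
        t(cs$part_scores), aggregate = cs$aggregate,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(dyad_id = character(), task = character(),
                      order_variant = character(),
                      attention_instruction = character(),
                      head = numeric(), torso = numeric(),
                      handLL = numeric(), handRR = numeric(),
                      handLR = numeric(), handRL = numeric(),
                      aggregate = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
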