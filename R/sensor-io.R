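## Reading, writing and segmenting WiTilt-style gyroscope sessions.
##
## On-disk dialect (the original capture software's format is unpublished):
## one CSV per (role, site) with header `t_ms,gx,gy,gz`; task markers in
## `markers.csv` with header `task,boundary,t_ms`; a `manifest.json` naming
## the dyad, the condition labels and the stream files.

#' @importFrom utils read.csv write.csv
NULL

SITES <- c("head", "torso", "left_wrist", "right_wrist")
ROLES <- c("interviewer", "interviewee")
TASKS <- c("truth", "easy_lie", "difficult_lie", "very_difficult_lie")

stream_name <- function(role, site) paste(role, site, sep = ".")

#' Construct a dyad session
#'
#' A dyad session bundles the raw gyroscope streams of one
#' interviewer-interviewee pair (up to 2 roles x 4 body sites; absent
#' streams are allowed, e.g. after sensor failure), the experimenter's task
#' markers, and the condition labels of the dyad.
#'
#' @param dyad_id character identifier.
#' @param streams named list of data frames with columns `t_ms` (integer
#'   milliseconds, sorted), `gx`, `gy`, `gz` (device units). Names are
#'   `"<role>.<site>"`, e.g. `"interviewer.head"`.
#' @param markers data frame with columns `task` (one of `truth`,
#'   `easy_lie`, `difficult_lie`, `very_difficult_lie`), `boundary`
#'   (`start`/`end`) and `t_ms`.
#' @param conditions list with elements `order_variant` (`forward` or
#'   `reverse`), `attention_instruction` (`nonverbal`, `verbal`, `none`, or
#'   `n/a`) and `nominal_rate_hz` (default 120).
#' @return an object of class `dyad_session`.
#' @export
dyad_session <- function(dyad_id, streams, markers,
                         conditions = list(order_variant = "forward",
                                           attention_instruction = "n/a",
                                           nominal_rate_hz = 120)) {
  conditions$nominal_rate_hz <- conditions$nominal_rate_hz %||% 120
  s <- structure(
    list(dyad_id = as.character(dyad_id), streams = streams,
         markers = markers, conditions = conditions),
    class = "dyad_session")
  validate_session(s)
  s
}

validate_session <- function(s) {
  nm <- names(s$streams)
  if (length(nm) != length(unique(nm))) {
    stop("duplicate (role, site) stream: ",
         paste(nm[duplicated(nm)], collapse = ", "), call. = FALSE)
  }
  valid <- as.vector(outer(ROLES, SITES, stream_name))
  bad <- setdiff(nm, valid)
  if (length(bad)) stop("unknown stream name(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (n in nm) {
    st <- s$streams[[n]]
    if (!all(c("t_ms", "gx", "gy", "gz") %in% names(st))) {
      stop("stream ", n, " lacks required columns t_ms,gx,gy,gz", call. = FALSE)
    }
    if (nrow(st) && any(st$t_ms < 0)) stop("stream ", n, ": negative timestamp",
                                           call. = FALSE)
    if (is.unsorted(st$t_ms)) {
      i <- which(diff(st$t_ms) < 0)[1] + 1L
      stop("stream ", n, ": timestamps not sorted at row ", i, call. = FALSE)
    }
  }
  validate_markers(s$markers)
  invisible(s)
}

validate_markers <- function(m) {
  if (!all(c("task", "boundary", "t_ms") %in% names(m))) {
    stop("markers need columns task,boundary,t_ms", call. = FALSE)
  }
  bad <- setdiff(unique(m$task), TASKS)
  if (length(bad)) stop("unknown task label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  iv <- marker_intervals(m)
  if (nrow(iv) > 1) {
    o <- order(iv$start)
    if (any(iv$start[o][-1] < iv$end[o][-nrow(iv)])) {
      stop("task intervals overlap", call. = FALSE)
    }
  }
  invisible(m)
}

## markers -> data.frame(task, start, end); a start without an end is fatal
marker_intervals <- function(m) {
  tasks <- unique(m$task)
  out <- data.frame(task = character(), start = numeric(), end = numeric(),
                    stringsAsFactors = FALSE)
  for (tk in tasks) {
    st <- m$t_ms[m$task == tk & m$boundary == "start"]
    en <- m$t_ms[m$task == tk & m$boundary == "end"]
    if (length(st) != 1 || length(en) != 1) {
      stop("task '", tk, "' must have exactly one start and one end marker",
           call. = FALSE)
    }
    if (st >= en) stop("task '", tk, "': start marker not before end",
                       call. = FALSE)
    out <- rbind(out, data.frame(task = tk, start = st, end = en,
                                 stringsAsFactors = FALSE))
  }
  out
}

read_stream_csv <- function(path) {
  raw <- read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("t_ms", "gx", "gy", "gz") %in% names(raw))) {
    stop("stream file ", path, " lacks header t_ms,gx,gy,gz", call. = FALSE)
  }
  num <- suppressWarnings(
    data.frame(t_ms = as.numeric(raw$t_ms), gx = as.numeric(raw$gx),
               gy = as.numeric(raw$gy), gz = as.numeric(raw$gz)))
  bad <- which(!stats::complete.cases(num))
  if (length(bad)) {
    stop("stream file ", path, ": ", length(bad),
         " malformed row(s); first at data row ", bad[1], call. = FALSE)
  }
  num
}

#' Read a dyad session from disk
#'
#' @param path directory containing a `manifest.json` written by
#'   [write_session()], or `NULL` when `stream_paths` and `marker_file` are
#'   given explicitly.
#' @param stream_paths named character vector of stream CSV paths; names are
#'   `"<role>.<site>"`.
#' @param marker_file path to the marker CSV.
#' @param dyad_id,conditions session metadata when no manifest is used.
#' @return a [dyad_session()].
#' @export
read_session <- function(path = NULL, stream_paths = NULL, marker_file = NULL,
                         dyad_id = "dyad", conditions = NULL) {
  if (!is.null(path)) {
    mf <- file.path(path, "manifest.json")
    if (!file.exists(mf)) stop("manifest not found: ", mf, call. = FALSE)
    man <- jsonlite::read_json(mf, simplifyVector = TRUE)
    dyad_id <- man$dyad_id
    conditions <- as.list(man$conditions)
    stream_paths <- vapply(man$streams, identity, "")
    if (length(stream_paths)) {
      stream_paths <- stats::setNames(file.path(path, stream_paths),
                                      names(man$streams))
    } else {
      stream_paths <- character()
    }
    marker_file <- file.path(path, man$markers)
  }
  if (is.null(marker_file) || !file.exists(marker_file)) {
    stop("marker file missing: ", marker_file %||% "<NULL>", call. = FALSE)
  }
  if (length(stream_paths) && length(unique(names(stream_paths))) !=
        length(stream_paths)) {
    stop("duplicate (role, site) stream in inputs", call. = FALSE)
  }
  streams <- lapply(stream_paths, read_stream_csv)
  names(streams) <- names(stream_paths)
  markers <- read.csv(marker_file, stringsAsFactors = FALSE,
                      strip.white = TRUE)
  markers$t_ms <- as.numeric(markers$t_ms)
  dyad_session(dyad_id, streams, markers,
               conditions %||% list(order_variant = "forward",
                                    attention_instruction = "n/a",
                                    nominal_rate_hz = 120))
}

#' Write a dyad session to disk
#'
#' Emits one CSV per stream, a marker CSV and a JSON manifest. Gyro values
#' are written with four fixed decimals and timestamps as integers, so
#' `read_session(write_session(s))` reproduces `s` exactly for values with
#' at most four decimals.
#'
#' @param session a [dyad_session()].
#' @param directory output directory (created if needed).
#' @return invisibly, the character vector of written file paths.
#' @export
write_session <- function(session, directory) {
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok) stop("cannot create directory ", directory, call. = FALSE)
  files <- character()
  stream_files <- list()
  for (n in names(session$streams)) {
    fn <- paste0(sub("\\.", "_", n), ".csv")
    st <- session$streams[[n]]
    txt <- c("t_ms,gx,gy,gz",
             sprintf("%d,%.4f,%.4f,%.4f", as.integer(st$t_ms),
                     st$gx, st$gy, st$gz))
    writeLines(txt, file.path(directory, fn))
    stream_files[[n]] <- fn
    files <- c(files, file.path(directory, fn))
  }
  m <- session$markers
  writeLines(c("task,boundary,t_ms",
               sprintf("%s,%s,%d", m$task, m$boundary, as.integer(m$t_ms))),
             file.path(directory, "markers.csv"))
  files <- c(files, file.path(directory, "markers.csv"))
  man <- list(dyad_id = session$dyad_id, conditions = session$conditions,
              streams = stream_files, markers = "markers.csv")
  jsonlite::write_json(man, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, file.path(directory, "manifest.json"))
  invisible(files)
}

#' Segment a session into per-task, per-site stream pairs
#'
#' Cuts every stream at the task markers (closed intervals
#' `[start, end]`) and pairs the interviewer and interviewee streams per
#' body site. Pairs are emitted only for sites recorded for both roles;
#' pairs where either side has no samples inside the interval are dropped
#' with a warning.
#'
#' @param session a [dyad_session()].
#' @return nested list: `result[[task]][[site]]` is a list with elements
#'   `interviewer` and `interviewee` (raw sample data frames).
#' @export
segment_tasks <- function(session) {
  iv <- marker_intervals(session$markers)
  out <- list()
  for (r in seq_len(nrow(iv))) {
    tk <- iv$task[r]
    seg <- list()
    for (site in SITES) {
      a <- session$streams[[stream_name("interviewer", site)]]
      b <- session$streams[[stream_name("interviewee", site)]]
      if (is.null(a) || is.null(b)) next
      ai <- a[a$t_ms >= iv$start[r] & a$t_ms <= iv$end[r], , drop = FALSE]
      bi <- b[b$t_ms >= iv$start[r] & b$t_ms <= iv$end[r], , drop = FALSE]
      if (nrow(ai) == 0 || nrow(bi) == 0) {
        warning("empty segment for task '", tk, "', site '", site,
                "'; excluded", call. = FALSE)
        next
      }
      seg[[site]] <- list(interviewer = ai, interviewee = bi)
    }
    out[[tk]] <- seg
  }
  out
}
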