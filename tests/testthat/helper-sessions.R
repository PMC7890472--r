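## Shared fixtures, all built in code.

## a minimal hand-written stream: regular 120 Hz-ish timestamps
make_stream <- function(n, t0 = 0, rate_hz = 120, seed = 1) {
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed(seed, data.frame(
    t_ms = t0 + round((0:(n - 1)) * 1000 / rate_hz),
    gx = round(rnorm(n, sd = 100), 4),
    gy = round(rnorm(n, sd = 100), 4),
    gz = round(rnorm(n, sd = 100), 4)))
}

## small two-task session with streams for the given sites
make_session <- function(sites = c("head", "torso"), n = 1200,
                         dyad_id = "t01", seed = 1) {
  streams <- list()
  k <- 0
  for (role in c("interviewer", "interviewee")) {
    for (site in sites) {
      k <- k + 1
      streams[[paste(role, site, sep = ".")]] <-
        make_stream(n, seed = seed + k)
    }
  }
  dur <- round((n - 1) * 1000 / 120)
  markers <- data.frame(
    task = rep(c("truth", "easy_lie"), each = 2),
    boundary = rep(c("start", "end"), 2),
    t_ms = c(0, floor(dur / 2), floor(dur / 2) + 100, dur))
  dyad_session(dyad_id, streams, markers)
}

## quick default pattern
p6c <- dyadwarp::rj_step_pattern(6, "c")

## enumerate all 1-D sequences of given lengths over an alphabet
all_sequences <- function(lengths, alphabet = 0:2) {
  out <- list()
  for (L in lengths) {
    g <- do.call(expand.grid, rep(list(alphabet), L))
    for (r in seq_len(nrow(g))) out[[length(out) + 1L]] <- as.numeric(g[r, ])
  }
  out
}

expect_same_alignment <- function(x, y, pattern) {
  a <- tryCatch(dtw_align(x, y, pattern), error = function(e) "infeasible")
  b <- tryCatch(brute_force_dtw(x, y, pattern),
                error = function(e) "infeasible")
  if (is.character(a) || is.character(b)) {
    expect_identical(is.character(a), is.character(b),
                     info = "feasibility must agree")
  } else {
    expect_equal(a$accumulated_cost, b$accumulated_cost, tolerance = 1e-12)
    expect_equal(a$normalized_distance, b$normalized_distance,
                 tolerance = 1e-12)
    expect_identical(nrow(a$path), nrow(b$path))
  }
}
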