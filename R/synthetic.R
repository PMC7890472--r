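## Synthetic dyadic-motion generator with known ground truth.
##
## Movement kernel: a mean-reverting Ornstein-Uhlenbeck process per axis
## (theta = 1/s, unit stationary SD) sampled at the device rate — smooth,
## stationary, and unit-scaled, which is all the pipeline may rely on.
## The interviewee follows the interviewer as a lagged, attenuated copy:
##   follower(t) = kappa * leader(t - tau(t)) + sqrt(1 - kappa^2) * OU'(t)
##                 + sensor noise,
## with tau(t) = tau0 + lag_drift * sin(2 pi t / 60): a slowly drifting
## short time delay, the structure DTW is designed to absorb. The
## construction preserves unit variance for every coupling strength.

#' Coupling and capture specification for the generator
#'
#' @param kappa coupling strength in `[0, 1]`.
#' @param tau0 base follower lag in seconds.
#' @param lag_drift amplitude (s) of the slow sinusoidal lag modulation
#'   (period 60 s).
#' @param dyad_effect_sd SD of the between-dyad random shift added to
#'   kappa (clamped back into `[0, 1]`).
#' @param noise_sd sensor noise SD (in stationary-signal units).
#' @param artifact_rate per-sample probability of an out-of-range
#'   recording error (device default approx 0.5%).
#' @param clock_offset_ms per-device recording start delay in ms.
#' @param rate_hz device sampling rate.
#' @param duration_s task segment duration in seconds.
#' @param gyro_scale device units per stationary SD.
#' @param spike_value out-of-range value used for injected artifacts.
#' @param kernel optional replacement movement kernel: a
#'   `function(n, dt)` returning a unit-variance stationary series; the
#'   default `NULL` uses the Ornstein-Uhlenbeck kernel. The pipeline's
#'   conclusions must not depend on this choice.
#' @return list of class `coupling_spec`.
#' @export
coupling_spec <- function(kappa = 0.3, tau0 = 0.5, lag_drift = 0.2,
                          dyad_effect_sd = 0.05, noise_sd = 0.05,
                          artifact_rate = 0.005, clock_offset_ms = 0,
                          rate_hz = 120, duration_s = 20,
                          gyro_scale = 200, spike_value = 9999,
                          kernel = NULL) {
  stopifnot(kappa >= 0, kappa <= 1, rate_hz > 0, duration_s > 0,
            artifact_rate >= 0, artifact_rate <= 0.05)
  structure(as.list(environment()), class = "coupling_spec")
}

## exact AR(1) discretization of an OU process with unit stationary SD
ou_axis <- function(n, dt, theta = 1) {
  a <- exp(-theta * dt)
  ## first draw from the stationary distribution, then exact AR(1) updates
  x <- c(stats::rnorm(1), stats::rnorm(n - 1, sd = sqrt(1 - a^2)))
  .ar1_filter(x, a)
}

#' Simulate an interviewer ("leader") movement stream
#'
#' Three independent unit-SD Ornstein-Uhlenbeck axes sampled at the
#' device rate, with integer-millisecond timestamps starting at `t0_ms`.
#' Deterministic given the seed.
#'
#' @param duration_s length in seconds.
#' @param rate_hz sampling rate.
#' @param seed integer seed.
#' @param t0_ms timestamp of the first sample.
#' @param theta OU mean-reversion rate (1/s).
#' @param kernel optional alternative `function(n, dt)` movement kernel
#'   (see [coupling_spec()]).
#' @return raw sample data frame (`t_ms`, `gx`, `gy`, `gz`),
#'   unit-stationary-SD units.
#' @export
simulate_leader <- function(duration_s, rate_hz = 120, seed = 1,
                            t0_ms = 0, theta = 1, kernel = NULL) {
  n <- floor(duration_s * rate_hz)
  dt <- 1 / rate_hz
  gen <- kernel %||% function(n, dt) ou_axis(n, dt, theta)
  with_seed(seed, {
    fast_df(list(t_ms = t0_ms + round((0:(n - 1)) * 1000 / rate_hz),
                 gx = gen(n, dt), gy = gen(n, dt), gz = gen(n, dt)))
  })
}

#' Simulate an interviewee ("follower") stream coupled to a leader
#'
#' @param leader raw sample data frame from [simulate_leader()].
#' @param spec a [coupling_spec()]; uses `kappa`, `tau0`, `lag_drift`,
#'   `noise_sd`, `rate_hz`.
#' @param seed integer seed.
#' @return raw sample data frame with the same timestamps as `leader`.
#' @export
simulate_follower <- function(leader, spec, seed = 1) {
  n <- nrow(leader)
  if (n == 0) stop("empty leader stream", call. = FALSE)
  ## work on the ideal sample grid; the integer-ms stamps are only labels
  t_s <- (0:(n - 1)) / spec$rate_hz
  dur <- t_s[n]
  if (spec$tau0 + abs(spec$lag_drift) >= dur) {
    stop("lag exceeds stream duration", call. = FALSE)
  }
  tau <- spec$tau0 + spec$lag_drift * sin(2 * pi * t_s / 60)
  k <- spec$kappa
  if (is.na(k) || k < 0 || k > 1) stop("kappa must be in [0, 1]",
                                       call. = FALSE)
  with_seed(seed, {
    ## linear interpolation of the leader at t - tau on its (uniform)
    ## sample grid, constant-extrapolated at the edges
    dt <- 1 / spec$rate_hz
    pos <- pmin(pmax((t_s - tau) / dt, 0), n - 1)
    i0 <- pmin(floor(pos), n - 2)
    frac <- pos - i0
    gen <- spec$kernel %||% function(n, dt) ou_axis(n, dt)
    one_axis <- function(ax) {
      v <- leader[[ax]]
      lagged <- v[i0 + 1] * (1 - frac) + v[i0 + 2] * frac
      k * lagged + sqrt(1 - k^2) * gen(n, 1 / spec$rate_hz) +
        stats::rnorm(n, sd = spec$noise_sd)
    }
    fast_df(list(t_ms = leader$t_ms, gx = one_axis("gx"),
                 gy = one_axis("gy"), gz = one_axis("gz")))
  })
}

#' Inject recording errors and a recording-start delay
#'
#' Each sample is independently replaced, with probability
#' `spec$artifact_rate`, by an out-of-range spike (all three axes set to
#' `spike_value` with a random sign) — emulating the electronic recording
#' errors the screening step removes. A positive `clock_offset_ms` models
#' a device that began recording late: leading samples are dropped
#' (timestamps come from the shared capture host and stay comparable
#' across devices).
#'
#' @param samples raw sample data frame.
#' @param spec a [coupling_spec()]; uses `artifact_rate`, `spike_value`,
#'   `clock_offset_ms`.
#' @param seed integer seed.
#' @return data frame with attributes `artifact_rows` (row indices of the
#'   injected spikes, after the delay cut) and `dropped_lead` (number of
#'   leading samples removed by the start delay).
#' @export
inject_artifacts <- function(samples, spec, seed = 1) {
  with_seed(seed, {
    out <- samples
    off <- spec$clock_offset_ms
    dropped <- 0L
    if (off > 0) {
      keep <- out$t_ms >= out$t_ms[1] + off
      dropped <- sum(!keep)
      out <- fast_df(list(t_ms = out$t_ms[keep], gx = out$gx[keep],
                          gy = out$gy[keep], gz = out$gz[keep]))
    }
    n <- nrow(out)
    hit <- which(stats::runif(n) < spec$artifact_rate)
    if (length(hit)) {
      sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
      out$gx[hit] <- sgn * spec$spike_value
      out$gy[hit] <- sgn * spec$spike_value
      out$gz[hit] <- sgn * spec$spike_value
    }
    attr(out, "artifact_rows") <- hit
    attr(out, "dropped_lead") <- dropped
    out
  })
}

## default coupling strengths per task; invented values, chosen only so the
## qualitative increase of coordination with difficulty is detectable at
## the study's sample size — NOT empirical estimates
default_kappa_by_task <- function() {
  c(easy_lie = 0.20, truth = 0.30, difficult_lie = 0.45,
    very_difficult_lie = 0.60)
}

## coded-accuracy targets per task for generated veracity judgements,
## matching the detection rates the contingency analyses operate on
default_judgement_accuracy <- function(design) {
  if (design == "exp1") {
    c(truth = 0.63, easy_lie = 0.16, difficult_lie = 0.32,
      very_difficult_lie = 0.57)
  } else {
    c(truth = 0.74, easy_lie = 0.29, very_difficult_lie = 0.52)
  }
}

## draw a 1..7 Likert rating whose coded correctness is `correct`
draw_rating <- function(veracity, correct) {
  if (veracity == "truth") {
    if (correct) sample(5:7, 1) else sample(1:4, 1)
  } else {
    if (correct) sample(1:3, 1) else sample(4:7, 1)
  }
}

#' Simulate one dyad session
#'
#' Builds the full 2-role x 4-site stream set for one dyad: per task
#' segment, an independent leader process per interviewer site and the
#' coupled follower for the matching interviewee site, concatenated on a
#' session timeline with task markers, scaled to device units, spiked
#' with recording errors and cut by per-device start delays.
#'
#' @param dyad_id identifier.
#' @param tasks character vector of task labels for this dyad.
#' @param kappa_by_task named coupling strength per task (already
#'   including any dyad-level shift).
#' @param spec a [coupling_spec()] (its `kappa` field is overridden per
#'   task).
#' @param seed integer; fans out to per-site/task/role sub-streams.
#' @param conditions session condition labels.
#' @param max_offset_ms upper bound of the uniform per-device start delay.
#' @return list with `session` (a [dyad_session()]) and `truth`
#'   (per-task kappa, per-device offsets, artifact bookkeeping).
#' @export
simulate_dyad_session <- function(dyad_id, tasks, kappa_by_task, spec,
                                  seed,
                                  conditions = list(
                                    order_variant = "forward",
                                    attention_instruction = "n/a",
                                    nominal_rate_hz = 120),
                                  max_offset_ms = 1000) {
  pad_ms <- 1000
  dur_ms <- spec$duration_s * 1000
  gap_ms <- 2 * pad_ms + 1000
  starts <- pad_ms + (seq_along(tasks) - 1) * (dur_ms + gap_ms)
  markers <- do.call(rbind, lapply(seq_along(tasks), function(k) {
    data.frame(task = tasks[k], boundary = c("start", "end"),
               t_ms = c(starts[k], starts[k] + dur_ms))
  }))
  offsets <- with_seed(substream_seed(seed, dyad_id, "offsets"), {
    stats::setNames(round(stats::runif(8, 0, max_offset_ms)),
                    as.vector(outer(ROLES, SITES, stream_name)))
  })
  conditions$nominal_rate_hz <- spec$rate_hz

  streams <- list()
  artifacts <- list()
  for (site in SITES) {
    lead_parts <- list(); foll_parts <- list()
    for (k in seq_along(tasks)) {
      seg_dur <- (dur_ms + 2 * pad_ms) / 1000
      lead <- simulate_leader(seg_dur, spec$rate_hz,
                              substream_seed(seed, dyad_id, site, tasks[k],
                                             "leader"),
                              t0_ms = starts[k] - pad_ms,
                              kernel = spec$kernel)
      sp_k <- spec
      sp_k$kappa <- unname(kappa_by_task[tasks[k]])
      foll <- simulate_follower(lead, sp_k,
                                substream_seed(seed, dyad_id, site,
                                               tasks[k], "follower"))
      lead_parts[[k]] <- lead; foll_parts[[k]] <- foll
    }
    for (role in ROLES) {
      parts <- if (role == "interviewer") lead_parts else foll_parts
      raw <- fast_df(list(
        t_ms = unlist(lapply(parts, `[[`, "t_ms"), use.names = FALSE),
        gx = unlist(lapply(parts, `[[`, "gx"), use.names = FALSE),
        gy = unlist(lapply(parts, `[[`, "gy"), use.names = FALSE),
        gz = unlist(lapply(parts, `[[`, "gz"), use.names = FALSE)))
      raw$gx <- round(raw$gx * spec$gyro_scale, 4)
      raw$gy <- round(raw$gy * spec$gyro_scale, 4)
      raw$gz <- round(raw$gz * spec$gyro_scale, 4)
      nm <- stream_name(role, site)
      sp_s <- spec
      sp_s$clock_offset_ms <- unname(offsets[nm])
      st <- inject_artifacts(raw, sp_s,
                             substream_seed(seed, dyad_id, site, role,
                                            "artifacts"))
      artifacts[[nm]] <- length(attr(st, "artifact_rows"))
      attr(st, "artifact_rows") <- NULL
      attr(st, "dropped_lead") <- NULL
      rownames(st) <- NULL
      streams[[nm]] <- st
    }
  }
  session <- dyad_session(dyad_id, streams, markers, conditions)
  list(session = session,
       truth = list(kappa = kappa_by_task[tasks], offsets = offsets,
                    artifact_counts = unlist(artifacts)))
}

#' Simulate a full study
#'
#' Generates sessions, veracity judgements and complete ground truth for
#' one of the two study designs. `exp1`: every dyad gives a truthful
#' account and an easy lie; the first half additionally a difficult lie,
#' the rest a very difficult lie; the topic order alternates
#' forward/reverse. `exp2`: every dyad gives a truth, an easy lie and a
#' very difficult lie, and dyads are allocated round-robin to the three
#' attention-instruction groups (nonverbal / verbal / none).
#'
#' Judgements are drawn directly at the coded-accuracy level: the
#' probability that a judgement is coded correct equals
#' `judgement_accuracy_by_task`, and a Likert rating consistent with the
#' drawn correctness is sampled uniformly from the corresponding band.
#'
#' @param n_dyads number of dyads.
#' @param design `"exp1"` or `"exp2"`.
#' @param kappa_by_task named per-task coupling strengths (defaults are
#'   invented, non-empirical values; see [coupling_spec()]).
#' @param judgement_accuracy_by_task named per-task probability that the
#'   interviewer's judgement is coded correct.
#' @param seed integer master seed; all randomness derives from it.
#' @param spec a [coupling_spec()] for capture parameters.
#' @param max_offset_ms per-device start-delay bound in ms.
#' @return list with `sessions` (list of [dyad_session()]),
#'   `judgements` (data frame `dyad_id`, `task`, `veracity`, `rating`)
#'   and `truth` (per dyad x task kappa, dyad effects, offsets, artifact
#'   counts, generating accuracies).
#' @export
simulate_study <- function(n_dyads = 43, design = c("exp1", "exp2"),
                           kappa_by_task = default_kappa_by_task(),
                           judgement_accuracy_by_task = NULL,
                           seed = 1, spec = coupling_spec(),
                           max_offset_ms = 1000) {
  design <- match.arg(design)
  acc <- judgement_accuracy_by_task %||% default_judgement_accuracy(design)
  sessions <- vector("list", n_dyads)
  judgements <- list()
  truth <- list(kappa = list(), dyad_effects = numeric(n_dyads),
                offsets = list(), artifact_counts = list(),
                judgement_p = list())
  n_difficult <- ceiling(n_dyads / 2)
  instr_groups <- c("nonverbal", "verbal", "none")
  for (i in seq_len(n_dyads)) {
    id <- sprintf("dyad%03d", i)
    if (design == "exp1") {
      third <- if (i <= n_difficult) "difficult_lie" else
        "very_difficult_lie"
      tasks <- c("truth", "easy_lie", third)
      conditions <- list(
        order_variant = if (i %% 2 == 1) "forward" else "reverse",
        attention_instruction = "n/a", nominal_rate_hz = spec$rate_hz)
    } else {
      tasks <- c("truth", "easy_lie", "very_difficult_lie")
      conditions <- list(
        order_variant = if (i %% 2 == 1) "forward" else "reverse",
        attention_instruction = instr_groups[(i - 1) %% 3 + 1],
        nominal_rate_hz = spec$rate_hz)
    }
    b_i <- with_seed(substream_seed(seed, id, "dyad_effect"),
                     stats::rnorm(1, 0, spec$dyad_effect_sd))
    kap <- pmin(pmax(kappa_by_task[tasks] + b_i, 0), 1)
    sim <- simulate_dyad_session(id, tasks, kap, spec, seed, conditions,
                                 max_offset_ms)
    sessions[[i]] <- sim$session
    truth$kappa[[id]] <- kap
    truth$dyad_effects[i] <- b_i
    truth$offsets[[id]] <- sim$truth$offsets
    truth$artifact_counts[[id]] <- sim$truth$artifact_counts
    for (tk in tasks) {
      ver <- if (tk == "truth") "truth" else "lie"
      p <- unname(acc[tk])
      jr <- with_seed(substream_seed(seed, id, tk, "judgement"), {
        correct <- stats::runif(1) < p
        draw_rating(ver, correct)
      })
      judgements[[length(judgements) + 1L]] <-
        data.frame(dyad_id = id, task = tk, veracity = ver, rating = jr)
      truth$judgement_p[[paste(id, tk, sep = ".")]] <- p
    }
  }
  list(sessions = sessions,
       judgements = do.call(rbind, judgements),
       truth = truth)
}

#' Simulate a score table from the mixed-model data-generating process
#'
#' Score-level generator for validating the difficulty model: per dyad a
#' random intercept, per task a linear effect of the difficulty code,
#' plus residual noise. Used for parameter-recovery and type-I-error
#' checks without running the sensor pipeline.
#'
#' @param n_dyads number of dyads.
#' @param beta true slope on the difficulty code.
#' @param sd_dyad SD of the dyad random intercept.
#' @param sd_eps residual SD.
#' @param tasks task labels per dyad.
#' @param seed integer seed.
#' @return score table with columns `dyad_id`, `task`, `aggregate`.
#' @export
simulate_score_table <- function(n_dyads = 40, beta = 0.5, sd_dyad = 1,
                                 sd_eps = 1,
                                 tasks = difficulty_coding()$levels,
                                 seed = 1) {
  coding <- difficulty_coding()
  with_seed(seed, {
    b <- stats::rnorm(n_dyads, 0, sd_dyad)
    rows <- expand.grid(dyad = seq_len(n_dyads), task = tasks,
                        stringsAsFactors = FALSE)
    code <- coding$codes[match(rows$task, coding$levels)]
    data.frame(dyad_id = sprintf("dyad%03d", rows$dyad),
               task = rows$task,
               aggregate = beta * code + b[rows$dyad] +
                 stats::rnorm(nrow(rows), 0, sd_eps))
  })
}
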