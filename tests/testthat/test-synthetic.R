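test_that("every generator output is a pure function of its seed", {
  a <- simulate_leader(5, 120, seed = 81)
  b <- simulate_leader(5, 120, seed = 81)
  expect_identical(a, b)
  expect_false(identical(a$gx, simulate_leader(5, 120, seed = 82)$gx))

  spec <- coupling_spec(kappa = 0.5, duration_s = 5)
  f1 <- simulate_follower(a, spec, seed = 83)
  f2 <- simulate_follower(a, spec, seed = 83)
  expect_identical(f1, f2)

  s1 <- simulate_study(n_dyads = 4, seed = 84,
                       spec = coupling_spec(duration_s = 5))
  s2 <- simulate_study(n_dyads = 4, seed = 84,
                       spec = coupling_spec(duration_s = 5))
  expect_identical(s1$sessions[[2]]$streams, s2$sessions[[2]]$streams)
  expect_identical(s1$judgements, s2$judgements)
  ## counter-based sub-streams: adding dyads never perturbs existing ones
  ## (dyad 2 keeps the same task set when n grows from 4 to 6)
  s3 <- simulate_study(n_dyads = 6, seed = 84,
                       spec = coupling_spec(duration_s = 5))
  expect_identical(s3$sessions[[2]]$streams, s1$sessions[[2]]$streams)
})

test_that("the movement kernel has unit stationary variance", {
  x <- simulate_leader(2000, 120, seed = 85)
  ## pool the three independent axes: the OU memory (1 s) makes per-axis
  ## variance estimates slow to converge
  pooled <- sd(c(x$gx, x$gy, x$gz))
  expect_lt(abs(pooled - 1), 0.05)
  expect_lt(abs(mean(x$gx)), 0.1)
  ## mean reversion: lag-1 autocorrelation matches exp(-theta * dt)
  r1 <- cor(x$gx[-1], x$gx[-nrow(x)])
  expect_lt(abs(r1 - exp(-1 / 120)), 0.01)
})

test_that("the follower interpolates the leader at the configured lag", {
  lead <- simulate_leader(60, 120, seed = 86)
  ## kappa = 1, zero lag, no noise: the follower IS the leader
  spec1 <- coupling_spec(kappa = 1, tau0 = 0, lag_drift = 0, noise_sd = 0,
                         duration_s = 60)
  fol1 <- simulate_follower(lead, spec1, seed = 87)
  expect_equal(fol1$gx, lead$gx, tolerance = 1e-12)

  ## kappa = 1, fixed lag: maximal correlation sits at the injected lag
  spec2 <- coupling_spec(kappa = 1, tau0 = 0.5, lag_drift = 0,
                         noise_sd = 0, duration_s = 60)
  fol2 <- simulate_follower(lead, spec2, seed = 87)
  lags <- 0:120
  cc <- sapply(lags, function(L) {
    n <- nrow(lead)
    cor(lead$gx[1:(n - L)], fol2$gx[(1 + L):n])
  })
  expect_equal(lags[which.max(cc)], 60, tolerance = 2)  # 0.5 s at 120 Hz

  ## kappa = 0: independent of the leader
  spec0 <- coupling_spec(kappa = 0, duration_s = 60)
  fol0 <- simulate_follower(simulate_leader(300, 120, seed = 88),
                            coupling_spec(kappa = 0, duration_s = 300),
                            seed = 89)
  lead0 <- simulate_leader(300, 120, seed = 88)
  expect_lt(abs(cor(lead0$gx, fol0$gx)), 0.1)
})

test_that("the coupling construction preserves variance at any kappa", {
  lead <- simulate_leader(1000, 120, seed = 90)
  sd_lead <- sd(c(lead$gx, lead$gy, lead$gz))
  for (k in c(0, 0.5, 1)) {
    spec <- coupling_spec(kappa = k, duration_s = 1000)
    fol <- simulate_follower(lead, spec, seed = 91)
    sd_fol <- sd(c(fol$gx, fol$gy, fol$gz))
    expect_lt(abs(sd_fol / sd_lead - 1), 0.05)
  }
  expect_error(
    simulate_follower(simulate_leader(1, 120, seed = 1),
                      coupling_spec(tau0 = 2, duration_s = 1), seed = 2),
    "lag exceeds")
})

test_that("artifact injection matches its binomial bounds and bookkeeping", {
  lead <- simulate_leader(300, 120, seed = 92)  # 36 000 samples
  spec <- coupling_spec(artifact_rate = 0.005)
  spiked <- inject_artifacts(lead, spec, seed = 93)
  k <- length(attr(spiked, "artifact_rows"))
  expect_gte(k, 126)  # 180 +- 3 binomial SDs
  expect_lte(k, 234)
  expect_true(all(abs(spiked$gx[attr(spiked, "artifact_rows")]) == 9999))

  ## rate zero: identity apart from the start delay
  spec0 <- coupling_spec(artifact_rate = 0, clock_offset_ms = 500)
  cut <- inject_artifacts(lead, spec0, seed = 94)
  expect_length(attr(cut, "artifact_rows"), 0)
  expect_identical(cut$gx, lead$gx[lead$t_ms >= 500])
})

test_that("the exp1 design reproduces the study's task allocation", {
  study <- simulate_study(n_dyads = 43, seed = 95,
                          spec = coupling_spec(duration_s = 2, tau0 = 0.3,
                                               lag_drift = 0.1))
  expect_length(study$sessions, 43)
  tasks <- unlist(lapply(study$sessions, function(s) unique(s$markers$task)))
  expect_identical(sum(tasks == "truth"), 43L)
  expect_identical(sum(tasks == "easy_lie"), 43L)
  expect_identical(sum(tasks == "difficult_lie"), 22L)
  expect_identical(sum(tasks == "very_difficult_lie"), 21L)
  expect_identical(nrow(study$judgements), 129L)  # 43 truths + 86 lies
  ## every dyad has 8 streams and complete ground truth
  expect_true(all(vapply(study$sessions,
                         function(s) length(s$streams) == 8L, TRUE)))
  expect_length(study$truth$kappa, 43)
})

test_that("exp2 allocates the three instruction groups round-robin", {
  study <- simulate_study(n_dyads = 9, design = "exp2", seed = 96,
                          spec = coupling_spec(duration_s = 2, tau0 = 0.3,
                                               lag_drift = 0.1))
  instr <- vapply(study$sessions,
                  function(s) s$conditions$attention_instruction, "")
  expect_identical(as.integer(table(instr)[c("nonverbal", "verbal",
                                             "none")]),
                   rep(3L, 3))
  expect_true(all(vapply(study$sessions, function(s)
    setequal(unique(s$markers$task),
             c("truth", "easy_lie", "very_difficult_lie")), TRUE)))
})

test_that("drawn Likert ratings always code back to the drawn correctness", {
  set.seed(97)
  for (v in c("truth", "lie")) {
    for (correct in c(TRUE, FALSE)) {
      ratings <- replicate(200, dyadwarp:::draw_rating(v, correct))
      expect_true(all(ratings %in% 1:7))
      coded <- code_judgement(rep(v, 200), ratings)
      expect_true(all((coded == "correct") == correct))
    }
  }
})

test_that("generated judgement accuracy tracks the generating rates", {
  study <- simulate_study(n_dyads = 40, seed = 98,
                          spec = coupling_spec(duration_s = 2, tau0 = 0.3,
                                               lag_drift = 0.1))
  j <- study$judgements
  coded <- code_judgement(j$veracity, j$rating)
  acc_truth <- mean(coded[j$task == "truth"] == "correct")
  acc_easy <- mean(coded[j$task == "easy_lie"] == "correct")
  ## binomial 99% bounds at n = 40 around 0.63 and 0.16
  expect_lt(abs(acc_truth - 0.63), 0.22)
  expect_lt(abs(acc_easy - 0.16), 0.17)
})

test_that("the pipeline's conclusions survive a movement-kernel swap", {
  ## smoothed-noise kernel instead of Ornstein-Uhlenbeck
  ma_kernel <- function(n, dt) {
    w <- stats::filter(rnorm(n + 20), rep(1 / sqrt(11), 11), sides = 1)
    x <- w[21:(n + 20)]
    as.numeric(x / sd(x))
  }
  spec <- coupling_spec(duration_s = 10, kernel = ma_kernel)
  wins <- 0
  for (i in 1:6) {
    hi <- simulate_dyad_session(paste0("k", i), "truth", c(truth = 0.8),
                                spec, seed = 300 + i)
    lo <- simulate_dyad_session(paste0("k", i), "truth", c(truth = 0.1),
                                spec, seed = 300 + i)
    wins <- wins +
      (score_dyad_task(hi$session, "truth", p6c)$aggregate >
         score_dyad_task(lo$session, "truth", p6c)$aggregate)
  }
  expect_gte(wins, 5)
})
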