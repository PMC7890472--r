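test_that("a part score is minus the normalized DTW distance", {
  sim <- simulate_dyad_session(
    "c1", "truth", c(truth = 0.5), coupling_spec(duration_s = 8), seed = 61)
  pp <- preprocess_pair(sim$session, "truth", "head", c(-1200, 1200))
  s_xy <- score_part(pp, p6c, orientation = "xy")
  expect_equal(s_xy, -dtw_align(pp$a, pp$b, p6c)$normalized_distance)
  expect_lte(s_xy, 0)

  ## symmetric orientation averages the two directions and is exactly
  ## invariant to swapping the interactants
  s_sym <- score_part(pp, p6c)
  expect_equal(s_sym, score_part(list(pp$b, pp$a), p6c))
  expect_equal(s_sym,
               -mean(c(dtw_align(pp$a, pp$b, p6c)$normalized_distance,
                       dtw_align(pp$b, pp$a, p6c)$normalized_distance)))
})

test_that("identical segments score zero, the maximum coordination", {
  sim <- simulate_dyad_session(
    "c2", "truth", c(truth = 0.3), coupling_spec(duration_s = 8), seed = 62)
  pp <- preprocess_pair(sim$session, "truth", "head", c(-1200, 1200))
  expect_identical(score_part(list(pp$a, pp$a), p6c), 0)
})

test_that("independent noise strictly lowers the coordination score", {
  set.seed(63)
  base <- matrix(round(1000 * scale(matrix(rnorm(180), ncol = 3))), ncol = 3)
  clean <- score_part(list(base, base), p6c)
  noisy <- sapply(c(200, 800), function(amp) {
    mean(replicate(20, {
      score_part(list(base, base + round(rnorm(180, sd = amp))), p6c)
    }))
  })
  expect_true(all(noisy < clean))
  expect_lt(noisy[2], noisy[1])
})

test_that("the aggregate is the mean of the available main parts", {
  ps <- c(head = -2, torso = -4, handLL = NA, handRR = -3,
          handLR = -9, handRL = -9)
  expect_identical(dyadwarp:::aggregate_parts(ps), -3)
  expect_identical(dyadwarp:::aggregate_parts(
    c(head = -2, torso = -2, handLL = -2, handRR = -2)), -2)
  ## permutation invariance and exclusion of cross-hand scores
  expect_identical(dyadwarp:::aggregate_parts(rev(ps)), -3)
  expect_true(is.na(dyadwarp:::aggregate_parts(
    c(head = NA, torso = NA, handLL = NA, handRR = NA, handLR = -1))))
})

test_that("missing sensors propagate as missing parts, never as zeros", {
  sim <- simulate_dyad_session(
    "c3", "truth", c(truth = 0.5), coupling_spec(duration_s = 8), seed = 64)
  s <- sim$session
  s$streams$interviewee.left_wrist <- NULL
  cs <- score_dyad_task(s, "truth", p6c)
  expect_true(is.na(cs$part_scores["handLL"]))
  expect_false(is.na(cs$part_scores["head"]))
  expect_equal(cs$aggregate,
               mean(cs$part_scores[c("head", "torso", "handRR")]))

  s$streams <- s$streams["interviewer.head"]
  expect_error(score_dyad_task(s, "truth", p6c), "no body-part score")
})

test_that("hand modes select the pairings they document", {
  sim <- simulate_dyad_session(
    "c4", "truth", c(truth = 0.5), coupling_spec(duration_s = 8), seed = 65)
  same <- score_dyad_task(sim$session, "truth", p6c, "same_label")
  cross <- score_dyad_task(sim$session, "truth", p6c, "cross")
  both <- score_dyad_task(sim$session, "truth", p6c, "both")
  expect_true(all(is.na(same$part_scores[c("handLR", "handRL")])))
  expect_true(all(is.na(cross$part_scores[c("handLL", "handRR")])))
  expect_false(any(is.na(both$part_scores)))
  ## cross-hand scores never enter the aggregate
  expect_equal(both$aggregate,
               mean(both$part_scores[c("head", "torso", "handLL",
                                       "handRR")]))
  expect_equal(cross$aggregate,
               mean(cross$part_scores[c("head", "torso")]))
})

test_that("stronger coupling yields higher aggregate scores", {
  spec <- coupling_spec(duration_s = 10)
  wins <- 0
  for (i in 1:10) {
    hi <- simulate_dyad_session(paste0("hi", i), "truth", c(truth = 0.8),
                                spec, seed = 100 + i)
    lo <- simulate_dyad_session(paste0("lo", i), "truth", c(truth = 0.1),
                                spec, seed = 100 + i)
    a_hi <- score_dyad_task(hi$session, "truth", p6c)$aggregate
    a_lo <- score_dyad_task(lo$session, "truth", p6c)$aggregate
    wins <- wins + (a_hi > a_lo)
  }
  expect_gte(wins, 9)
})

test_that("the score table has one deterministic row per dyad and task", {
  study <- simulate_study(n_dyads = 5, seed = 66,
                          spec = coupling_spec(duration_s = 8))
  st <- suppressWarnings(score_table(study$sessions))
  expect_identical(nrow(st), 15L)
  expect_identical(sum(st$task == "truth"), 5L)
  expect_identical(sum(st$task == "difficult_lie"), 3L)  # ceiling(5/2)
  expect_identical(sum(st$task == "very_difficult_lie"), 2L)
  ## rows equal independent score_dyad_task calls
  cs <- score_dyad_task(study$sessions[[2]], "truth", p6c)
  row <- st[st$dyad_id == "dyad002" & st$task == "truth", ]
  expect_equal(row$aggregate, cs$aggregate)
  expect_equal(row$head, unname(cs$part_scores["head"]))
  ## empty input gives an empty, well-formed table
  empty <- score_table(list())
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("dyad_id", "task", "aggregate") %in% names(empty)))
})

test_that("uncoupled true pairs look like shuffled pseudo-pairs", {
  ## kappa = 0: real partners are statistically indistinguishable from
  ## partners re-paired across dyads
  spec <- coupling_spec(duration_s = 10)
  n <- 12
  sims <- lapply(1:n, function(i) {
    simulate_dyad_session(sprintf("u%02d", i), "truth", c(truth = 0),
                          spec, seed = 200 + i)$session
  })
  true_scores <- sapply(sims, function(s)
    score_dyad_task(s, "truth", p6c)$aggregate)
  pseudo <- sims
  for (i in 1:n) {  # give each interviewer the next dyad's interviewee
    j <- i %% n + 1
    for (site in c("head", "torso", "left_wrist", "right_wrist")) {
      pseudo[[i]]$streams[[paste0("interviewee.", site)]] <-
        sims[[j]]$streams[[paste0("interviewee.", site)]]
    }
  }
  pseudo_scores <- sapply(pseudo, function(s)
    score_dyad_task(s, "truth", p6c)$aggregate)
  expect_gt(stats::t.test(true_scores, pseudo_scores)$p.value, 0.01)
})

test_that("the per-axis metric alternative behaves like a distance", {
  sim <- simulate_dyad_session(
    "c5", "truth", c(truth = 0.6), coupling_spec(duration_s = 8), seed = 68)
  pp <- preprocess_pair(sim$session, "truth", "head", c(-1200, 1200))
  s_pa <- score_part(pp, p6c, metric = "per_axis")
  expect_lte(s_pa, 0)
  expect_identical(score_part(list(pp$a, pp$a), p6c, metric = "per_axis"), 0)
  ## swap invariance holds for the per-axis variant too
  expect_equal(s_pa, score_part(list(pp$b, pp$a), p6c,
                                metric = "per_axis"))
})
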