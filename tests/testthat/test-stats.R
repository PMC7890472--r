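test_that("judgement coding applies the 5-7 / 1-3 rule with neutral wrong", {
  expect_identical(code_judgement("truth", 5), "correct")
  expect_identical(code_judgement("lie", 4), "incorrect")
  expect_identical(code_judgement("lie", 1), "correct")
  ## partition: every rating maps to exactly one class
  for (v in c("truth", "lie")) {
    coded <- code_judgement(rep(v, 7), 1:7)
    expect_true(all(coded %in% c("correct", "incorrect")))
    expect_identical(sum(coded == "correct"), 3L)
  }
  expect_error(code_judgement("truth", 9), "1..7")
})

test_that("accuracy tabulation counts coded judgements", {
  j <- data.frame(dyad_id = "d1",
                  task = c("truth", "easy_lie", "easy_lie"),
                  veracity = c("truth", "lie", "lie"),
                  rating = c(6, 2, 5))
  tab <- tabulate_accuracy(j, "veracity")
  expect_identical(tab["truth", "correct"], 1L)
  expect_identical(tab["lie", "correct"], 1L)
  expect_identical(tab["lie", "incorrect"], 1L)
})

test_that("chi-squared is Pearson without continuity correction", {
  r <- chi_squared(rbind(c(10, 10), c(10, 10)))
  expect_identical(r$statistic, 0)
  expect_identical(r$effect, 0)
  expect_identical(r$df, 1L)

  ## against the closed form on a 2x2 table
  tab <- rbind(c(27, 16), c(26, 60))
  r2 <- chi_squared(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r2$statistic, sum((tab - e)^2 / e))
  expect_equal(r2$effect, sqrt(r2$statistic / sum(tab)))

  expect_error(chi_squared(rbind(c(0, 0), c(5, 5))), "zero marginal")
})

test_that("Bonferroni alpha matches the reported convention", {
  expect_identical(bonferroni_alpha(0.05, 3), 0.017)
  expect_identical(bonferroni_alpha(0.05, 2), 0.025)
  expect_identical(bonferroni_alpha(0.05, 1), 0.05)
  expect_error(bonferroni_alpha(0, 2), "family_alpha")
})

test_that("the difficulty model recovers a known generating slope", {
  st <- simulate_score_table(n_dyads = 40, beta = 0.5, sd_dyad = 1,
                             sd_eps = 1, seed = 71)
  fit <- fit_difficulty_model(st)
  expect_lt(abs(fit$trend$estimate - 0.5), 0.15)
  expect_identical(fit$n_obs, 160L)
  expect_identical(fit$trend$df, 160 - 40 - 2)
  expect_equal(fit$trend$r,
               sqrt(fit$trend$t^2 / (fit$trend$t^2 + fit$trend$df)))
  expect_identical(fit$alpha_corrected, 0.017)  # 3 truth-vs-lie contrasts
  expect_identical(nrow(fit$contrasts), 3L)
  ## omnibus agrees in direction with the trend
  expect_gt(fit$omnibus$F, 10)
  expect_lt(fit$omnibus$p, 0.001)
})

test_that("near-constant scores give a near-zero slope and omnibus F", {
  st <- simulate_score_table(n_dyads = 12, beta = 0, sd_dyad = 0,
                             sd_eps = 1e-6, seed = 72)
  st$aggregate <- st$aggregate + 5
  fit <- suppressMessages(fit_difficulty_model(st))
  expect_lt(abs(fit$trend$estimate), 1e-6)
  expect_lt(fit$omnibus$F, 1)
})

test_that("Satterthwaite df are available and close to containment here", {
  st <- simulate_score_table(n_dyads = 30, beta = 0.3, seed = 73)
  f1 <- fit_difficulty_model(st, ddf = "containment")
  f2 <- fit_difficulty_model(st, ddf = "satterthwaite")
  expect_equal(f1$trend$estimate, f2$trend$estimate, tolerance = 1e-6)
  expect_lt(abs(f1$trend$df - f2$trend$df) / f1$trend$df, 0.35)
})

test_that("the suspicion model is calibrated under independence", {
  covered <- 0
  for (i in 1:100) {
    st <- simulate_score_table(n_dyads = 20, beta = 0, sd_dyad = 0.5,
                               seed = 7000 + i)
    set.seed(8000 + i)
    susp <- data.frame(dyad_id = st$dyad_id, task = st$task,
                       suspicion = sample(1:7, nrow(st), TRUE))
    fit <- suppressMessages(fit_suspicion_model(st, susp))
    ci <- fit$trend$ci
    covered <- covered + (ci[1] <= 0 && 0 <= ci[2])
  }
  expect_gte(covered, 90)
})

test_that("the suspicion model recovers an injected linear relation", {
  st <- simulate_score_table(n_dyads = 25, beta = 0, sd_dyad = 0,
                             sd_eps = 1e-8, seed = 74)
  set.seed(75)
  susp <- data.frame(dyad_id = st$dyad_id, task = st$task,
                     suspicion = runif(nrow(st), 1, 7))
  st$aggregate <- 2.5 * susp$suspicion - 1
  fit <- suppressMessages(fit_suspicion_model(st, susp))
  expect_lt(abs(fit$trend$estimate - 2.5) / 2.5, 0.05)

  expect_error(fit_suspicion_model(st, susp[0, ]), "empty join")
})

test_that("the mixed ANOVA detects a task effect and respects the null", {
  ## instruction effect zero, task effect large
  set.seed(76)
  n <- 18
  grp <- rep(c("nonverbal", "verbal", "none"), length.out = n)
  rows <- expand.grid(dyad = 1:n, task = c("easy_lie", "truth",
                                           "very_difficult_lie"),
                      stringsAsFactors = FALSE)
  rows$grp <- grp[rows$dyad]
  task_eff <- c(easy_lie = 0, truth = 1, very_difficult_lie = 3)
  b <- rnorm(n, 0, 0.5)
  rows$aggregate <- task_eff[rows$task] + b[rows$dyad] + rnorm(nrow(rows))
  st <- data.frame(dyad_id = sprintf("d%02d", rows$dyad), task = rows$task,
                   attention_instruction = rows$grp,
                   aggregate = rows$aggregate)
  an <- mixed_anova_3x3(st)
  expect_identical(an$effect, c("task", "instruction", "instruction:task"))
  expect_gt(an$F[an$effect == "task"], 10)
  expect_lt(an$p[an$effect == "task"], 0.001)
  expect_gt(an$p[an$effect == "instruction"], 0.01)
  expect_true(all(an$partial_eta_sq >= 0 & an$partial_eta_sq <= 1))
  expect_gt(an$partial_eta_sq[1], an$partial_eta_sq[2])
})

test_that("permuting task labels within dyads destroys the task effect", {
  set.seed(77)
  n <- 12
  rows <- expand.grid(dyad = 1:n, task = c("easy_lie", "truth",
                                           "very_difficult_lie"),
                      stringsAsFactors = FALSE)
  task_eff <- c(easy_lie = 0, truth = 1, very_difficult_lie = 2)
  b <- rnorm(n, 0, 0.5)
  rows$aggregate <- task_eff[rows$task] + b[rows$dyad] + rnorm(nrow(rows))
  rows$attention_instruction <- rep(c("nonverbal", "verbal", "none"),
                                    length.out = n)[rows$dyad]
  st0 <- data.frame(dyad_id = sprintf("d%02d", rows$dyad),
                    task = rows$task,
                    attention_instruction = rows$attention_instruction,
                    aggregate = rows$aggregate)
  pvals <- replicate(200, {
    st <- st0
    for (d in unique(st$dyad_id)) {
      idx <- which(st$dyad_id == d)
      st$task[idx] <- sample(st$task[idx])
    }
    an <- mixed_anova_3x3(st)
    an$p[an$effect == "task"]
  })
  ## permutation null: p-values approximately uniform
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.5) - 0.5), 0.12)
})

test_that("dyads missing a task level are dropped listwise with a warning", {
  st <- simulate_score_table(n_dyads = 9, beta = 0.4, seed = 78,
                             tasks = c("easy_lie", "truth",
                                       "very_difficult_lie"))
  st$attention_instruction <- rep(c("nonverbal", "verbal", "none"), 9)
  st <- st[-1, ]  # first dyad loses a task
  expect_warning(an <- mixed_anova_3x3(st), "listwise")
  expect_identical(nrow(an), 3L)
})
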