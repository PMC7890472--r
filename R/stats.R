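## Statistical layer: judgement coding, contingency analyses,
## random-intercept mixed models of coordination, pairwise contrasts, and
## the 3x3 mixed ANOVA.

#' Task difficulty coding
#'
#' The empirically established difficulty order of the four interview
#' tasks: concealing a transgression (easy lie) is experienced as easier
#' than telling the truth, which is easier than a fabrication (difficult
#' lie), which is easier than the same fabrication told in reverse order
#' (very difficult lie). Codes are equally spaced 1..4; the linear-trend
#' analyses use them as a numeric predictor.
#'
#' @return list with `levels` (ordered task labels) and `codes`.
#' @export
difficulty_coding <- function() {
  list(levels = c("easy_lie", "truth", "difficult_lie",
                  "very_difficult_lie"),
       codes = 1:4)
}

#' Code a veracity judgement as correct or incorrect
#'
#' Interviewers rated "the interviewee told the truth" on a 1-7 Likert
#' scale. A response is correct when scoring 5-7 about truths and 1-3
#' about lies; the neutral 4 is always incorrect.
#'
#' @param veracity `"truth"` or `"lie"` (vectorized).
#' @param rating integer 1..7 (vectorized).
#' @return character vector of `"correct"` / `"incorrect"`.
#' @export
code_judgement <- function(veracity, rating) {
  if (any(!rating %in% 1:7)) stop("rating must be in 1..7", call. = FALSE)
  if (any(!veracity %in% c("truth", "lie"))) {
    stop("veracity must be 'truth' or 'lie'", call. = FALSE)
  }
  ok <- ifelse(veracity == "truth", rating >= 5, rating <= 3)
  ifelse(ok, "correct", "incorrect")
}

#' Correct/incorrect counts from a printed detection rate
#'
#' Reconstructs one contingency-table row from a reported percentage
#' correct and a group size: `round(rate * n)` correct, the rest
#' incorrect.
#'
#' @param rate proportion correct in `[0, 1]`.
#' @param n group size.
#' @return integer vector `c(correct, incorrect)`.
#' @export
counts_from_rate <- function(rate, n) {
  k <- round(rate * n)
  c(correct = k, incorrect = n - k)
}

#' Cross-tabulate coded judgement accuracy
#'
#' @param judgements data frame with columns `dyad_id`, `task`,
#'   `veracity`, `rating`.
#' @param by `"task"` or `"veracity"`: the row variable.
#' @return contingency matrix with columns correct, incorrect.
#' @export
tabulate_accuracy <- function(judgements, by = c("task", "veracity")) {
  by <- match.arg(by)
  coded <- code_judgement(judgements$veracity, judgements$rating)
  tab <- table(judgements[[by]], factor(coded, c("correct", "incorrect")))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), c("correct", "incorrect")))
  m
}

#' Pearson chi-squared test with phi / Cramer's V
#'
#' Plain Pearson chi-squared (no continuity correction) on a contingency
#' table of counts, with the effect size
#' `sqrt(chi^2 / (n * min(r - 1, c - 1)))` (phi for 2x2 tables, Cramer's V
#' otherwise; non-negative by definition).
#'
#' @param table matrix of non-negative integer counts.
#' @return list with `statistic`, `df`, `p_value`, `effect`, `n`.
#' @export
chi_squared <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  n <- sum(table)
  chi <- unname(ht$statistic)
  list(statistic = chi, df = as.integer(ht$parameter),
       p_value = unname(ht$p.value),
       effect = sqrt(chi / (n * (min(dim(table)) - 1))),
       n = n)
}

#' Bonferroni-corrected alpha
#'
#' @param family_alpha family-wise error rate (e.g. 0.05).
#' @param k number of comparisons.
#' @return corrected per-comparison alpha, rounded to 3 decimals as
#'   conventionally reported.
#' @export
bonferroni_alpha <- function(family_alpha, k) {
  if (k < 1 || family_alpha <= 0 || family_alpha >= 1) {
    stop("need k >= 1 and 0 < family_alpha < 1", call. = FALSE)
  }
  round(family_alpha / k, 3)
}

## Wald F for a set of fixed-effect coefficients of an lmer fit, with
## containment denominator df: n_obs - n_groups - rank(X).
wald_f <- function(model, coef_idx) {
  b <- lme4::fixef(model)[coef_idx]
  V <- as.matrix(stats::vcov(model))[coef_idx, coef_idx, drop = FALSE]
  q <- length(coef_idx)
  Fval <- as.numeric(t(b) %*% solve(V, b)) / q
  n <- nrow(stats::model.frame(model))
  g <- lme4::ngrps(model)[[1]]
  p <- length(lme4::fixef(model))
  df2 <- n - g - p
  list(F = Fval, df1 = q, df2 = df2,
       p = stats::pf(Fval, q, df2, lower.tail = FALSE))
}

new_mixed_model_fit <- function(...) {
  structure(list(...), class = "mixed_model_fit")
}

#' Mixed-effects model of coordination on task difficulty
#'
#' Fits, by REML, random-intercept-per-dyad models of a coordination score
#' on (a) task as a categorical factor (omnibus F over levels) and (b) the
#' numeric difficulty coding (linear trend). Denominator degrees of
#' freedom use the containment method
#' (`n_obs - n_dyads - rank(X)`) by default; Satterthwaite is available
#' via `ddf = "satterthwaite"`. The effect size `r` is computed from the
#' linear-trend t statistic as `sqrt(t^2 / (t^2 + df))` and labelled as
#' trend-based in the output. Pairwise task contrasts are paired t tests
#' on dyad differences with Cohen's `d = mean(diff) / sd(diff)` and a
#' Bonferroni-corrected alpha for the contrast family.
#'
#' @param scores score table as from [score_table()] (needs columns
#'   `dyad_id`, `task` and the response).
#' @param coding a [difficulty_coding()].
#' @param response column of `scores` to analyse (default `"aggregate"`).
#' @param contrasts list of task-label pairs to test; defaults to truth
#'   versus each lie present in the data.
#' @param family_alpha family-wise alpha for the contrast correction.
#' @param ddf `"containment"` or `"satterthwaite"`.
#' @return a `mixed_model_fit`: omnibus F, linear trend (estimate, t, df,
#'   p, r), variance components, contrast table, corrected alpha, and a
#'   singular-fit flag.
#' @export
fit_difficulty_model <- function(scores, coding = difficulty_coding(),
                                 response = "aggregate",
                                 contrasts = NULL, family_alpha = 0.05,
                                 ddf = c("containment", "satterthwaite")) {
  ddf <- match.arg(ddf)
  d <- data.frame(dyad = factor(scores$dyad_id),
                  task = factor(scores$task, coding$levels),
                  y = scores[[response]])
  d <- d[stats::complete.cases(d), ]
  d$task <- droplevels(d$task)
  d$code <- coding$codes[match(as.character(d$task), coding$levels)]
  if (nlevels(d$task) < 2 || nlevels(d$dyad) < 2) {
    stop("need >= 2 tasks for >= 2 dyads", call. = FALSE)
  }

  m_f <- lme4::lmer(y ~ task + (1 | dyad), data = d, REML = TRUE)
  m_t <- lme4::lmer(y ~ code + (1 | dyad), data = d, REML = TRUE)
  singular <- lme4::isSingular(m_f) || lme4::isSingular(m_t)

  q <- nlevels(d$task) - 1
  if (ddf == "containment") {
    omni <- wald_f(m_f, 1 + seq_len(q))
    ct <- stats::coef(summary(m_t))["code", ]
    tdf <- nrow(d) - nlevels(d$dyad) - 2
    trend <- list(estimate = unname(ct["Estimate"]),
                  se = unname(ct["Std. Error"]),
                  t = unname(ct["t value"]), df = tdf,
                  p = 2 * stats::pt(abs(ct["t value"]), tdf,
                                    lower.tail = FALSE))
  } else {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      stop("ddf = 'satterthwaite' needs the lmerTest package",
           call. = FALSE)
    }
    mf2 <- lmerTest::lmer(y ~ task + (1 | dyad), data = d, REML = TRUE)
    av <- stats::anova(mf2, ddf = "Satterthwaite")
    omni <- list(F = av[1, "F value"], df1 = av[1, "NumDF"],
                 df2 = av[1, "DenDF"], p = av[1, "Pr(>F)"])
    mt2 <- lmerTest::lmer(y ~ code + (1 | dyad), data = d, REML = TRUE)
    ct <- stats::coef(summary(mt2))["code", ]
    trend <- list(estimate = unname(ct["Estimate"]),
                  se = unname(ct["Std. Error"]),
                  t = unname(ct["t value"]), df = unname(ct["df"]),
                  p = unname(ct["Pr(>|t|)"]))
  }
  trend$p <- unname(trend$p)
  trend$r <- sqrt(trend$t^2 / (trend$t^2 + trend$df))

  vc <- as.data.frame(lme4::VarCorr(m_t))
  varcomp <- c(dyad = vc$vcov[vc$grp == "dyad"],
               residual = vc$vcov[vc$grp == "Residual"])

  if (is.null(contrasts)) {
    lies <- intersect(c("easy_lie", "difficult_lie", "very_difficult_lie"),
                      levels(d$task))
    contrasts <- lapply(lies, function(l) c("truth", l))
    contrasts <- Filter(function(p) all(p %in% levels(d$task)), contrasts)
  }
  alpha_c <- if (length(contrasts)) {
    bonferroni_alpha(family_alpha, length(contrasts))
  } else {
    family_alpha
  }
  ctr <- lapply(contrasts, function(pr) {
    wide <- merge(d[d$task == pr[1], c("dyad", "y")],
                  d[d$task == pr[2], c("dyad", "y")], by = "dyad")
    diff <- wide$y.x - wide$y.y
    if (length(diff) < 3 || stats::sd(diff) == 0) {
      return(data.frame(pair = paste(pr, collapse = " vs "), n = length(diff),
                        t = NA, df = NA, p = NA, d = NA))
    }
    tt <- stats::t.test(diff)
    data.frame(pair = paste(pr, collapse = " vs "), n = length(diff),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, d = mean(diff) / stats::sd(diff))
  })
  ctr <- if (length(ctr)) do.call(rbind, ctr) else NULL

  new_mixed_model_fit(
    response = response, predictor = "difficulty",
    fixed = lme4::fixef(m_t), varcomp = varcomp, omnibus = omni,
    trend = trend, effect_r = trend$r, effect_r_basis = "linear trend t",
    contrasts = ctr, alpha_corrected = alpha_c, singular = singular,
    n_obs = nrow(d), n_dyads = nlevels(d$dyad))
}

#' Mixed-effects model of coordination on interviewer suspicion
#'
#' Random-intercept-per-dyad regression of a coordination score on a
#' continuous suspicion rating, joined on dyad x task.
#'
#' @param scores score table (columns `dyad_id`, `task`, response).
#' @param suspicion data frame with columns `dyad_id`, `task`,
#'   `suspicion` (Likert rating).
#' @inheritParams fit_difficulty_model
#' @return a `mixed_model_fit` (the omnibus F is the squared slope t).
#' @export
fit_suspicion_model <- function(scores, suspicion, response = "aggregate",
                                ddf = c("containment", "satterthwaite")) {
  ddf <- match.arg(ddf)
  j <- merge(scores[, c("dyad_id", "task", response)], suspicion,
             by = c("dyad_id", "task"))
  j <- j[stats::complete.cases(j), ]
  if (nrow(j) == 0) stop("empty join of scores and suspicion ratings",
                         call. = FALSE)
  d <- data.frame(dyad = factor(j$dyad_id), x = j$suspicion,
                  y = j[[response]])
  m <- lme4::lmer(y ~ x + (1 | dyad), data = d, REML = TRUE)
  ct <- stats::coef(summary(m))["x", ]
  if (ddf == "containment") {
    tdf <- nrow(d) - nlevels(d$dyad) - 2
  } else {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      stop("ddf = 'satterthwaite' needs the lmerTest package", call. = FALSE)
    }
    m2 <- lmerTest::lmer(y ~ x + (1 | dyad), data = d, REML = TRUE)
    tdf <- unname(stats::coef(summary(m2))["x", "df"])
  }
  tval <- unname(ct["t value"])
  p <- 2 * stats::pt(abs(tval), tdf, lower.tail = FALSE)
  se <- unname(ct["Std. Error"])
  est <- unname(ct["Estimate"])
  vc <- as.data.frame(lme4::VarCorr(m))
  new_mixed_model_fit(
    response = response, predictor = "suspicion",
    fixed = lme4::fixef(m),
    varcomp = c(dyad = vc$vcov[vc$grp == "dyad"],
                residual = vc$vcov[vc$grp == "Residual"]),
    omnibus = list(F = tval^2, df1 = 1, df2 = tdf,
                   p = stats::pf(tval^2, 1, tdf, lower.tail = FALSE)),
    trend = list(estimate = est, se = se, t = tval, df = tdf, p = p,
                 r = sqrt(tval^2 / (tval^2 + tdf)),
                 ci = est + c(-1, 1) * stats::qt(0.975, tdf) * se),
    effect_r = sqrt(tval^2 / (tval^2 + tdf)),
    effect_r_basis = "slope t",
    singular = lme4::isSingular(m),
    n_obs = nrow(d), n_dyads = nlevels(d$dyad))
}

#' 3x3 mixed-design ANOVA with partial eta squared
#'
#' Classical mixed ANOVA with a between-dyad factor (attention
#' instruction) and a within-dyad repeated measure (task), on a
#' coordination score. Dyads missing a task level (or the between label)
#' are dropped listwise with a warning. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` with each effect's own error
#' stratum (between-dyad error for the instruction effect, within-dyad
#' error for task and the interaction).
#'
#' @param scores score table with columns `dyad_id`, `task`, the between
#'   factor and the response.
#' @param between name of the between-dyad factor column.
#' @param response response column.
#' @return data frame with one row per effect: F, df, partial eta
#'   squared, p.
#' @export
mixed_anova_3x3 <- function(scores, between = "attention_instruction",
                            response = "aggregate") {
  d <- data.frame(dyad = factor(scores$dyad_id),
                  task = factor(scores$task),
                  grp = factor(scores[[between]]),
                  y = scores[[response]])
  d <- d[stats::complete.cases(d), ]
  n_tasks <- nlevels(droplevels(d$task))
  full <- tapply(d$task, d$dyad, function(x) length(unique(x)))
  keep <- names(full)[full == n_tasks]
  if (length(keep) < nlevels(d$dyad)) {
    warning(nlevels(d$dyad) - length(keep),
            " dyad(s) missing a task level dropped listwise",
            call. = FALSE)
  }
  d <- droplevels(d[d$dyad %in% keep, ])
  fit <- stats::aov(y ~ grp * task + Error(dyad), data = d)
  sm <- summary(fit)
  between_tab <- sm[["Error: dyad"]][[1]]
  within_tab <- sm[["Error: Within"]][[1]]
  rn_b <- trimws(rownames(between_tab))
  rn_w <- trimws(rownames(within_tab))
  get <- function(tab, rn, term) {
    i <- match(term, rn)
    e <- match("Residuals", rn)
    ss <- tab[i, "Sum Sq"]; sse <- tab[e, "Sum Sq"]
    data.frame(effect = term, F = tab[i, "F value"],
               df1 = tab[i, "Df"], df2 = tab[e, "Df"],
               partial_eta_sq = ss / (ss + sse),
               p = tab[i, "Pr(>F)"])
  }
  out <- rbind(get(within_tab, rn_w, "task"),
               get(between_tab, rn_b, "grp"),
               get(within_tab, rn_w, "grp:task"))
  out$effect <- c("task", "instruction", "instruction:task")
  rownames(out) <- NULL
  out
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat("Mixed-effects model of", x$response, "on", x$predictor,
      "(random intercept per dyad)\n")
  cat(sprintf("  omnibus: F(%g, %g) = %.3f, p = %.4g\n", x$omnibus$df1,
              x$omnibus$df2, x$omnibus$F, x$omnibus$p))
  cat(sprintf("  linear trend: b = %.4f (SE %.4f), t(%g) = %.3f, p = %.4g, r = %.3f\n",
              x$trend$estimate, x$trend$se, x$trend$df, x$trend$t,
              x$trend$p, x$trend$r))
  if (!is.null(x$contrasts)) {
    cat("  contrasts (Bonferroni-corrected alpha =", x$alpha_corrected,
        "):\n")
    print(x$contrasts, row.names = FALSE)
  }
  if (isTRUE(x$singular)) cat("  NOTE: singular fit\n")
  invisible(x)
}
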