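test_that("every 2-level effect equals the squared paired t statistic", {
  tbl <- make_exponent_table(n_subjects = 12, seed = 2)
  fit <- rm_anova(tbl, within = c("period", "drug", "prime", "flanker"))
  td <- tidy(fit)

  # paired t oracle for the drug main effect
  bw <- brainwide_exponents(tbl)
  per <- tapply(bw$exponent, list(bw$participant, bw$drug), mean)
  tt <- t.test(per[, "MPH"], per[, "placebo"], paired = TRUE)
  expect_equal(td$F[td$effect == "drug"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(td$p[td$effect == "drug"], tt$p.value, tolerance = 1e-10)

  # partial eta squared identity for df1 = 1
  expect_equal(td$partial_eta_sq, td$F / (td$F + td$df2), tolerance = 1e-12)
})

test_that("the full effect table matches the aov error-strata oracle", {
  tbl <- make_exponent_table(n_subjects = 10, effect_drug = 0.13, seed = 7)
  fit <- rm_anova(tbl, within = c("period", "drug", "prime", "flanker"))
  td <- tidy(fit)
  df <- as.data.frame(tbl)
  df$participant <- factor(df$participant)
  a <- summary(stats::aov(
    exponent ~ period * drug * prime * flanker +
      Error(participant / (period * drug * prime * flanker)),
    data = df
  ))
  Fs <- sapply(a[-1], function(s) s[[1]][1, "F value"])
  effs <- gsub("Error: participant:", "", names(Fs))
  expect_equal(td$F[match(effs, td$effect)], unname(Fs), tolerance = 1e-9)
})

test_that("identical MPH and placebo cells give F = 0 and p = 1", {
  tbl <- make_exponent_table(n_subjects = 8, seed = 3)
  wide <- tidyr::pivot_wider(tbl, names_from = "drug", values_from = "exponent")
  wide$MPH <- wide$placebo
  tbl2 <- tidyr::pivot_longer(wide, c("placebo", "MPH"),
                              names_to = "drug", values_to = "exponent")
  fit <- rm_anova(tbl2, within = c("period", "drug", "prime", "flanker"))
  td <- tidy(fit)
  expect_equal(td$F[td$effect == "drug"], 0, tolerance = 1e-20)
  expect_equal(td$p[td$effect == "drug"], 1)
})

test_that("an injected drug effect is detected at p < .001 across replicates", {
  hits <- vapply(1:10, function(seed) {
    tbl <- make_exponent_table(n_subjects = 25, effect_drug = 0.129,
                               noise_sd = 0.05, seed = seed)
    td <- tidy(rm_anova(tbl, within = c("period", "drug", "prime", "flanker")))
    td$p[td$effect == "drug"] < 0.001 && td$estimate[td$effect == "drug"] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("missing or unbalanced cells and tiny samples are explicit errors", {
  tbl <- make_exponent_table(n_subjects = 4, seed = 5)
  expect_error(rm_anova(tbl[-1, ], within = c("period", "drug", "prime", "flanker")),
               "missing cells", class = "aperiodic_input_error")
  expect_error(rm_anova(tbl[tbl$participant == 1, ],
                        within = c("period", "drug", "prime", "flanker")),
               class = "aperiodic_input_error")
})

test_that("marginal level means and SEM are reported per factor", {
  tbl <- make_exponent_table(n_subjects = 6, effect_drug = 0.2, seed = 6)
  fit <- rm_anova(tbl, within = c("drug", "period"))
  lm_drug <- fit$level_means[fit$level_means$factor == "drug", ]
  expect_equal(nrow(lm_drug), 2)
  expect_gt(lm_drug$mean[lm_drug$level == "MPH"],
            lm_drug$mean[lm_drug$level == "placebo"])
  expect_true(all(lm_drug$sem > 0))
})

test_that("follow-up ANOVAs split correctly and Bonferroni-correct p-values", {
  # effect present only in the within-trial period
  tbl <- make_exponent_table(n_subjects = 20, seed = 8, noise_sd = 0.05)
  tbl$exponent <- tbl$exponent +
    0.25 * (tbl$drug == "MPH" & tbl$period == "within_trial")
  fu <- follow_up_anovas(tbl, split_by = "period",
                         within = c("drug", "prime", "flanker"))
  drug_rows <- fu[fu$effect == "drug", ]
  expect_lt(drug_rows$p[drug_rows$period == "within_trial"], 0.001)
  expect_gt(drug_rows$p[drug_rows$period == "pre_trial"], 0.05)
  expect_equal(fu$p_bonferroni, pmin(1, 2 * fu$p))

  # null data: no effect significant in either half
  null_tbl <- make_exponent_table(n_subjects = 15, seed = 9, noise_sd = 0.05)
  fu0 <- follow_up_anovas(null_tbl, split_by = "period",
                          within = c("drug", "prime", "flanker"))
  expect_gt(min(fu0$p_bonferroni), 0.001)
})
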