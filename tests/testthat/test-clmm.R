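test_that("exclusion rule applies the strict more-than count", {
  mk <- function(subject, ratings) {
    data.frame(subject = subject, item = NA, scenario = NA,
               rating = ratings, sententiality = NA, predictability = NA,
               script_type = NA, position = NA, familiarity_raw = NA,
               is_control = TRUE, control_kind = "ungrammatical")
  }
  exp_rows <- data.frame(subject = rep(c("s1", "s2", "s3"), each = 2),
                         item = 1:2, scenario = "x", rating = 4,
                         sententiality = rep(c("sentence", "fragment"), 3),
                         predictability = "predictable", script_type = NA,
                         position = 1:2, familiarity_raw = 3,
                         is_control = FALSE, control_kind = NA)
  tab <- rbind(exp_rows,
               mk("s1", c(7, 7, 7, 1, 1)),   # 3 natural > 2 -> excluded
               mk("s2", c(7, 7, 1, 1, 1)),   # 2 is not more than 2
               mk("s3", c(1, 1, 1, 1, 1)))
  out <- exclude_subjects(tab)
  expect_identical(out$excluded, "s1")
  expect_setequal(unique(out$table$subject), c("s2", "s3"))

  # monotonicity: stricter cutoffs never exclude more subjects
  n1 <- length(exclude_subjects(tab, min_flagged = 2, natural_cutoff = 6)$excluded)
  n2 <- length(exclude_subjects(tab, min_flagged = 3, natural_cutoff = 6)$excluded)
  n3 <- length(exclude_subjects(tab, min_flagged = 2, natural_cutoff = 7)$excluded)
  expect_lte(n2, n1)
  expect_lte(n3, n1)

  expect_error(exclude_subjects(exp_rows), "control")
})

test_that("design preparation codes, centers and flags correctly", {
  spec <- rating_sim_spec(n_subjects = 8, n_items = 8,
                          n_missing_familiarity = 2)
  tab <- sample_ratings(spec, seed = 8)
  des <- prepare_design(tab)
  expect_false(any(des$rating %in% NA))
  expect_setequal(unique(des$sententiality), c(-1, 1))
  expect_setequal(unique(des$predictability), c(-1, 1))
  expect_equal(sum(des$sententiality), 0)  # balanced design
  expect_equal(sum(des$predictability), 0)
  # familiarity z-scored over available values; missing at 0 and flagged
  avail <- des$familiarity[!des$familiarity_missing]
  expect_equal(mean(avail), 0, tolerance = 1e-10)
  expect_equal(sd(avail), 1, tolerance = 1e-10)
  expect_true(all(des$familiarity[des$familiarity_missing] == 0))
  expect_equal(attr(des, "n_familiarity_missing"), sum(des$familiarity_missing))
  expect_gt(sum(des$familiarity_missing), 0)

  # zero-variance familiarity flagged
  tab2 <- tab[!(tab$is_control %in% TRUE), ]
  tab2$familiarity_raw <- 3
  expect_warning(des2 <- prepare_design(tab2), "zero variance")
  expect_true(attr(des2, "familiarity_zero_variance"))

  # level absent entirely
  tab3 <- tab[!(tab$is_control %in% TRUE) &
                tab$sententiality == "sentence", ]
  expect_error(prepare_design(tab3), "absent")
})

test_that("with zero random variance the fit matches a plain cumulative logit", {
  skip_if_not_installed("MASS")
  spec <- rating_sim_spec(n_subjects = 24, n_items = 16,
                          random_sds = c(subject_intercept = 0),
                          n_controls = 0)
  tab <- sample_ratings(spec, seed = 3)
  des <- prepare_design(tab)
  sp <- clmm_spec(c("sententiality", "predictability", "position",
                    "familiarity"), random = list())
  fit <- fit_clmm(des, sp)
  pol <- MASS::polr(ordered(rating) ~ sententiality + predictability +
                      position + familiarity, data = des,
                    method = "logistic")
  expect_equal(fit$coefficients$estimate, unname(coef(pol)),
               tolerance = 1e-3)
  expect_equal(fit$thresholds, unname(pol$zeta), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(pol)), tolerance = 1e-6)
})

test_that("converged fits have ordered thresholds and normalized predictions", {
  spec <- rating_sim_spec(n_subjects = 16, n_items = 8,
                          random_sds = c(subject_intercept = 0.8,
                                         item_intercept = 0.4),
                          n_controls = 0)
  tab <- sample_ratings(spec, seed = 12)
  des <- prepare_design(tab)
  sp <- clmm_spec(c("sententiality", "predictability"),
                  random = list(subject = "(Intercept)",
                                item = "(Intercept)"))
  fit <- fit_clmm(des, sp)
  expect_true(fit$converged)
  expect_true(all(diff(fit$thresholds) > 0))
  expect_true(all(fit$coefficients$se > 0))
  P <- predict_probs(fit)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-9)
  expect_gt(fit$random_sd[["subject_intercept"]], 0)
})

test_that("mixed fit recovers generating effects on a seeded simulation", {
  spec <- rating_sim_spec(
    n_subjects = 24, n_items = 12,
    fixed_effects = c(sententiality = -1, predictability = -0.5),
    random_sds = c(subject_intercept = 0.8, item_intercept = 0.4),
    n_controls = 0)
  tab <- sample_ratings(spec, seed = 31)
  des <- prepare_design(tab)
  fit <- fit_clmm(des, clmm_spec(c("sententiality", "predictability"),
                                 random = list(subject = "(Intercept)",
                                               item = "(Intercept)")))
  cf <- fit$coefficients
  expect_lt(abs(cf$estimate[cf$term == "sententiality"] - (-1)) /
              cf$se[cf$term == "sententiality"], 2)
  expect_lt(abs(cf$estimate[cf$term == "predictability"] - (-0.5)) /
              cf$se[cf$term == "predictability"], 2)
})

test_that("likelihood-ratio tests are nested-model arithmetic", {
  spec <- rating_sim_spec(n_subjects = 16, n_items = 8,
                          random_sds = c(subject_intercept = 0.5),
                          n_controls = 0)
  tab <- sample_ratings(spec, seed = 9)
  des <- prepare_design(tab)
  rand <- list(subject = "(Intercept)")
  f2 <- fit_clmm(des, clmm_spec(c("sententiality", "predictability"),
                                random = rand))
  f1 <- fit_clmm(des, clmm_spec("sententiality", random = rand))
  lt <- lr_test(f2, f1)
  expect_equal(lt$chisq, max(0, 2 * (f2$loglik - f1$loglik)))
  expect_equal(lt$df, 1L)
  expect_equal(lt$p, pchisq(lt$chisq, 1, lower.tail = FALSE))

  # identical models: statistic 0, p = 1
  same <- lr_test(f2, f2)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)

  # non-nested specs error
  f_other <- fit_clmm(des, clmm_spec("predictability", random = rand))
  expect_error(lr_test(f1, f_other), "not nested")
})

test_that("backward selection respects marginality and the alpha limits", {
  spec <- rating_sim_spec(
    n_subjects = 24, n_items = 12,
    fixed_effects = c(sententiality = -1.2),
    random_sds = c(subject_intercept = 0.6, item_intercept = 0.3),
    n_controls = 0)
  tab <- sample_ratings(spec, seed = 5)
  des <- prepare_design(tab)
  rand <- list(subject = "(Intercept)", item = "(Intercept)")
  full <- clmm_spec(c("sententiality", "predictability", "script_type",
                      "sententiality:predictability"), random = rand)

  sel <- backward_select(des, full, alpha = 0.05)
  expect_true("sententiality" %in% sel$spec$fixed)
  expect_false("script_type" %in% sel$spec$fixed)
  expect_false("sententiality:predictability" %in% sel$spec$fixed)
  # the interaction must be dropped before its parents could be
  drop_order <- sel$trail$term[sel$trail$dropped]
  expect_lt(match("sententiality:predictability", drop_order),
            Inf)
  parents_dropped <- intersect(drop_order, c("sententiality",
                                             "predictability"))
  for (p in parents_dropped) {
    expect_lt(match("sententiality:predictability", drop_order),
              match(p, drop_order))
  }

  # alpha = 0: full model retained
  sel0 <- backward_select(des, full, alpha = 0)
  expect_identical(sel0$spec$fixed, full$fixed)
  # alpha = 1: every droppable term removed
  sel1 <- backward_select(des, full, alpha = 1)
  expect_length(sel1$spec$fixed, 0)
})

test_that("rating loader maps columns and reports degraded capability", {
  spec <- rating_sim_spec(n_subjects = 6, n_items = 8)
  tab <- sample_ratings(spec, seed = 2)
  tf <- withr::local_tempfile(fileext = ".csv")
  renamed <- tab
  names(renamed)[names(renamed) == "subject"] <- "worker"
  names(renamed)[names(renamed) == "rating"] <- "judgment"
  write.csv(renamed, tf, row.names = FALSE)

  back <- read_ratings(tf, mapping = c(subject = "worker",
                                       rating = "judgment"))
  expect_true(all(c("subject", "rating") %in% names(back)))
  expect_length(attr(back, "missing_columns"), 0)
  fc <- feasible_checks(back)
  expect_true(all(fc))

  # minimal table: core model only
  mini <- tab[!(tab$is_control %in% TRUE),
              c("subject", "item", "rating", "sententiality",
                "predictability")]
  tf2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(mini, tf2, row.names = FALSE)
  back2 <- read_ratings(tf2)
  fc2 <- feasible_checks(back2)
  expect_true(fc2[["core_model"]])
  expect_false(fc2[["exclusion_rule"]])
  expect_false(fc2[["familiarity_terms"]])
  expect_true("familiarity_raw" %in% attr(back2, "missing_columns"))
})
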