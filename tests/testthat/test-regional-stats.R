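test_that("per-region ANOVA matches explicit sums of squares", {
  # toy 4-group x 1-region data with integer values, hand SS oracle
  y <- c(1, 2, 3, 4, 8, 9, 10, 2, 3, 4, 5, 6)
  g <- rep(c("A4-T-", "A4+T+", "A4+T-"), each = 4)[1:12]
  grand <- mean(y)
  ss_between <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ss_between / 2) / (ss_within / 9)

  atlas <- aal90_atlas()
  vals <- matrix(rep(y, 90), 12, dimnames = list(NULL, atlas$name))
  set.seed(1)
  vals[, -1] <- vals[, -1] + rnorm(12 * 89, 0, 0.01)
  co <- tau_cohort(vals, data.frame(id = sprintf("s%d", 1:12), group = g,
                                    stringsAsFactors = FALSE))
  res <- anova_regions(co)
  expect_equal(res$F[res$region == atlas$name[1]], f_oracle,
               tolerance = 1e-12)

  # location invariance
  co2 <- tau_cohort(vals + 100, co$subjects)
  expect_equal(anova_regions(co2)$F, res$F, tolerance = 1e-9)

  # two-group F equals the squared contrast t
  co3 <- tau_cohort(vals[1:8, ], co$subjects[1:8, ])
  res3 <- anova_regions(co3)
  ct <- posthoc_contrasts(co3, reference_group = "A4-T-",
                          regions = atlas$name)
  expect_equal(res3$F, unname(ct[["A4+T+"]]$t^2), tolerance = 1e-9)
})

test_that("post-hoc contrasts match the pooled-variance formula and are specific", {
  co <- toy_cohort(n_per_group = 10, groups = c("A4-T-", "A4+T+", "A4+T-"),
                   seed = 33)
  regions <- aal90_regions()[1:5]
  ct <- posthoc_contrasts(co, "A4-T-", regions = regions)
  # closed-form pooled t oracle on one region
  r <- regions[2]
  g <- co$subjects$group
  a <- co$values[g == "A4+T+", r]; b <- co$values[g == "A4-T-", r]
  sp <- sqrt(((9) * var(a) + (9) * var(b)) / 18)
  t_oracle <- (mean(a) - mean(b)) / (sp * sqrt(1 / 10 + 1 / 10))
  expect_equal(ct[["A4+T+"]]$t[ct[["A4+T+"]]$region == r], t_oracle,
               tolerance = 1e-12)

  # identical comparison group: all t = 0, nothing significant
  base <- split_by_group(co)[["A4-T-"]]
  dup_sub <- base$subjects
  dup_sub$id <- paste0("D", dup_sub$id)
  dup_sub$group <- "A4+T-"
  both <- tau_cohort(rbind(base$values,
                           `rownames<-`(base$values, dup_sub$id)),
                     rbind(base$subjects, dup_sub), base$atlas)
  ct2 <- posthoc_contrasts(both, "A4-T-", regions = regions)
  expect_equal(ct2[["A4+T-"]]$t, rep(0, 5), tolerance = 1e-12)
  expect_false(any(ct2[["A4+T-"]]$significant))

  # planted single-group elevation is flagged only for the planted group
  cfg <- simulation_config(seed = 61)
  sim <- generate_cohort(cfg)
  ct3 <- posthoc_contrasts(sim$cohort, "A4-T-",
                           regions = cfg$effect_regions)
  expect_gt(mean(ct3[["A4+T+"]]$significant), 0.7)
  expect_lt(mean(ct3[["A4-T+"]]$significant), 0.3)
})

test_that("score correlations behave at the edges and recover planted coupling", {
  co <- toy_cohort(n_per_group = 12, groups = "A4+T+", seed = 44)
  r <- "Precentral_L"
  # score equal (up to rescaling and rounding) to a region's values: r near 1
  co$subjects$faq <- as.integer(round(30 * (co$values[, r] -
                                              min(co$values[, r])) /
                                        diff(range(co$values[, r]))))
  res <- correlate_with_score(co, regions = c(r, "Amygdala_L"),
                              score_field = "faq", group = "A4+T+")
  expect_gt(res$r[res$region == r], 0.95)
  expect_equal(res$n, c(12, 12))

  co$subjects$faq <- rep(5L, 12)
  expect_error(correlate_with_score(co, r, "faq", "A4+T+"), "constant")

  co$subjects$faq <- c(NA, as.integer(rep(c(3L, 9L), 5)), NA)
  expect_message(res2 <- correlate_with_score(co, r, "faq", "A4+T+"),
                 "missing")
  expect_equal(res2$n, 10)

  # planted FAQ coupling gives positive correlations in the coupled group
  sim <- generate_cohort(simulation_config(seed = 71))
  faq_res <- correlate_with_score(sim$cohort, sim$truth$effect_regions,
                                  "faq", sim$truth$faq_group)
  expect_gt(mean(faq_res$r), 0)
  expect_gt(mean(faq_res$r > 0), 0.8)
})

test_that("CSF-PET correlations include a faithful global term", {
  co <- toy_cohort(n_per_group = 12, groups = "A4+T+", seed = 55)
  co$subjects$csf_ttau <- 320 + 100 * (rowMeans(co$values) -
                                         min(rowMeans(co$values)))
  res <- correlate_csf_pet(co, "A4+T+")
  expect_equal(res$r[res$region == "global_mean"], 1, tolerance = 1e-9)

  # planted coupling: the coupled regions rank top by |r|
  sim <- generate_cohort(simulation_config(seed = 81))
  res2 <- correlate_csf_pet(sim$cohort, sim$truth$csf_group)
  regional <- res2[res2$region != "global_mean", ]
  top5 <- regional$region[order(-abs(regional$r))][1:5]
  expect_gt(length(intersect(sim$truth$csf_regions, top5)), 0)
})
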