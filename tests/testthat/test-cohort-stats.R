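test_that("group summaries report mean and SEM per cell", {
  tab <- data.frame(
    animal = c("a1", "a2", "a3"), group = "g", timepoint = "d2",
    metric = "m", value = c(1, 2, 3))
  s <- summarize_metric(tab, "m")
  expect_equal(nrow(s), 1)
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$n, 3L)
  expect_error(summarize_metric(tab, "absent"), "absent")
})

test_that("cohort sample means land within 3 SEM of generative truth", {
  set.seed(44)
  tab <- random_study_table(n_per_group = c(ctl = 30, trt = 30),
                            timepoints = "d2", mu = 5, sd = 1)
  s <- summarize_metric(tab, "m")
  expect_true(all(abs(s$mean - 5) < 3 * s$sem))
})

test_that("pooled-variance t-test matches the closed-form oracle", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  got <- unpaired_t_test(a, b)
  oracle <- pooled_t_oracle(a, b)
  expect_equal(got$t, oracle$t, tolerance = 1e-10)
  expect_equal(got$df, oracle$df)
  expect_equal(got$p, oracle$p, tolerance = 1e-10)
  # closed form: t = -1 / sqrt(sp2 * 1/2) with sp2 = 5/3, df = 6
  expect_equal(got$t, -1 / sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(got$p, 0.3153335962, tolerance = 1e-9)

  set.seed(17)
  for (k in 1:20) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), 0.5)
    got <- unpaired_t_test(a, b)
    oracle <- pooled_t_oracle(a, b)
    expect_equal(got$t, oracle$t, tolerance = 1e-10)
    expect_equal(got$p, oracle$p, tolerance = 1e-10)
  }
})

test_that("t-test is symmetric and handles identical samples", {
  a <- rnorm(5); b <- rnorm(6)
  ab <- unpaired_t_test(a, b); ba <- unpaired_t_test(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  same <- unpaired_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(unpaired_t_test(1, c(1, 2)), "n >= 2")
})

test_that("mixed ANOVA matches the classical sums-of-squares oracle", {
  set.seed(23)
  tab <- random_study_table(n_per_group = c(ctl = 5, trt = 5),
                            mu = 2, sd = 1, subject_sd = 0.7)
  tab$value <- tab$value + ifelse(tab$group == "trt", 0.8, 0)
  res <- rm_anova_bonferroni(tab, "m")
  oracle <- mixed_anova_oracle(tab$value, tab$group, tab$timepoint,
                               tab$animal)
  expect_equal(res$anova$F[res$anova$effect == "group"], oracle$group$F,
               tolerance = 1e-8)
  expect_equal(res$anova$p[res$anova$effect == "group"], oracle$group$p,
               tolerance = 1e-8)
  expect_equal(res$anova$F[res$anova$effect == "time"], oracle$time$F,
               tolerance = 1e-8)
  expect_equal(res$anova$p[res$anova$effect == "group:time"],
               oracle$interaction$p, tolerance = 1e-8)
})

test_that("Bonferroni post tests multiply raw p by the timepoint count", {
  set.seed(29)
  tab <- random_study_table(n_per_group = c(ctl = 4, trt = 4))
  res <- rm_anova_bonferroni(tab, "m")
  for (i in seq_len(nrow(res$posthoc))) {
    tp <- res$posthoc$timepoint[i]
    a <- tab$value[tab$timepoint == tp & tab$group == "ctl"]
    b <- tab$value[tab$timepoint == tp & tab$group == "trt"]
    raw <- unpaired_t_test(a, b)$p
    expect_equal(res$posthoc$p_raw[i], raw)
    expect_equal(res$posthoc$p_adj[i], min(1, raw * 4))
  }
})

test_that("incomplete animals are dropped complete-case with a warning", {
  set.seed(37)
  tab <- random_study_table(n_per_group = c(ctl = 4, trt = 4))
  tab <- tab[!(tab$animal == "ctl01" & tab$timepoint == "d7"), ]
  expect_warning(res <- rm_anova_bonferroni(tab, "m"), "ctl01")
  # 7 animals x 4 timepoints remain
  expect_equal(res$anova$df_error[res$anova$effect == "group"], 5)
})

test_that("strong group separation is detected essentially always", {
  set.seed(41)
  hits <- 0L
  for (r in 1:50) {
    tab <- random_study_table(n_per_group = c(ctl = 5, trt = 5), sd = 1)
    tab$value <- tab$value + ifelse(tab$group == "trt", 5, 0)
    res <- rm_anova_bonferroni(tab, "m")
    if (res$anova$p[res$anova$effect == "group"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 49L)
})

test_that("study tables with duplicate keys are rejected", {
  tab <- data.frame(animal = c("a", "a"), group = "g", timepoint = "d2",
                    metric = "m", value = c(1, 2))
  expect_error(summarize_metric(tab, "m"), "duplicate")
})
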