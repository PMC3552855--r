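toy_table <- function() {
  # three donors x four shear rates
  tibble::tibble(
    donor_id = rep(1:3, each = 4),
    shear_rate = rep(c(150, 300, 750, 1500), 3),
    sc_end = c(0.5, 0.8, 0.3, 2.0,    # low binder (1500 ignored)
               0.5, 1.5, 0.3, 0.1,    # fails at 300
               5.0, 6.0, 3.0, 1.5))   # normal responder
}

test_that("low-binder rule flags SC<1% at 150/300/750 only", {
  tab <- classify_low_binders(toy_table())
  flags <- unique(tab[c("donor_id", "low_binder")])
  expect_equal(flags$low_binder, c(TRUE, FALSE, FALSE))
  # all donors above 1% everywhere: none flagged
  tab2 <- toy_table(); tab2$sc_end <- tab2$sc_end + 2
  expect_false(any(classify_low_binders(tab2)$low_binder))
  # idempotent and order-invariant
  once <- classify_low_binders(toy_table())
  twice <- classify_low_binders(once)
  expect_equal(once, twice)
  shuffled <- toy_table()[sample(12), ]
  re <- classify_low_binders(shuffled)
  expect_equal(
    dplyr::arrange(re, donor_id, shear_rate)$low_binder,
    dplyr::arrange(once, donor_id, shear_rate)$low_binder)
  # missing a required shear rate is an error
  expect_error(classify_low_binders(toy_table()[-1, ]), "missing required")
})

test_that("quartile summary bins donors lower-inclusively by covariate", {
  tab <- tibble::tibble(
    donor_id = rep(1:8, each = 1),
    shear_rate = 300,
    vwf_level = seq(10, 80, by = 10),
    sc_end = seq(1, 8))
  qs <- quartile_summary(tab)
  expect_equal(nrow(qs), 4L)
  expect_equal(qs$n, rep(2L, 4))
  expect_equal(qs$mean, c(1.5, 3.5, 5.5, 7.5))
  # constant covariate: too few distinct values
  tab$vwf_level <- 50
  expect_error(quartile_summary(tab), "distinct")
})

test_that("quartile means of coverage rise with VWF in a coupled cohort", {
  cohort <- sample_cohort(50, seed = 61)
  tab <- simulate_cohort_runs(cohort, seed = 62)
  qs <- quartile_summary(tab)
  for (sr in unique(qs$shear_rate)) {
    m <- qs$mean[qs$shear_rate == sr]
    expect_true(all(diff(m) >= 0))
  }
})

test_that("Mann-Whitney: identical outcomes give p = 1, U + U' = n1 n2", {
  tab <- tibble::tibble(
    donor_id = 1:10, shear_rate = 150,
    sex = rep(c("F", "M"), 5), sc_end = rep(4.2, 10))
  res <- association_tests(tab, outcomes = "sc_end", covariates = "sex")
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 25 / 2)
  # complementarity on unequal data
  set.seed(71)
  tab$sc_end <- runif(10)
  u1 <- association_tests(tab, outcomes = "sc_end",
                          covariates = "sex")$statistic
  tab2 <- tab; tab2$sex <- ifelse(tab$sex == "F", "M", "F")
  u2 <- association_tests(tab2, outcomes = "sc_end",
                          covariates = "sex")$statistic
  expect_equal(u1 + u2, 25)
})

test_that("Spearman: perfect monotone pairing gives rho = 1, invariant to transforms", {
  tab <- tibble::tibble(
    donor_id = 1:10, shear_rate = 750,
    vwf_level = 1:10, sc_end = (1:10)^2)
  res <- association_tests(tab, outcomes = "sc_end", covariates = "vwf_level")
  expect_equal(res$estimate, 1)
  # strictly monotone transform of either variable leaves rho unchanged
  set.seed(81)
  tab$sc_end <- rnorm(10)
  r0 <- association_tests(tab, outcomes = "sc_end",
                          covariates = "vwf_level")$estimate
  tab$vwf_level <- exp(tab$vwf_level / 3)
  r1 <- association_tests(tab, outcomes = "sc_end",
                          covariates = "vwf_level")$estimate
  expect_equal(r0, r1)
})

test_that("undefined lag/velocity rows are excluded and small groups skipped", {
  tab <- tibble::tibble(
    donor_id = 1:6, shear_rate = 150,
    sex = c("F", "F", "F", "F", "F", "M"),
    vwf_level = c(50, 60, 70, 80, 90, 100),
    sc_end = c(0.4, 3, 4, 5, 6, 7),
    lag_time_s = c(NA, 70, 63, 56, 49, 42),
    reached_1pct = c(FALSE, rep(TRUE, 5)))
  res <- association_tests(tab, outcomes = "lag_time_s",
                           covariates = c("vwf_level", "sex"))
  sp <- res[res$test == "spearman", ]
  expect_equal(sp$estimate, -1)  # computed on the 5 defined rows only
  mw <- res[res$test == "mann_whitney", ]
  expect_true(is.na(mw$p_value))
  expect_match(mw$note, "fewer than 2")
})

test_that("three-level factors use Kruskal-Wallis with Tukey HSD pairs", {
  set.seed(91)
  tab <- tibble::tibble(
    donor_id = 1:18, shear_rate = 300,
    grp = rep(c("a", "b", "c"), each = 6),
    sc_end = c(rnorm(6, 2), rnorm(6, 5), rnorm(6, 12)))
  res <- association_tests(tab, outcomes = "sc_end", covariates = "grp")
  expect_true("kruskal_wallis" %in% res$test)
  expect_equal(sum(grepl("tukey_hsd", res$test)), 3L)  # 3 pairwise rows
  kw <- res[res$test == "kruskal_wallis", ]
  expect_lt(kw$p_value, 0.01)
  # matches stats::kruskal.test directly
  expect_equal(kw$statistic,
               unname(kruskal.test(tab$sc_end, factor(tab$grp))$statistic))
})

test_that("two-way ANOVA interaction term is reported when requested", {
  set.seed(95)
  tab <- tibble::tibble(
    donor_id = 1:40, shear_rate = 300,
    sex = rep(c("F", "M"), 20),
    gp6_genotype = rep(c("AA", "AA", "AG", "AG"), 10),
    sc_end = rnorm(40, 8))
  res <- association_tests(tab, outcomes = "sc_end", covariates = character(),
                           interactions = list(c("sex", "gp6_genotype")))
  expect_equal(res$test, "two_way_anova_interaction")
  expect_true(is.finite(res$p_value))
})
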