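test_that("RILT binarization follows the grade >= 2 rule", {
  expect_identical(rilt_event(0:5), c(0L, 0L, 1L, 1L, 1L, 1L))
  expect_error(rilt_event(6), "0..5")
  expect_error(rilt_event(-1), "0..5")
  expect_error(rilt_event(1.5), "0..5")
  # monotone non-decreasing in grade
  expect_true(all(diff(rilt_event(0:5)) >= 0))
})

test_that("Spearman matches hand-computed tie-corrected values", {
  # x = 1..5, y = (1,1,2,2,3): average ranks of y are (1.5,1.5,3.5,3.5,5);
  # Pearson of (1..5) with those ranks is 9/sqrt(90)
  s <- spearman_cor(1:5, c(1, 1, 2, 2, 3))
  expect_equal(s$r, 9 / sqrt(90), tolerance = 1e-15)

  expect_equal(spearman_cor(1:6, (1:6)^3)$r, 1)
  expect_equal(spearman_cor(1:6, -(1:6)^3)$r, -1)
  expect_equal(spearman_cor(1:6, (1:6)^3)$p, 0)

  # independent oracle: base cor.test's rho and t-approximation p-value
  set.seed(55)
  for (i in 1:20) {
    x <- sample(1:8, 30, replace = TRUE)
    y <- sample(1:4, 30, replace = TRUE)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    s <- spearman_cor(x, y)
    expect_equal(s$r, unname(ct$estimate), tolerance = 1e-12)
  }

  expect_error(spearman_cor(1:5, rep(2, 5)), "constant")
  expect_error(spearman_cor(1:5, 1:4), "equal length")
  expect_error(spearman_cor(1:2, 2:1), "at least 3")
})

test_that("Spearman is symmetric and invariant under monotone transforms", {
  set.seed(66)
  x <- rnorm(40); y <- rnorm(40) + 0.5 * x
  expect_equal(spearman_cor(x, y)$r, spearman_cor(y, x)$r)
  for (f in list(function(u) exp(u), function(u) u^3, function(u) rank(u))) {
    expect_equal(spearman_cor(f(x), y)$r, spearman_cor(x, y)$r, tolerance = 1e-12)
  }
})

test_that("permutation p-values are seeded, valid and ordered like |r|", {
  set.seed(12)
  x <- rnorm(20); y <- 0.6 * x + rnorm(20)
  p1 <- spearman_cor(x, y, p_method = "permutation", n_perm = 500, seed = 3)$p
  p2 <- spearman_cor(x, y, p_method = "permutation", n_perm = 500, seed = 3)$p
  expect_identical(p1, p2)
  expect_error(spearman_cor(x, y, p_method = "permutation"), "seed")

  # stronger |r| gives smaller p for both methods on the same n
  y_strong <- x + 0.1 * rnorm(20)
  for (m in c("t_approx", "permutation")) {
    ps <- spearman_cor(x, y_strong, p_method = m, n_perm = 2000, seed = 5)$p
    pw <- spearman_cor(x, y, p_method = m, n_perm = 2000, seed = 5)$p
    expect_lt(ps, pw)
  }
})

test_that("subgroup tables flag non-computable strata and honor stratifiers", {
  co <- simulate_cohort(cohort_spec(), seed = 2)

  # constant outcome in a stratum: force all COPD patients to grade 0
  co2 <- co
  co2$rilt_grade[co2$copd == "yes"] <- 0L
  tab <- subgroup_correlations(co2, strata = "copd")
  copd_rows <- tab[tab$subgroup == "COPD", ]
  expect_true(all(!copd_rows$computable))
  expect_true(all(is.na(copd_rows$r)))
  expect_identical(unique(copd_rows$dominance), "n/a")

  # single-level stratifier behaves as the all-patients analysis
  co3 <- co
  co3$copd <- "yes"
  tab3 <- subgroup_correlations(co3, strata = "copd")
  all_r <- tab3$r[tab3$subgroup == "All patients"]
  expect_equal(tab3$r[tab3$subgroup == "COPD"], all_r)
  expect_equal(nrow(tab3[tab3$subgroup == "Non-COPD", ]), 6)
  expect_true(all(!tab3$computable[tab3$subgroup == "Non-COPD"]))

  expect_error(subgroup_correlations(co, strata = "smoking"), "unknown stratifier")
})

test_that("dominance labels follow the family-mean epsilon rule", {
  mk <- function(r6) tibble::tibble(metric = c("V20", "MLD", "Q_V20", "Q_MLD",
                                               "V_V20", "V_MLD"),
                                    r = r6, computable = TRUE)
  # family means V = 0.70, Q = 0.69, CT = 0.40
  lab <- dominance_label(mk(c(0.40, 0.40, 0.69, 0.69, 0.70, 0.70)))
  expect_identical(dominance_groups(lab), list(c("Q", "V"), "CT"))
  expect_match(lab, "^V")   # V leads inside the tied group

  expect_identical(
    dominance_groups(dominance_label(mk(rep(0.5, 6)))),
    list(c("CT", "Q", "V"))
  )
  lab3 <- dominance_label(mk(c(0.45, 0.45, 0.60, 0.60, 0.75, 0.75)))
  expect_identical(dominance_groups(lab3), list("V", "Q", "CT"))

  res_na <- mk(c(0.4, 0.4, NA, NA, 0.7, 0.7))
  res_na$computable <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  expect_identical(dominance_label(res_na), "n/a")
})

test_that("characteristic comparisons pick tests by the expected-count rule", {
  co <- table1_fixture()
  tab <- compare_characteristics(co)
  expect_true(all(tab$computable))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))

  # the printed-style sex table (11,4 / 32,10) has an expected cell of
  # 15 * 14 / 57 = 3.68 < 5, so the 2x2 Fisher path must trigger
  expect_identical(tab$test[tab$covariate == "sex"], "fisher")

  # a large unbalanced 2x2 takes the Yates chi-square path and matches
  # the textbook continuity-corrected formula
  co_big <- tibble::tibble(
    rilt_grade = rep(c(0L, 2L), each = 100),
    copd = c(rep(c("yes", "no"), times = c(30, 70)),
             rep(c("yes", "no"), times = c(45, 55)))
  )
  tab_big <- compare_characteristics(co_big, covariates = "copd")
  expect_identical(tab_big$test, "chisq_yates")
  m <- table(rilt_event(co_big$rilt_grade), co_big$copd)
  n <- sum(m)
  num <- n * (abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]) - n / 2)^2
  den <- prod(rowSums(m)) * prod(colSums(m))
  expect_equal(tab_big$p_value, stats::pchisq(num / den, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # covariate identically distributed across groups by construction: p = 1
  co_null <- tibble::tibble(
    rilt_grade = rep(c(0L, 2L), each = 100),
    copd = rep(rep(c("yes", "no"), each = 50), 2)
  )
  expect_equal(compare_characteristics(co_null, covariates = "copd")$p_value, 1)

  # single-level covariate flagged not computable
  co_one <- co; co_one$sex <- "male"
  t1 <- compare_characteristics(co_one, covariates = "sex")
  expect_false(t1$computable)

  co_allev <- co; co_allev$rilt_grade <- 3L
  expect_error(compare_characteristics(co_allev), "both outcome groups")
})
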