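test_that("pearson validity reproduces closed-form r and assigns bands", {
  x <- c(1, 2, 3, 4, 5)
  pv <- pearson_validity(x, x)
  expect_equal(pv$r, 1)
  expect_equal(pv$band, "excellent")
  expect_equal(pearson_validity(x, -x)$r, -1)
  expect_equal(pearson_validity(x, -x)$band, "excellent")

  # printed-style 6-pair table vs the covariance-formula oracle
  a <- c(41, 25, 33, 52, 18, 46)
  b <- c(55, 40, 38, 60, 29, 52)
  pv <- pearson_validity(a, b)
  expect_equal(pv$r, pearson_oracle(a, b), tolerance = 1e-12)
  expect_equal(pv$p, stats::cor.test(a, b)$p.value)

  expect_error(pearson_validity(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_validity(1:2, 2:3), ">= 3")
})

test_that("validity bands are total and deterministic on [0, 1]", {
  r <- seq(-1, 1, by = 0.001)
  bands <- validity_band(r)
  expect_false(any(is.na(bands)))
  # half-open boundaries: 0.8 is strong, just above is excellent; 0.2 very weak
  expect_equal(validity_band(c(0.8, 0.8000001, 0.2, -0.6)), c("strong", "excellent", "very weak", "moderate"))
})

test_that("ICC(2,1) matches the two-way ANOVA oracle and known identities", {
  # columns are identical copies of differing rows -> ICC = 1
  m <- cbind(c(1, 5, 9, 3), c(1, 5, 9, 3))
  expect_equal(icc_2_1(m)$icc, 1)

  # 4 x 2 integer matrix vs the from-scratch aov decomposition
  m <- rbind(c(8, 7), c(5, 4), c(9, 9), c(2, 3))
  expect_equal(icc_2_1(m)$icc, icc_oracle_aov(m), tolerance = 1e-12)

  # absolute agreement penalises a constant rater shift
  m2 <- m
  m2[, 2] <- m2[, 2] + 3
  expect_lt(icc_2_1(m2)$icc, icc_2_1(m)$icc)

  # p-value equals the row-effect F test
  r <- icc_2_1(m)
  f <- r$msr / r$mse
  expect_equal(r$p, stats::pf(f, 3, 3, lower.tail = FALSE))

  expect_error(icc_2_1(matrix(2, 3, 2)), "zero total variance")
  expect_error(icc_2_1(matrix(1:2, 1, 2)), "n >= 2")
})

test_that("SEM and MDC95 follow their defining identities", {
  sc <- c(10, 12, 9, 14, 11)
  expect_equal(sem(sc, 1), 0)
  expect_equal(sem(sc, 0), stats::sd(sc))
  expect_error(sem(sc, 1.2), "<= 1")
  expect_error(mdc95(-1), ">= 0")
  expect_equal(mdc95(0), 0)
  # published-table spot checks: SEM 2.09 -> MDC 5.79; SEM 0.83 -> MDC 2.30
  expect_equal(round(mdc95(2.09), 2), 5.79)
  expect_equal(round(mdc95(0.83), 2), 2.30)
})

test_that("SEM recovers the error-implied value on simulated two-way data", {
  vc <- variance_components(9, 0.25, 0.25)
  # average over replicates to separate the estimator's bias from MC noise
  sems <- vapply(1:20, function(i) {
    y <- simulate_reliability(200, 2, mu = 30, vc = vc, seed = 500 + i)
    sem(as.vector(y), icc_2_1(y)$icc)
  }, 0)
  # theoretical within-subject error SD: sqrt(sigma2_s + sigma2_e)
  expect_lt(abs(mean(sems) - sqrt(0.5)) / sqrt(0.5), 0.15)
})

test_that("reliability_report bundles ICCs, SEM and the MDC identity", {
  vc <- variance_components(9, 0.5, 0.5)
  # columns: session 1 and 2 by rater A, session 3 by rater B, same cohort
  y3 <- simulate_reliability(23, 3, mu = 40, vc = vc, seed = 8)
  rep <- reliability_report(y3, "tap_count")
  expect_equal(rep$mdc95, 1.96 * sqrt(2) * rep$sem, tolerance = 1e-12)
  expect_gt(rep$icc_intra, 0.5)
  expect_gt(rep$icc_inter, 0.5)
  expect_equal(rep$n, 23)
  expect_error(reliability_report(y3[, 1:2]), "3 columns")
})

test_that("outlier removal flags cells beyond 3 SD and drops repeat offenders", {
  set.seed(2)
  base <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:20),
    m1 = rnorm(20, 10, 1), m2 = rnorm(20, 5, 1), m3 = rnorm(20, 0, 1), m4 = rnorm(20)
  )
  # nothing removed when all values are equal per measure (zero SD -> warning)
  const <- tibble::tibble(participant_id = c("a", "b", "c"), m = c(2, 2, 2))
  expect_warning(res <- remove_outliers(const), "zero-SD")
  expect_equal(nrow(res$table), 3L)
  expect_equal(nrow(res$log), 0L)

  # one cell far out -> that cell removed, participant kept
  t1 <- base
  t1$m1[4] <- mean(t1$m1[-4]) + 8 * sd(t1$m1[-4])
  res <- remove_outliers(t1)
  expect_true(is.na(res$table$m1[4]))
  expect_equal(res$log$participant_id, "P04")
  expect_equal(res$removed, character(0))
  expect_true("P04" %in% res$table$participant_id)

  # extreme in 3 measures -> participant dropped entirely
  t2 <- base
  for (mcol in c("m1", "m2", "m3")) t2[[mcol]][7] <- t2[[mcol]][7] + 40
  res <- remove_outliers(t2)
  expect_false("P07" %in% res$table$participant_id)
  expect_equal(res$removed, "P07")
})

test_that("severity classification follows the FMA-UE ranges", {
  expect_equal(classify_severity(38), "moderate")
  expect_equal(classify_severity(57), "mild")
  # boundary: 46 moderate, 47 mild
  expect_equal(classify_severity(c(46, 47)), c("moderate", "mild"))
  expect_equal(classify_severity(c(19, 66)), c("moderate", "mild"))
  expect_error(classify_severity(12), "out of scope")
  expect_error(classify_severity(70), "\\[0, 66\\]")
})

test_that("group comparison is the pooled-variance Student t", {
  g <- c(4, 5, 6)
  same <- compare_groups(g, g)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  x <- c(10, 14, 12); y <- c(7, 6, 9)
  cg <- compare_groups(x, y)
  expect_equal(cg$t, pooled_t_oracle(x, y), tolerance = 1e-12)
  expect_equal(cg$df, 4)
  # Welch variant differs on unequal variances
  expect_false(isTRUE(all.equal(
    compare_groups(x * 3, y, welch = TRUE)$df, 4
  )))
  expect_error(compare_groups(1, c(2, 3)), ">= 2")
})

test_that("group comparison has high power at the published tapping contrast", {
  # mild 43.97 (14.47) n=69 vs moderate 25.26 (13.51) n=19
  hits <- 0
  set.seed(31)
  n_rep <- 300
  for (i in seq_len(n_rep)) {
    mild <- rnorm(69, 43.97, 14.47)
    mod <- rnorm(19, 25.26, 13.51)
    if (compare_groups(mild, mod, alpha = 0.01)$significant) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("validity matrix covers all pairs and marks unavailable ones", {
  out <- tibble::tibble(participant_id = sprintf("P%d", 1:10), tapping = c(1:10))
  clin <- tibble::tibble(
    participant_id = sprintf("P%d", 1:10),
    dup = c(1:10), noise = c(5, 3, 8, 1, 9, 2, 7, 4, 10, 6)
  )
  vm <- validity_matrix(out, clin)
  expect_equal(nrow(vm), 2L)
  expect_equal(vm$r[vm$clinical == "dup"], 1)
  expect_true(vm$highlight[vm$clinical == "dup"])

  # disjoint participant keys -> all pairs unavailable
  clin2 <- clin
  clin2$participant_id <- sprintf("Q%d", 1:10)
  vm2 <- validity_matrix(out, clin2)
  expect_true(all(!vm2$available))
  expect_true(all(is.na(vm2$r)))
})
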