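test_that("seed connectivity matches the correlation matrix entry", {
  set.seed(1)
  m <- matrix(rnorm(300 * 4), 300, 4)
  colnames(m) <- c("VTA", "NAc", "BLA", "vmPFC")
  C <- correlation_matrix(m)
  expect_equal(
    seed_roi_connectivity(m, "VTA", "NAc"),
    atanh(C["VTA", "NAc"]),
    tolerance = 1e-12
  )
  # identical series: clipped, finite
  m2 <- cbind(VTA = m[, 1], copy = m[, 1])
  expect_equal(seed_roi_connectivity(m2, "VTA", "copy"), atanh(0.99))
  # independent noise at large T stays near zero
  set.seed(2)
  m3 <- matrix(rnorm(5000 * 2), 5000, 2)
  colnames(m3) <- c("VTA", "x")
  expect_lt(abs(seed_roi_connectivity(m3, "VTA", "x")), 0.05)
})

test_that("BH q-values match the hand step-up and its boundary cases", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(sample(2:12, 1))
    q <- bh_fdr(p)
    expect_equal(q, hand_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    # monotone in sorted p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("rank-sum test agrees with exact enumeration for all small samples", {
  # extreme separation: W = 0, two-sided p = 2/20
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$statistic, 0)
  expect_equal(rs$p_value, 0.1)
  set.seed(4)
  for (rep in 1:30) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- sample(1:8, n1, replace = TRUE) # replace => ties occur
    y <- sample(1:8, n2, replace = TRUE)
    rs <- rank_sum_test(x, y)
    expect_equal(rs$p_value, enumerate_rank_sum_p(x, y), tolerance = 1e-12)
    # symmetry under sample swap
    expect_equal(rank_sum_test(y, x)$p_value, rs$p_value, tolerance = 1e-12)
  }
})

test_that("rank-sum matches wilcox.test exactly on untied data", {
  set.seed(5)
  for (rep in 1:20) {
    x <- rnorm(sample(3:6, 1))
    y <- rnorm(sample(3:6, 1))
    rs <- rank_sum_test(x, y)
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(rs$statistic, unname(wt$statistic))
    expect_equal(rs$p_value, wt$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample rank-sum is calibrated under the null", {
  set.seed(6)
  ps <- replicate(400, rank_sum_test(rnorm(30), rnorm(35))$p_value)
  expect_lt(mean(ps < 0.05), 0.08)
  expect_gt(mean(ps < 0.05), 0.02)
})

test_that("signed-rank wrapper reports the paired statistic", {
  x <- c(1.2, 2.1, 3.3, 4.8, 5.0)
  y <- x + c(0.5, 0.4, 0.7, 0.2, 0.6)
  sr <- signed_rank_test(x, y)
  wt <- stats::wilcox.test(x, y, paired = TRUE)
  expect_equal(sr$statistic, unname(wt$statistic))
  expect_equal(sr$p_value, wt$p.value)
})

test_that("partial correlation reduces to Pearson and matches the Eq-3 form", {
  set.seed(7)
  x <- rnorm(50)
  y <- 0.5 * x + rnorm(50)
  plain <- adjusted_partial_correlation(x, y, NULL)
  expect_equal(plain$estimate, cor(x, y), tolerance = 1e-12)
  ct <- stats::cor.test(x, y)
  expect_equal(plain$p_value, ct$p.value, tolerance = 1e-10)

  # single covariate: equals the correlation-matrix partial correlation
  z <- rnorm(50)
  x2 <- 0.6 * z + rnorm(50)
  y2 <- 0.4 * z + rnorm(50)
  C <- cor(cbind(x2, y2, z))
  adj <- adjusted_partial_correlation(x2, y2, data.frame(z = z))
  expect_equal(adj$estimate, partial_correlation(C, 1, 2, 3),
    tolerance = 1e-10
  )
})

test_that("planted score-connectivity links are detected with correct sign", {
  set.seed(8)
  hits <- replicate(40, {
    n <- 60
    z <- rnorm(n)
    conn <- 0.5 * z + rnorm(n) * sqrt(1 - 0.25)
    res <- adjusted_partial_correlation(conn, z, NULL)
    res$p_value < 0.05 && res$estimate > 0
  })
  expect_gte(mean(hits), 0.9)
})

test_that("shuffled scores give uniform p-values", {
  set.seed(9)
  ps <- replicate(300, {
    adjusted_partial_correlation(rnorm(40), rnorm(40),
      data.frame(a = rnorm(40))
    )$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("group-difference family analysis applies BH across ROIs", {
  set.seed(10)
  n <- 50
  ids <- sprintf("s%02d", 1:n)
  grp <- rep(c("HC", "MDD"), length.out = n)
  rois <- c("NAc", "BLA", "vmPFC", "dmPFC", "sgACC", "plACC", "hippocampus")
  conn <- tidyr::expand_grid(subject_id = ids, roi = rois) |>
    dplyr::mutate(z = rnorm(dplyr::n(), sd = 0.3))
  # plant a shift in NAc for MDD
  mdd_nac <- conn$roi == "NAc" & grp[match(conn$subject_id, ids)] == "MDD"
  conn$z[mdd_nac] <- conn$z[mdd_nac] + 0.5
  co <- make_cohort_table(ids, grp)
  res <- adjusted_group_difference(conn, co)
  expect_equal(nrow(res), 7L)
  expect_equal(res$family_size[1], 7L)
  expect_equal(res$roi[which.min(res$q_fdr)], "NAc")
  expect_true(all(res$q_fdr >= res$p_value - 1e-12))
  # collinear covariate errors loudly
  co_bad <- dplyr::mutate(co, grp2 = group)
  expect_error(
    adjusted_group_difference(conn, co_bad,
      covariates = c("age", "grp2")
    ),
    "collinear"
  )
})

test_that("Spearman correlation handles ranks, ties and boundaries", {
  x <- c(2, 5, 1, 9, 4)
  expect_equal(cross_state_spearman(x, exp(x))$rho, 1)
  expect_equal(cross_state_spearman(x, -x)$rho, -1)
  set.seed(11)
  x5 <- rnorm(5)
  y5 <- rnorm(5)
  cs <- cross_state_spearman(x5, y5)
  # direct rank-formula computation
  expect_equal(cs$rho, cor(rank(x5), rank(y5)), tolerance = 1e-12)
  ct <- suppressWarnings(
    stats::cor.test(x5, y5, method = "spearman", exact = FALSE)
  )
  expect_equal(cs$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(cs$p_value, ct$p.value, tolerance = 1e-10)
  expect_error(cross_state_spearman(rep(1, 5), rnorm(5)), "constant")
  expect_error(cross_state_spearman(rnorm(3), rnorm(3)), "n >= 4")
})

test_that("mixed model recovers the learning-curve structure", {
  # zero between-subject variance: fixed effects match OLS
  set.seed(12)
  df <- tidyr::expand_grid(
    subject_id = sprintf("s%02d", 1:20),
    trial = 1:20
  ) |>
    dplyr::mutate(
      group = ifelse(subject_id <= "s10", "HC", "MDD"),
      trial_type = rep(c("gain", "loss"), length.out = dplyr::n()),
      correct = runif(dplyr::n()) < 0.7
    )
  mm <- suppressMessages(learning_mixed_model(df))
  ols <- lm(
    as.numeric(correct) ~ group * factor(trial_type, c("loss", "gain")) + trial,
    data = df
  )
  expect_equal(sort(mm$estimate), sort(unname(coef(ols))), tolerance = 1e-6)
  expect_equal(sum(mm$interaction), 1L)
  expect_error(
    learning_mixed_model(dplyr::select(df, -group)),
    "Missing columns"
  )
})
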