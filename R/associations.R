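#' Fisher-z seed-to-ROI connectivity
#'
#' Pearson correlation between the seed node's series and a target ROI's
#' series, Fisher-z transformed. Correlations at |r| = 1 are clipped to
#' 0.99 before the transform (the same policy as the dependency analysis),
#' keeping the value finite.
#'
#' @param series Timepoints-by-nodes matrix with labeled columns.
#' @param seed_label,roi_label Column labels.
#' @return Scalar Fisher-z connectivity.
#' @export
seed_roi_connectivity <- function(series, seed_label = "VTA", roi_label) {
  series <- as.matrix(series)
  if (!all(c(seed_label, roi_label) %in% colnames(series))) {
    stop("Seed or ROI label not present in the series.", call. = FALSE)
  }
  if (nrow(series) < 3L) stop("Need at least 3 timepoints.", call. = FALSE)
  x <- series[, seed_label]
  y <- series[, roi_label]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("Constant time series for ", seed_label, " or ", roi_label, ".",
      call. = FALSE
    )
  }
  fisher_z(cor(x, y))
}

#' Seed connectivity table for a panel
#'
#' @param panel Nested tibble (`subject_id`, `series`).
#' @param seed_label Seed node (default `"VTA"`).
#' @param state Brain-state label stored with the rows (default
#'   `"task_free"`).
#' @return Long tibble: `subject_id`, `roi`, `z`, `state`.
#' @export
connectivity_table <- function(panel, seed_label = "VTA",
                               state = "task_free") {
  purrr::map2(panel$subject_id, panel$series, function(id, m) {
    rois <- setdiff(colnames(m), seed_label)
    tibble::tibble(
      subject_id = id,
      roi = rois,
      z = vapply(rois, function(r) {
        seed_roi_connectivity(m, seed_label, r)
      }, numeric(1)),
      state = state
    )
  }) |>
    purrr::list_rbind()
}

#' Benjamini-Hochberg q-values
#'
#' Standard BH step-up with monotonicity enforcement,
#' `q_(i) = min_(j >= i) m p_(j) / j`.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Covariate-adjusted group difference per ROI
#'
#' For each ROI, OLS of the connectivity value on the group label plus
#' nuisance covariates; BH-FDR is applied across the ROI family.
#'
#' @param conn Connectivity tibble from [connectivity_table()] (columns
#'   `subject_id`, `roi`, `z`).
#' @param cohort Cohort tibble.
#' @param covariates Nuisance columns
#'   (default `c("age", "sex", "medicated", "daw")`).
#' @param group_col Grouping column (default `"group"`).
#' @return Association tibble, one row per ROI, with `q_fdr` over the
#'   family.
#' @export
adjusted_group_difference <- function(conn, cohort,
                                      covariates = c(
                                        "age", "sex", "medicated", "daw"
                                      ),
                                      group_col = "group") {
  res <- conn |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_map(function(df, key) {
      df <- dplyr::inner_join(df, cohort, by = "subject_id")
      out <- adjusted_ols(df, "z", group_col, covariates,
        analysis = paste0("z(", key$roi, ")~", group_col)
      )
      dplyr::mutate(out, roi = key$roi, .before = 1)
    }) |>
    purrr::list_rbind()
  res$q_fdr <- bh_fdr(res$p_value)
  res$family_size <- nrow(res)
  res
}

#' Covariate-adjusted partial correlation
#'
#' Partial Pearson correlation between two vectors after residualizing
#' both on the covariate columns (double residualization); the t test uses
#' `n - 2 - k` degrees of freedom for `k` covariate regressors. With no
#' covariates this reduces to the plain Pearson correlation test.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame of covariates (or NULL).
#' @param analysis Label stored in the result.
#' @return One-row association tibble: `analysis`, `estimate` (partial r),
#'   `statistic`, `p_value`, `n`, `covariates`.
#' @export
adjusted_partial_correlation <- function(x, y, covariates = NULL,
                                         analysis = "partial_correlation") {
  df <- data.frame(x = x, y = y)
  k <- 0L
  cov_names <- ""
  if (!is.null(covariates) && length(covariates) > 0L &&
    NCOL(covariates) > 0L) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
    keep <- complete.cases(df)
    df <- df[keep, , drop = FALSE]
    mm <- model.matrix(~., data = df[, -(1:2), drop = FALSE])
    k <- ncol(mm) - 1L
    rx <- stats::lm.fit(mm, df$x)$residuals
    ry <- stats::lm.fit(mm, df$y)$residuals
    cov_names <- paste(colnames(covariates), collapse = ",")
  } else {
    df <- df[complete.cases(df), , drop = FALSE]
    rx <- df$x
    ry <- df$y
  }
  n <- nrow(df)
  if (n < k + 4L) stop("Too few complete cases.", call. = FALSE)
  r <- cor(rx, ry)
  dof <- n - 2L - k
  tstat <- r * sqrt(dof / (1 - r^2))
  tibble::tibble(
    analysis = analysis,
    estimate = r,
    statistic = tstat,
    p_value = 2 * pt(-abs(tstat), dof),
    n = n,
    covariates = cov_names
  )
}

#' Symptom/hormone partial correlations across an ROI family
#'
#' Runs [adjusted_partial_correlation()] between a per-subject score and
#' the seed connectivity of every ROI, with BH-FDR across the family.
#'
#' @param conn Connectivity tibble (`subject_id`, `roi`, `z`).
#' @param cohort Cohort tibble containing `score_col` and the covariates.
#' @param score_col Score column name (e.g. `"teps_a"`).
#' @param covariates Covariate column names.
#' @return Association tibble, one row per ROI, with `q_fdr`.
#' @export
score_roi_correlations <- function(conn, cohort, score_col,
                                   covariates = c(
                                     "age", "sex", "medicated", "daw"
                                   )) {
  res <- conn |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_map(function(df, key) {
      df <- dplyr::inner_join(df, cohort, by = "subject_id")
      covs <- if (length(covariates)) df[, covariates, drop = FALSE] else NULL
      out <- adjusted_partial_correlation(
        df$z, df[[score_col]], covs,
        analysis = paste0("z(", key$roi, ")~", score_col)
      )
      dplyr::mutate(out, roi = key$roi, .before = 1)
    }) |>
    purrr::list_rbind()
  res$q_fdr <- bh_fdr(res$p_value)
  res$family_size <- nrow(res)
  res
}

#' Wilcoxon rank-sum test (Mann-Whitney)
#'
#' Two-sided rank-sum test with midrank ties. For small samples
#' (`choose(n, n1)` at or below `exact_limit`) the null distribution of
#' the rank sum is enumerated exactly over all group assignments of the
#' observed (mid)ranks, so ties are handled without approximation; larger
#' samples use the normal approximation with tie correction and
#' continuity correction. The reported `W` is the Mann-Whitney U of the
#' first sample (rank sum minus its minimum), matching the common
#' convention.
#'
#' @param x,y Numeric samples.
#' @param exact_limit Maximum number of enumerated assignments
#'   (default 20000).
#' @return A list: `statistic` (W), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_limit = 20000) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("Both samples must be non-empty.", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 # Mann-Whitney U of x
  n_assign <- choose(n1 + n2, n1)
  if (n_assign <= exact_limit) {
    combos <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(us - mu) >= abs(w - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    zstat <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(zstat))
    method <- "normal approximation"
  }
  list(statistic = w, p_value = min(1, p), method = method)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Thin wrapper over [stats::wilcox.test()] with `paired = TRUE`, exposed
#' alongside [rank_sum_test()] so paired contrasts use the matching
#' procedure.
#'
#' @param x,y Paired numeric samples (or `y = NULL` for a one-sample
#'   test against zero).
#' @param ... Passed to [stats::wilcox.test()].
#' @return A list: `statistic` (V), `p_value`, `method`.
#' @export
signed_rank_test <- function(x, y = NULL, ...) {
  ht <- if (is.null(y)) {
    stats::wilcox.test(x, ...)
  } else {
    stats::wilcox.test(x, y, paired = TRUE, ...)
  }
  list(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    method = ht$method
  )
}

#' Mixed-effects learning-curve model
#'
#' Fits `correct ~ group * trial_type + trial + (1 | subject_id)` to the
#' gain/loss trials of a behavioral table (linear probability model, as
#' the formula implies; set `logistic = TRUE` for the GLMM variant) and
#' reports the fixed-effect coefficient table with the group-by-trial-type
#' interaction row flagged. A singular random-effects fit is reported via
#' the `singular` attribute rather than an error.
#'
#' @param trial_table Long behavior tibble with `subject_id`, `group`,
#'   `trial_type`, `trial`, `correct`.
#' @param logistic Fit a binomial GLMM instead of the linear model.
#' @return Tibble of fixed effects: `term`, `estimate`, `std.error`,
#'   `statistic`, `p_value`, `interaction` (logical flag).
#' @export
learning_mixed_model <- function(trial_table, logistic = FALSE) {
  need <- c("subject_id", "group", "trial_type", "trial", "correct")
  if (!all(need %in% names(trial_table))) {
    stop("Missing columns: ", paste(setdiff(need, names(trial_table)),
      collapse = ", "
    ), call. = FALSE)
  }
  df <- trial_table |>
    dplyr::filter(.data$trial_type %in% c("gain", "loss")) |>
    dplyr::mutate(
      correct = as.numeric(.data$correct),
      group = factor(.data$group),
      # loss as reference level: a gain-specific deficit in the second
      # group shows up as a negative group:trial_type interaction
      trial_type = factor(.data$trial_type, levels = c("loss", "gain"))
    )
  if (length(unique(df$group)) < 2L) {
    stop("Need two groups.", call. = FALSE)
  }
  fit <- if (logistic) {
    lme4::glmer(
      correct ~ group * trial_type + trial + (1 | subject_id),
      data = df, family = stats::binomial()
    )
  } else {
    lmerTest::lmer(
      correct ~ group * trial_type + trial + (1 | subject_id),
      data = df
    )
  }
  ct <- coef(summary(fit))
  pcol <- grep("^Pr", colnames(ct))
  out <- tibble::tibble(
    term = rownames(ct),
    estimate = unname(ct[, "Estimate"]),
    std.error = unname(ct[, "Std. Error"]),
    statistic = unname(ct[, grep("value$", colnames(ct))[1]]),
    p_value = if (length(pcol)) unname(ct[, pcol]) else NA_real_,
    interaction = grepl(":", rownames(ct))
  )
  attr(out, "singular") <- lme4::isSingular(fit)
  out
}

#' Spearman correlation across brain states
#'
#' Midrank-based Spearman rho with the t approximation for the two-sided
#' p-value, for relating a subject-wise connectivity estimate across
#' task-free and task-based states.
#'
#' @param x,y Equal-length numeric vectors (n >= 4), neither constant.
#' @return A list: `rho`, `p_value`, `n`.
#' @export
cross_state_spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4L) {
    stop("Need equal-length vectors with n >= 4.", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("Spearman correlation undefined for constant input.", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  n <- length(x)
  if (abs(rho) >= 1) {
    return(list(rho = rho, p_value = 0, n = n))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * pt(-abs(tstat), n - 2), n = n)
}
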