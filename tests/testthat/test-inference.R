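make_record <- function(params, seed = 1, n = 30) {
  sch <- generate_schedule(task_config(n_trials_per_type = n), seed = seed)
  simulate_agent(params, sch, seed = seed + 1000, subject_id = "s01")
}

test_that("pointwise log-likelihood matches the naive replay oracle", {
  set.seed(1)
  for (rep in 1:5) {
    p <- agent_params(
      beta = runif(1, 0.5, 8),
      alpha_gain = runif(1), alpha_loss = runif(1)
    )
    rec <- make_record(p, seed = rep)
    ll <- log_likelihood(p, rec)
    expect_equal(ll,
      naive_loglik(p$alpha_gain, p$alpha_loss, p$beta, rec),
      tolerance = 1e-10
    )
  }
})

test_that("uniform-policy and single-trial likelihoods equal log(1/2)", {
  p <- agent_params(beta = 1e-9, alpha_gain = 0.5, alpha_loss = 0.5)
  rec <- make_record(p, seed = 2)
  expect_equal(log_likelihood(p, rec), rep(log(0.5), nrow(rec)))
  one <- tibble::tibble(
    subject_id = "s01", trial = 1L, trial_type = "gain",
    pair = 1L, choice = 1L, outcome = 1
  )
  p2 <- agent_params(beta = 7, alpha_gain = 0.9, alpha_loss = 0.1)
  expect_equal(log_likelihood(p2, one), log(0.5))
})

test_that("no-response trials contribute exactly zero", {
  p <- agent_params(beta = 3, alpha_gain = 0.5, alpha_loss = 0.5)
  rec <- make_record(p, seed = 3)
  rec$no_response <- FALSE
  rec$no_response[c(4, 9)] <- TRUE
  ll <- log_likelihood(p, rec)
  expect_equal(ll[c(4, 9)], c(0, 0))
  expect_true(all(ll[-c(4, 9)] < 0))
})

test_that("generating parameters dominate perturbed ones in likelihood", {
  set.seed(4)
  wins <- replicate(100, {
    p <- agent_params(beta = 5, alpha_gain = 0.5, alpha_loss = 0.5)
    rec <- make_record(p, seed = sample.int(1e6, 1), n = 150)
    shift <- agent_params(beta = 5, alpha_gain = 0.8, alpha_loss = 0.8)
    sum(log_likelihood(p, rec)) >= sum(log_likelihood(shift, rec))
  })
  expect_gte(mean(wins), 0.95)
})

test_that("hierarchical fits are deterministic and respect supports", {
  beh <- make_behavior_cohort(5, c(0.4, 0.4), seed = 5)
  f1 <- fit_hierarchical(dplyr::select(beh, -group), model_spec(2),
    chains = 2, iter_warmup = 150, iter_sampling = 150, seed = 42
  )
  f2 <- fit_hierarchical(dplyr::select(beh, -group), model_spec(2),
    chains = 2, iter_warmup = 150, iter_sampling = 150, seed = 42
  )
  expect_identical(f1$group_draws, f2$group_draws)
  expect_identical(f1$log_lik, f2$log_lik)

  sd_ <- f1$subject_draws
  a_cols <- grep("^alpha", colnames(sd_))
  b_cols <- grep("^beta", colnames(sd_))
  expect_true(all(sd_[, a_cols] >= 0 & sd_[, a_cols] <= 1))
  expect_true(all(sd_[, b_cols] > 0))
  expect_true(all(grepl("sigma", f1$group_draws |> colnames()) |
    is.finite(f1$group_draws)))
  expect_equal(dim(f1$log_lik), c(300L, nrow(beh)))
})

test_that("a shared true parameter set shrinks the group-level scale", {
  cfg <- task_config()
  set.seed(6)
  p <- agent_params(beta = 5, alpha_gain = 0.45, alpha_loss = 0.45)
  beh <- purrr::map(1:20, function(s) {
    simulate_agent(p, generate_schedule(cfg, seed = 600 + s),
      seed = 700 + s, subject_id = sprintf("s%02d", s)
    )
  }) |> purrr::list_rbind()
  fit <- fit_hierarchical(beh, model_spec(2),
    chains = 2,
    iter_warmup = 300, iter_sampling = 300, seed = 7
  )
  sig <- colMeans(fit$group_draws[, grep("^sigma_alpha_gain", colnames(fit$group_draws)), drop = FALSE])
  # prior scale is half-normal(0.5) with mean ~0.4; identical subjects
  # must concentrate well below it
  expect_lt(unname(sig), 0.4)
})

test_that("model 3 splits hyperparameters by group symmetrically", {
  beh <- make_behavior_cohort(8, c(0.55, 0.15), alpha_sd = 0.25, seed = 8)
  co <- dplyr::distinct(beh, subject_id, group)
  fit <- fit_hierarchical(dplyr::select(beh, -group), model_spec(3),
    cohort = co, chains = 2, iter_warmup = 300, iter_sampling = 300,
    seed = 9
  )
  gd <- colnames(fit$group_draws)
  expect_true(any(grepl("mu_alpha_gain\\[HC\\]", gd)))
  expect_true(any(grepl("mu_alpha_gain\\[MDD\\]", gd)))
  mu_hc <- mean(fit$group_draws[, "mu_alpha_gain[HC]"])
  mu_md <- mean(fit$group_draws[, "mu_alpha_gain[MDD]"])
  expect_gt(mu_hc, mu_md)

  # permuting the group labels permutes the hyperparameter posteriors
  co_sw <- dplyr::mutate(co,
    group = ifelse(group == "HC", "MDD", "HC")
  )
  fit_sw <- fit_hierarchical(dplyr::select(beh, -group), model_spec(3),
    cohort = co_sw, chains = 2, iter_warmup = 300, iter_sampling = 300,
    seed = 9
  )
  expect_equal(mean(fit_sw$group_draws[, "mu_alpha_gain[MDD]"]), mu_hc,
    tolerance = 0.15
  )
  expect_equal(mean(fit_sw$group_draws[, "mu_alpha_gain[HC]"]), mu_md,
    tolerance = 0.15
  )
})

test_that("model 3 requires a cohort and rejects unknown subjects", {
  beh <- make_behavior_cohort(3, c(0.4, 0.4), seed = 10)
  expect_error(
    fit_hierarchical(dplyr::select(beh, -group), model_spec(3)),
    "cohort"
  )
})

test_that("WAIC identity and self-comparison hold exactly", {
  beh <- make_behavior_cohort(4, c(0.4, 0.4), seed = 11)
  fit <- fit_hierarchical(dplyr::select(beh, -group), model_spec(2),
    chains = 2, iter_warmup = 150, iter_sampling = 150, seed = 12
  )
  w <- compute_waic(fit)
  expect_lt(abs(w$waic - (-2 * (w$lppd - w$p_waic))), 1e-9)
  expect_gte(w$p_waic, 0)
  cmp <- compare_waic(a = fit, b = fit)
  expect_equal(cmp$delta_waic, c(0, 0))
  expect_equal(cmp$se_delta, c(0, 0))

  # mismatched trial counts across fits are an input error
  beh2 <- make_behavior_cohort(4, c(0.4, 0.4), seed = 13,
    cfg = task_config(n_trials_per_type = 10)
  )
  fit2 <- fit_hierarchical(dplyr::select(beh2, -group), model_spec(2),
    chains = 2, iter_warmup = 100, iter_sampling = 100, seed = 12
  )
  expect_error(compare_waic(fit, fit2), "different numbers of trials")
})

test_that("posterior predictive bands cover self-generated data", {
  cfg <- task_config()
  set.seed(14)
  sessions <- purrr::map(1:15, ~ generate_schedule(cfg, seed = 300 + .x))
  beh <- purrr::map2(1:15, sessions, function(s, sch) {
    p <- agent_params(
      beta = exp(rnorm(1, log(4), 0.4)),
      alpha_gain = pnorm(rnorm(1, qnorm(0.4), 0.5)),
      alpha_loss = pnorm(rnorm(1, qnorm(0.3), 0.5))
    )
    simulate_agent(p, sch, seed = 400 + s, subject_id = sprintf("s%02d", s))
  }) |> purrr::list_rbind()
  fit <- fit_hierarchical(beh, model_spec(2),
    chains = 2,
    iter_warmup = 300, iter_sampling = 300, seed = 15
  )
  ppc <- posterior_predictive(
    fit,
    tibble::tibble(
      subject_id = sprintf("s%02d", 1:15),
      session = sessions
    ),
    n_draws = 80, seed = 16
  )
  expect_gte(attr(ppc, "coverage"), 0.9)
  expect_true(all(c("observed", "predicted", "lo", "hi") %in% names(ppc)))
})

test_that("shuffled choices collapse the fit toward a random policy", {
  cfg <- task_config()
  set.seed(17)
  beh <- purrr::map(1:10, function(s) {
    p <- agent_params(beta = 5, alpha_gain = 0.5, alpha_loss = 0.3)
    b <- simulate_agent(p, generate_schedule(cfg, seed = 800 + s),
      seed = 900 + s, subject_id = sprintf("s%02d", s)
    )
    b$choice <- sample(b$choice)
    b$correct <- runif(nrow(b)) < 0.5
    b
  }) |> purrr::list_rbind()
  fit <- fit_hierarchical(beh, model_spec(2),
    chains = 2,
    iter_warmup = 300, iter_sampling = 300, seed = 18
  )
  mu_b <- mean(fit$group_draws[, "mu_beta[all]"])
  # posterior mean beta should be small (weak preference structure)
  expect_lt(exp(mu_b), 2)
  # and observed accuracy flat around 0.5
  expect_lt(abs(mean(beh$correct) - 0.5), 0.06)
})

test_that("tidy and glance expose posterior summaries", {
  beh <- make_behavior_cohort(4, c(0.4, 0.4), seed = 19)
  fit <- fit_hierarchical(dplyr::select(beh, -group), model_spec(1),
    chains = 2, iter_warmup = 150, iter_sampling = 150, seed = 20
  )
  tg <- tidy(fit, level = "group")
  expect_true(all(c("parameter", "mean", "conf.low", "conf.high", "rhat") %in%
    names(tg)))
  expect_equal(nrow(tg), 4L) # mu/sigma x alpha/beta
  ts <- tidy(fit, level = "subject")
  expect_true(all(c("term", "subject_id", "mean") %in% names(ts)))
  gl <- glance(fit)
  expect_equal(gl$model_id, 1L)
  expect_true(is.finite(gl$waic))
})
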