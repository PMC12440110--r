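# Independent oracles and small fixture builders used across the suite.
# Every oracle is a deliberately naive reimplementation, kept free of the
# package's own code paths.

# naive per-trial log-likelihood by direct replay of the update and
# softmax rules (plain R loop)
naive_loglik <- function(alpha_gain, alpha_loss, beta, trials) {
  pair <- trials$pair
  q <- matrix(0, nrow = max(pair), ncol = 2)
  ll <- numeric(nrow(trials))
  for (t in seq_len(nrow(trials))) {
    p <- pair[t]
    ez <- exp(beta * q[p, ] - max(beta * q[p, ]))
    pr <- ez / sum(ez)
    ll[t] <- log(pr[trials$choice[t]])
    a <- if (trials$trial_type[t] == "loss") alpha_loss else alpha_gain
    ch <- trials$choice[t]
    q[p, ch] <- q[p, ch] + a * (trials$outcome[t] - q[p, ch])
  }
  ll
}

# residualization-based partial correlation: regress node i out of the raw
# series for j and k, correlate the residuals
resid_partial_cor <- function(x, j, k, i) {
  rj <- residuals(lm(x[, j] ~ x[, i]))
  rk <- residuals(lm(x[, k] ~ x[, i]))
  cor(rj, rk)
}

# naive triple-loop dependency matrix with inline formulas
naive_dependency <- function(C, denom = nrow(C) - 1) {
  n <- nrow(C)
  clip <- function(r) ifelse(abs(r) > 0.99, sign(r) * 0.99, r)
  D <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j) next
      acc <- 0
      for (r in setdiff(1:n, c(i, j))) {
        pc <- (C[j, r] - C[j, i] * C[r, i]) /
          sqrt((1 - C[j, i]^2) * (1 - C[r, i]^2))
        d <- atanh(clip(C[j, r])) - atanh(clip(pc))
        acc <- acc + max(0, d)
      }
      D[j, i] <- acc / denom
    }
  }
  dimnames(D) <- dimnames(C)
  D
}

# hand BH step-up: q_(i) = min_{j >= i} m p_(j) / j
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# exhaustive rank-sum null: all group assignments of the observed midranks
enumerate_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combos <- utils::combn(length(r), n1)
  us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(w_obs - mu) - 1e-12)
}

# simulate a behavioral cohort directly from agent parameters
make_behavior_cohort <- function(n_per_group, alpha_gain_mean,
                                 alpha_loss_mean = 0.30, alpha_sd = 0.4,
                                 beta_mean = 5, beta_log_sd = 0.3,
                                 seed = 1, cfg = task_config()) {
  n <- 2L * n_per_group
  with_test_seed(seed)
  purrr::map(seq_len(n), function(s) {
    mdd <- s > n_per_group
    ag_mu <- if (mdd) alpha_gain_mean[2] else alpha_gain_mean[1]
    p <- agent_params(
      beta = exp(rnorm(1, log(beta_mean), beta_log_sd)),
      alpha_gain = pnorm(rnorm(1, qnorm(ag_mu), alpha_sd)),
      alpha_loss = pnorm(rnorm(1, qnorm(alpha_loss_mean), alpha_sd))
    )
    simulate_agent(p, generate_schedule(cfg, seed = seed + s),
      seed = seed + 600L + s, subject_id = sprintf("s%02d", s)
    ) |>
      dplyr::mutate(group = ifelse(mdd, "MDD", "HC"))
  }) |>
    purrr::list_rbind()
}

with_test_seed <- function(seed) set.seed(seed)

# small cohort covariate table for regression tests
make_cohort_table <- function(subject_ids, groups, seed = 1) {
  set.seed(seed)
  n <- length(subject_ids)
  tibble::tibble(
    subject_id = subject_ids,
    group = groups,
    age = rnorm(n, 35, 10),
    sex = sample(c("F", "M"), n, replace = TRUE),
    medicated = groups == "MDD" & runif(n) < 0.5,
    daw = rnorm(n)
  )
}
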