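#' Posterior predictive check of choice accuracy
#'
#' For a thinned subset of posterior draws, replays the full task
#' generative process with each subject's drawn parameters on their own
#' session schedule, then summarizes correct-choice rates by trial position
#' within trial type. The observed curve from the fitted data is overlaid
#' with the central posterior predictive interval of the replicated
#' curves.
#'
#' @param fit An `hbfit`.
#' @param sessions Tibble with `subject_id` and a `session` list-column of
#'   schedules (as produced by [simulate_cohort()]); every fitted subject
#'   must be present.
#' @param n_draws Number of posterior draws to replay (default 200).
#' @param prob Predictive interval mass (default 0.95).
#' @param seed Seed for the replays.
#' @return A `ppc_result` tibble: `trial_type`, `position`, `observed`,
#'   `predicted`, `lo`, `hi`, plus a `coverage` attribute (fraction of
#'   positions whose observed accuracy falls inside the band).
#' @export
posterior_predictive <- function(fit, sessions, n_draws = 200L, prob = 0.95,
                                 seed = 1L) {
  stopifnot(inherits(fit, "hbfit"))
  idx <- match(fit$subjects, sessions$subject_id)
  if (anyNA(idx)) stop("`sessions` is missing fitted subjects.", call. = FALSE)
  sess <- sessions$session[idx]
  total <- nrow(fit$subject_draws)
  keep <- unique(round(seq(1L, total, length.out = min(n_draws, total))))

  curve_of <- function(beh) {
    beh |>
      dplyr::filter(.data$trial_type != "neutral") |>
      dplyr::group_by(.data$subject_id, .data$trial_type) |>
      dplyr::mutate(position = dplyr::row_number()) |>
      dplyr::group_by(.data$trial_type, .data$position) |>
      dplyr::summarise(accuracy = mean(.data$correct), .groups = "drop")
  }

  observed <- curve_of(fit$behavior)

  rep_curves <- with_seed(seed, {
    purrr::map(keep, function(row) {
      beh <- purrr::map2(seq_along(fit$subjects), sess, function(s, sch) {
        p <- agent_params(
          beta = fit$subject_draws[row, 3 * (s - 1) + 3],
          alpha_gain = fit$subject_draws[row, 3 * (s - 1) + 1],
          alpha_loss = fit$subject_draws[row, 3 * (s - 1) + 2],
          model_id = 2L
        )
        simulate_agent(p, sch, subject_id = fit$subjects[s])
      }) |>
        purrr::list_rbind()
      curve_of(beh)$accuracy
    })
  })
  rep_mat <- do.call(rbind, rep_curves)
  lo_p <- (1 - prob) / 2
  out <- observed |>
    dplyr::rename(observed = "accuracy") |>
    dplyr::mutate(
      predicted = colMeans(rep_mat),
      lo = apply(rep_mat, 2, quantile, probs = lo_p),
      hi = apply(rep_mat, 2, quantile, probs = 1 - lo_p)
    )
  attr(out, "coverage") <- mean(out$observed >= out$lo & out$observed <= out$hi)
  class(out) <- c("ppc_result", class(out))
  out
}

#' Parameter-recovery study
#'
#' Repeatedly draws true subject-level parameters from the generative
#' hierarchy, simulates full sessions, refits the model, and scores
#' recovery: true-vs-posterior-mean correlation per parameter and the
#' fraction of truths inside the central 95% credible intervals.
#'
#' @param spec A [model_spec()] (model 2 by default).
#' @param n_subjects Subjects per replicate (default 30).
#' @param n_reps Replicates (default 20).
#' @param cfg_task A [task_config()].
#' @param cfg_pop A [population_spec()] supplying the truth-generating
#'   hierarchy (single-group: the HC entries are used for all subjects).
#'   The default spreads truths widely across the parameter supports
#'   (probit-scale SD 0.9 for the learning rates, log-scale SD 0.5 for
#'   `beta`), as a recovery study should: it probes identifiability over
#'   the support rather than one cohort's narrow range.
#' @param chains,iter_warmup,iter_sampling Sampler configuration for the
#'   refits (light defaults suited to a recovery loop).
#' @param seed Master seed.
#' @param conf_level Credible-interval mass scored for coverage.
#' @return A `recovery_report` tibble with one row per subject, replicate
#'   and parameter: `rep`, `subject_id`, `parameter`, `truth`, `estimate`,
#'   `conf.low`, `conf.high`, `inside`.
#' @export
parameter_recovery <- function(spec = model_spec(2L), n_subjects = 30L,
                               n_reps = 20L, cfg_task = task_config(),
                               cfg_pop = population_spec(
                                 alpha_gain_mean = c(HC = 0.5, MDD = 0.5),
                                 alpha_loss_mean = c(HC = 0.4, MDD = 0.4),
                                 alpha_sd = 0.9,
                                 beta_mean = 4, beta_log_sd = 0.5
                               ),
                               chains = 2L, iter_warmup = 500L,
                               iter_sampling = 500L, seed = 1L,
                               conf_level = 0.95) {
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  base_seed <- derive_seed(seed, "recovery")
  reports <- purrr::map(seq_len(n_reps), function(r) {
    rs <- (base_seed + 977L * r) %% 2147483629L
    truth <- with_seed(rs, tibble::tibble(
      subject_id = sprintf("s%02d", seq_len(n_subjects)),
      alpha_gain = pnorm(rnorm(
        n_subjects, qnorm(cfg_pop$alpha_gain_mean[["HC"]]), cfg_pop$alpha_sd
      )),
      alpha_loss = pnorm(rnorm(
        n_subjects, qnorm(cfg_pop$alpha_loss_mean[["HC"]]), cfg_pop$alpha_sd
      )),
      beta = exp(rnorm(
        n_subjects, log(cfg_pop$beta_mean), cfg_pop$beta_log_sd
      ))
    ))
    behavior <- purrr::map(seq_len(n_subjects), function(s) {
      sch <- generate_schedule(cfg_task, seed = rs + 3L * s)
      p <- if (spec$model_id == 1L) {
        agent_params(
          beta = truth$beta[s], alpha = truth$alpha_gain[s],
          model_id = 1L
        )
      } else {
        agent_params(
          beta = truth$beta[s], alpha_gain = truth$alpha_gain[s],
          alpha_loss = truth$alpha_loss[s], model_id = 2L
        )
      }
      simulate_agent(p, sch, seed = rs + 3L * s + 1L,
        subject_id = truth$subject_id[s]
      )
    }) |>
      purrr::list_rbind()
    fit <- fit_hierarchical(behavior, spec,
      chains = chains, iter_warmup = iter_warmup,
      iter_sampling = iter_sampling, seed = rs + 2L
    )
    est <- tidy(fit, level = "subject", conf_level = conf_level)
    truth_long <- truth |>
      tidyr::pivot_longer(-"subject_id",
        names_to = "term", values_to = "truth"
      )
    if (spec$model_id == 1L) {
      truth_long <- dplyr::filter(
        truth_long,
        .data$term != "alpha_loss"
      ) |>
        dplyr::mutate(term = dplyr::if_else(
          .data$term == "alpha_gain", "alpha_gain", .data$term
        ))
    }
    dplyr::inner_join(est, truth_long, by = c("term", "subject_id")) |>
      dplyr::transmute(
        rep = r,
        subject_id = .data$subject_id,
        parameter = .data$term,
        truth = .data$truth,
        estimate = .data$mean,
        conf.low = .data$conf.low,
        conf.high = .data$conf.high,
        inside = .data$truth >= .data$conf.low &
          .data$truth <= .data$conf.high
      )
  })
  out <- purrr::list_rbind(reports)
  class(out) <- c("recovery_report", class(out))
  out
}

#' Summarize a recovery report
#'
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @return Per-parameter tibble: recovery correlation, bias, 95% CI
#'   coverage, and the correlation of estimation errors between the
#'   learning-rate and inverse-temperature estimates (identifiability
#'   check, constant across rows).
#' @export
glance.recovery_report <- function(x, ...) {
  err <- x |>
    dplyr::mutate(error = .data$estimate - .data$truth) |>
    dplyr::select("rep", "subject_id", "parameter", "error") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "error")
  alpha_col <- intersect(c("alpha_gain", "alpha"), names(err))[1]
  ident <- cor(err[[alpha_col]], err$beta)
  x |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      correlation = cor(.data$truth, .data$estimate),
      bias = mean(.data$estimate - .data$truth),
      coverage = mean(.data$inside),
      .groups = "drop"
    ) |>
    dplyr::mutate(error_cor_alpha_beta = ident)
}
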