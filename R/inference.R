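#' Specify a hierarchical Q-learning model
#'
#' Model 1: one learning rate `alpha` and one inverse temperature `beta`
#' per subject, one set of group-level hyperparameters. Model 2: separate
#' gain- and loss-trial learning rates (`alpha_gain`, `alpha_loss`).
#' Model 3: the likelihood of model 2, with a separate set of group-level
#' hyperparameters (location and scale of every parameter) per clinical
#' group. Learning rates map to \[0, 1\] through the probit link of a
#' normal group-level draw; `beta` maps to (0, Inf) through `exp()`.
#'
#' @param model_id 1, 2 or 3.
#' @param prior_loc_sd SD of the Normal(0, .) prior on unconstrained
#'   group-level locations (default 1).
#' @param prior_scale_sd Scale of the half-Normal prior on group-level
#'   scales (default 0.5).
#' @return A `model_spec` list.
#' @export
model_spec <- function(model_id = 2L, prior_loc_sd = 1, prior_scale_sd = 0.5) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:3) stop("`model_id` must be 1, 2 or 3.", call. = FALSE)
  params <- if (model_id == 1L) {
    c("alpha", "beta")
  } else {
    c("alpha_gain", "alpha_loss", "beta")
  }
  structure(
    list(
      model_id = model_id, parameters = params,
      grouped = model_id == 3L,
      prior_loc_sd = prior_loc_sd, prior_scale_sd = prior_scale_sd
    ),
    class = "model_spec"
  )
}

# behavior tibble -> 0-based arrays for the compiled likelihood
behavior_arrays <- function(behavior) {
  need <- c("subject_id", "trial_type", "choice", "outcome")
  if (!all(need %in% names(behavior))) {
    stop(
      "Behavior needs columns subject_id, trial_type, choice, outcome.",
      call. = FALSE
    )
  }
  behavior <- dplyr::arrange(behavior, .data$subject_id, .data$trial)
  subjects <- unique(behavior$subject_id)
  noresp <- behavior[["no_response"]] %||% rep(FALSE, nrow(behavior))
  pair <- behavior[["pair"]] %||%
    match(behavior$trial_type, c("gain", "loss", "neutral"))
  choice <- ifelse(noresp, -1L, as.integer(behavior$choice) - 1L)
  list(
    subj = match(behavior$subject_id, subjects) - 1L,
    pair_id = as.integer(pair) - 1L,
    choice = as.integer(choice),
    ttype = match(behavior$trial_type, c("gain", "loss", "neutral")) - 1L,
    outcome = as.double(ifelse(noresp, 0, behavior$outcome)),
    subjects = subjects,
    behavior = behavior
  )
}

#' Per-trial log-likelihood of observed choices under fixed parameters
#'
#' Replays the delta rule over the observed record and returns
#' `log p(choice_t | Q_t, beta)` per trial. No-response trials contribute
#' exactly 0.
#'
#' @param params An [agent_params()].
#' @param record One subject's behavioral record (tibble with
#'   `trial_type`, `choice`, `outcome`, optionally `pair`, `no_response`).
#' @return Numeric vector, one element per trial.
#' @export
log_likelihood <- function(params, record) {
  stopifnot(inherits(params, "agent_params"))
  record$subject_id <- record[["subject_id"]] %||% "s1"
  record$trial <- record[["trial"]] %||% seq_len(nrow(record))
  if (length(unique(record$subject_id)) != 1L) {
    stop("`record` must contain a single subject.", call. = FALSE)
  }
  a <- behavior_arrays(record)
  ll <- pointwise_ll_cpp(
    a$subj, a$pair_id, a$choice, a$ttype, a$outcome, 1L,
    params$alpha_gain, params$alpha_loss, params$beta
  )
  if (anyNA(ll) || any(!is.finite(ll))) {
    stop("Non-finite log-likelihood at trial ",
      which(!is.finite(ll))[1],
      call. = FALSE
    )
  }
  ll
}

#' Fit a hierarchical Q-learning model by adaptive MCMC
#'
#' Subject-level parameters are given a non-centered hierarchy on the
#' unconstrained scale (`u = mu + sigma * z`, `z ~ N(0,1)`), with
#' Normal(0, `prior_loc_sd`) priors on locations and half-Normal
#' (`prior_scale_sd`) priors on scales. Sampling is adaptive
#' Metropolis-within-Gibbs: componentwise random-walk updates of subject
#' and group parameters with proposal scales tuned during warmup only.
#' Draws are deterministic given `seed`.
#'
#' @param behavior Long behavioral tibble across subjects (one row per
#'   trial; columns `subject_id`, `trial`, `trial_type`, `choice`,
#'   `outcome`, optionally `pair`, `no_response`).
#' @param spec A [model_spec()] (or model id 1-3).
#' @param cohort Cohort tibble with `subject_id` and `group`; required for
#'   model 3.
#' @param chains,iter_warmup,iter_sampling MCMC configuration
#'   (defaults 4, 1000, 1000).
#' @param seed Integer seed.
#' @param divergence_cap Maximum tolerated fraction of stuck group-level
#'   updates before a convergence warning (diagnostics are always
#'   reported).
#' @return An `hbfit` object with posterior draws (group level and
#'   natural-scale subject level), the pointwise log-likelihood matrix
#'   (draws x trials) and split-R-hat / effective-sample-size diagnostics.
#' @export
fit_hierarchical <- function(behavior, spec = model_spec(2L), cohort = NULL,
                             chains = 4L, iter_warmup = 1000L,
                             iter_sampling = 1000L, seed = 1L,
                             divergence_cap = 0.02) {
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  a <- behavior_arrays(behavior)
  n_subj <- length(a$subjects)
  if (n_subj < 2L) stop("Need at least 2 subjects.", call. = FALSE)

  if (spec$grouped) {
    if (is.null(cohort) || !all(c("subject_id", "group") %in% names(cohort))) {
      stop("Model 3 needs a `cohort` with subject_id and group.",
        call. = FALSE
      )
    }
    grp_lab <- cohort$group[match(a$subjects, cohort$subject_id)]
    if (anyNA(grp_lab)) stop("Cohort is missing subjects.", call. = FALSE)
    groups <- sort(unique(grp_lab))
    group <- match(grp_lab, groups) - 1L
  } else {
    groups <- "all"
    group <- rep(0L, n_subj)
  }

  res <- mcmc_qlearn_cpp(
    a$subj, a$pair_id, a$choice, a$ttype, a$outcome, n_subj,
    group, length(groups), spec$model_id,
    as.integer(chains), as.integer(iter_warmup), as.integer(iter_sampling),
    as.integer(seed), spec$prior_loc_sd, spec$prior_scale_sd
  )

  P <- if (spec$model_id == 1L) 2L else 3L
  unames <- if (spec$model_id == 1L) {
    c("alpha", "beta")
  } else {
    c("alpha_gain", "alpha_loss", "beta")
  }
  gp <- expand.grid(param = unames, group = groups,
    stringsAsFactors = FALSE
  )
  colnames(res$group_draws) <- c(
    paste0("mu_", gp$param, "[", gp$group, "]"),
    paste0("sigma_", gp$param, "[", gp$group, "]")
  )
  sp <- expand.grid(
    param = c("alpha_gain", "alpha_loss", "beta"),
    subject = a$subjects, stringsAsFactors = FALSE
  )
  colnames(res$subject_draws) <- paste0(sp$param, "[", sp$subject, "]")

  diag_tbl <- mcmc_diagnostics(res$group_draws, res$chain, chains,
    iter_sampling
  )
  fit <- structure(
    list(
      spec = spec,
      group_draws = res$group_draws,
      subject_draws = res$subject_draws,
      log_lik = res$log_lik,
      chain = res$chain,
      subjects = a$subjects,
      groups = groups,
      group_of_subject = setNames(groups[group + 1L], a$subjects),
      diagnostics = diag_tbl,
      accept = list(
        subject = res$accept_subject,
        group = res$accept_group
      ),
      behavior = a$behavior,
      config = list(
        chains = chains, iter_warmup = iter_warmup,
        iter_sampling = iter_sampling, seed = seed
      )
    ),
    class = "hbfit"
  )
  stuck <- mean(res$accept_group < divergence_cap)
  if (stuck > 0) {
    warning("Some chains had near-zero group-level acceptance; ",
      "inspect diagnostics before use.",
      call. = FALSE
    )
  }
  fit
}

# Split-R-hat and a Geyer initial-positive-sequence effective sample size,
# computed per column of a draws matrix.
mcmc_diagnostics <- function(draws, chain, n_chains, n_iter) {
  split_chains <- function(x) {
    # x: iterations x chains -> split each chain in half
    n <- nrow(x)
    h <- floor(n / 2)
    cbind(x[seq_len(h), , drop = FALSE],
      x[(n - h + 1):n, , drop = FALSE]
    )
  }
  per_param <- function(v) {
    m <- matrix(v, nrow = n_iter, ncol = n_chains)
    m <- split_chains(m)
    n <- nrow(m)
    cm <- colMeans(m)
    B <- n * var(cm)
    W <- mean(apply(m, 2, var))
    rhat <- if (W <= 0) 1 else sqrt(((n - 1) / n * W + B / n) / W)
    # ESS via averaged autocorrelation, initial positive sequence
    rho_sum <- 0
    max_lag <- min(n - 2L, 200L)
    prev <- 1
    for (lag in seq_len(max_lag)) {
      rho <- mean(apply(m, 2, function(x) {
        x1 <- x[1:(n - lag)] - mean(x)
        x2 <- x[(lag + 1):n] - mean(x)
        sum(x1 * x2) / ((n - 1) * var(x))
      }))
      if (!is.finite(rho) || rho < 0.01) break
      rho_sum <- rho_sum + rho
      prev <- rho
    }
    ess <- length(v) / (1 + 2 * rho_sum)
    c(rhat = rhat, ess = ess)
  }
  out <- t(apply(draws, 2, per_param))
  tibble::tibble(
    parameter = colnames(draws),
    rhat = out[, "rhat"],
    ess = out[, "ess"]
  )
}

#' @export
print.hbfit <- function(x, ...) {
  cat("<hbfit> model ", x$spec$model_id, ": ", length(x$subjects),
    " subjects, ", nrow(x$group_draws), " draws (",
    x$config$chains, " chains x ", x$config$iter_sampling, ")\n",
    sep = ""
  )
  cat(
    "max split-Rhat: ", round(max(x$diagnostics$rhat), 3),
    "; min ESS: ", round(min(x$diagnostics$ess)), "\n",
    sep = ""
  )
  invisible(x)
}

#' Posterior summaries of a hierarchical fit
#'
#' @param x An `hbfit`.
#' @param level `"group"` for group-level hyperparameters (reported on
#'   both the unconstrained and, for locations, the natural scale) or
#'   `"subject"` for natural-scale subject parameters.
#' @param conf_level Credible-interval mass (default 0.95, central).
#' @param ... Unused.
#' @return A tibble with posterior mean, median, credible bounds and
#'   diagnostics (group level).
#' @export
tidy.hbfit <- function(x, level = c("subject", "group"), conf_level = 0.95,
                       ...) {
  level <- match.arg(level)
  draws <- if (level == "group") x$group_draws else x$subject_draws
  lo <- (1 - conf_level) / 2
  out <- tibble::tibble(
    parameter = colnames(draws),
    mean = colMeans(draws),
    median = apply(draws, 2, median),
    conf.low = apply(draws, 2, quantile, probs = lo),
    conf.high = apply(draws, 2, quantile, probs = 1 - lo)
  )
  if (level == "group") {
    out <- dplyr::left_join(out, x$diagnostics, by = "parameter")
  } else {
    out <- out |>
      tidyr::separate_wider_regex(
        "parameter",
        patterns = c(term = "[^\\[]+", "\\[", subject_id = "[^\\]]+", "\\]")
      )
  }
  out
}

#' @export
glance.hbfit <- function(x, ...) {
  w <- compute_waic(x)
  tibble::tibble(
    model_id = x$spec$model_id,
    n_subjects = length(x$subjects),
    n_draws = nrow(x$group_draws),
    waic = w$waic, p_waic = w$p_waic, lppd = w$lppd,
    max_rhat = max(x$diagnostics$rhat),
    min_ess = min(x$diagnostics$ess)
  )
}

# Posterior-mean subject parameters as agent_params-compatible tibble.
subject_posterior_means <- function(fit) {
  tidy(fit, level = "subject") |>
    dplyr::select("term", "subject_id", "mean") |>
    tidyr::pivot_wider(names_from = "term", values_from = "mean")
}
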