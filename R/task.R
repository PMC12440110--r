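#' Configure the two-armed probabilistic bandit task
#'
#' The task interleaves three trial types -- gain, loss and neutral -- each
#' with its own fixed pair of stimuli. On every trial one stimulus of the
#' pair is the high-probability ("good") arm: on gain trials it pays
#' `gain_value` with probability `p_good` (the other arm with `p_bad`); on
#' loss trials it *avoids* `loss_value` with probability `p_good`; neutral
#' trials always return `neutral_value`. The default 80/20 contingency with
#' 30 trials per type (90 total) mirrors the standard bi-valent
#' probabilistic-selection design.
#'
#' @param n_trials_per_type Trials of each type (default 30).
#' @param p_good,p_bad Probability that the good / bad arm yields its
#'   favorable outcome. Must satisfy `0 <= p_bad < p_good <= 1`.
#' @param gain_value,loss_value,neutral_value Outcome magnitudes
#'   (defaults +1, -1, 0).
#' @param seed Optional integer seed used by [generate_schedule()].
#' @return A `task_config` list.
#' @export
task_config <- function(n_trials_per_type = 30L,
                        p_good = 0.8, p_bad = 0.2,
                        gain_value = 1, loss_value = -1, neutral_value = 0,
                        seed = NULL) {
  if (!is.numeric(n_trials_per_type) || n_trials_per_type < 1) {
    stop("`n_trials_per_type` must be >= 1.", call. = FALSE)
  }
  assert_scalar_prob(p_good, "p_good")
  assert_scalar_prob(p_bad, "p_bad")
  if (!(p_bad < p_good)) {
    stop("Task contingency requires p_bad < p_good.", call. = FALSE)
  }
  structure(
    list(
      n_trials_per_type = as.integer(n_trials_per_type),
      trial_types = c("gain", "loss", "neutral"),
      p_good = p_good, p_bad = p_bad,
      gain_value = gain_value, loss_value = loss_value,
      neutral_value = neutral_value,
      seed = seed
    ),
    class = "task_config"
  )
}

#' Draw task outcomes from an arm's contingency
#'
#' Vectorized lottery draw used both when pre-drawing session outcomes and
#' for empirically checking the programmed contingencies. The favorable
#' outcome (gain on gain trials, loss *avoidance* on loss trials) occurs
#' with probability `p_good` for the good arm and `p_bad` otherwise.
#'
#' @param arm_is_good Logical vector: is the sampled arm the
#'   high-probability arm?
#' @param trial_type Character vector in `c("gain", "loss", "neutral")`,
#'   recycled against `arm_is_good`.
#' @param cfg A [task_config()].
#' @param seed Optional seed.
#' @return Numeric vector of outcomes.
#' @export
sample_outcome <- function(arm_is_good, trial_type, cfg = task_config(),
                           seed = NULL) {
  stopifnot(inherits(cfg, "task_config"))
  n <- max(length(arm_is_good), length(trial_type))
  arm_is_good <- rep_len(as.logical(arm_is_good), n)
  trial_type <- rep_len(as.character(trial_type), n)
  if (!all(trial_type %in% cfg$trial_types)) {
    stop("Unknown trial type.", call. = FALSE)
  }
  with_seed(seed, {
    p_fav <- ifelse(arm_is_good, cfg$p_good, cfg$p_bad)
    fav <- runif(n) < p_fav
    out <- numeric(n)
    g <- trial_type == "gain"
    l <- trial_type == "loss"
    out[g] <- ifelse(fav[g], cfg$gain_value, 0)
    out[l] <- ifelse(fav[l], 0, cfg$loss_value)
    out[trial_type == "neutral"] <- cfg$neutral_value
    out
  })
}

#' Generate an intermixed trial schedule
#'
#' Produces the full session: a seeded permutation of exactly
#' `n_trials_per_type` trials of each type, one fixed stimulus pair per
#' type, a randomly assigned good arm per pair, and pre-drawn outcome
#' lotteries for both arms on every trial.
#'
#' @param cfg A [task_config()].
#' @param seed Seed for the permutation, arm assignment and lotteries;
#'   defaults to `cfg$seed`.
#' @return A tibble with one row per trial: `trial`, `trial_type`, `pair`,
#'   `good_arm`, `outcome_arm1`, `outcome_arm2`.
#' @export
generate_schedule <- function(cfg = task_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "task_config"))
  n <- cfg$n_trials_per_type
  with_seed(seed, {
    types <- sample(rep(cfg$trial_types, each = n))
    pair <- match(types, cfg$trial_types)
    good_arm <- sample(1:2, 3L, replace = TRUE)[pair]
    out1 <- sample_outcome(good_arm == 1L, types, cfg)
    out2 <- sample_outcome(good_arm == 2L, types, cfg)
    tibble::tibble(
      trial = seq_len(3L * n),
      trial_type = types,
      pair = pair,
      good_arm = good_arm,
      outcome_arm1 = out1,
      outcome_arm2 = out2
    )
  })
}

#' Q-learning agent parameters
#'
#' Model 1 carries a single learning rate `alpha`; models 2 and 3 split it
#' into `alpha_gain` (gain and neutral trials) and `alpha_loss` (loss
#' trials). `beta` is the softmax inverse temperature. Model 3 shares the
#' likelihood of model 2 and differs only in its group-level hierarchy.
#'
#' @param beta Inverse temperature, > 0.
#' @param alpha Learning rate in \[0, 1\] (model 1).
#' @param alpha_gain,alpha_loss Valence-specific learning rates in
#'   \[0, 1\] (models 2-3).
#' @param model_id 1, 2 or 3.
#' @return An `agent_params` list with elements `alpha_gain`, `alpha_loss`
#'   (equal for model 1), `beta`, `model_id`.
#' @export
agent_params <- function(beta, alpha = NULL, alpha_gain = NULL,
                         alpha_loss = NULL, model_id = if (is.null(alpha)) 2L else 1L) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop("`beta` must be a single value > 0.", call. = FALSE)
  }
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:3) stop("`model_id` must be 1, 2 or 3.", call. = FALSE)
  chk <- function(a, nm) {
    if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a < 0 || a > 1) {
      stop("`", nm, "` must be a learning rate in [0, 1].", call. = FALSE)
    }
    a
  }
  if (model_id == 1L) {
    a <- chk(alpha, "alpha")
    ag <- al <- a
  } else {
    ag <- chk(alpha_gain, "alpha_gain")
    al <- chk(alpha_loss, "alpha_loss")
  }
  structure(
    list(alpha_gain = ag, alpha_loss = al, beta = beta, model_id = model_id),
    class = "agent_params"
  )
}

#' Softmax choice probabilities
#'
#' `p_a = exp(beta * q_a) / sum_a' exp(beta * q_a')`, evaluated with a
#' max-subtraction guard so arbitrarily large `beta * q` cannot overflow.
#'
#' @param q Numeric vector of action values (one entry per arm).
#' @param beta Inverse temperature, > 0.
#' @return Probability vector summing to 1.
#' @export
choice_prob <- function(q, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop("`beta` must be a single value > 0.", call. = FALSE)
  }
  if (!is.numeric(q) || any(!is.finite(q))) {
    stop("`q` must be finite.", call. = FALSE)
  }
  z <- beta * q
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Delta-rule value update
#'
#' `q_new = q_prev + alpha * (reward - q_prev)`; the update has its fixed
#' point at `q_prev = reward`.
#'
#' @param q_prev Previous value.
#' @param alpha Learning rate in \[0, 1\].
#' @param reward Observed outcome.
#' @return Updated value.
#' @export
q_update <- function(q_prev, alpha, reward) {
  if (!is.numeric(alpha) || any(alpha < 0 | alpha > 1)) {
    stop("`alpha` must lie in [0, 1].", call. = FALSE)
  }
  q_prev + alpha * (reward - q_prev)
}

# Learning rate applied on a given trial type. Neutral trials use the gain
# learning rate in models 2-3; with zero-valued outcomes and zero
# initialization this contributes no updates under defaults.
alpha_for_type <- function(params, trial_type) {
  ifelse(trial_type == "loss", params$alpha_loss, params$alpha_gain)
}

#' Simulate a Q-learning agent on a task session
#'
#' Sequentially plays the session: softmax choice between the current
#' Q-values of the trial's stimulus pair, outcome read from the pre-drawn
#' lottery of the chosen arm, delta-rule update of the chosen arm only with
#' the valence-appropriate learning rate. Q-values start at zero for every
#' stimulus.
#'
#' @param params An [agent_params()].
#' @param session A schedule from [generate_schedule()].
#' @param seed Optional seed for the choice draws.
#' @param subject_id Identifier stored in the output.
#' @return A behavioral-record tibble: `subject_id`, `trial`, `trial_type`,
#'   `pair`, `choice`, `correct`, `outcome`, `q_chosen` (pre-update value of
#'   the chosen arm), `rpe`, `no_response`.
#' @export
simulate_agent <- function(params, session, seed = NULL, subject_id = "s1") {
  stopifnot(inherits(params, "agent_params"))
  n <- nrow(session)
  with_seed(seed, {
    q <- matrix(0, nrow = max(session$pair), ncol = 2L)
    choice <- integer(n)
    q_chosen <- rpe <- outcome <- numeric(n)
    for (t in seq_len(n)) {
      p <- session$pair[t]
      pr <- choice_prob(q[p, ], params$beta)
      ch <- if (runif(1) < pr[1L]) 1L else 2L
      choice[t] <- ch
      out <- if (ch == 1L) session$outcome_arm1[t] else session$outcome_arm2[t]
      outcome[t] <- out
      q_chosen[t] <- q[p, ch]
      rpe[t] <- out - q[p, ch]
      a <- alpha_for_type(params, session$trial_type[t])
      q[p, ch] <- q_update(q[p, ch], a, out)
    }
    tibble::tibble(
      subject_id = subject_id,
      trial = session$trial,
      trial_type = session$trial_type,
      pair = session$pair,
      choice = choice,
      correct = choice == session$good_arm,
      outcome = outcome,
      q_chosen = q_chosen,
      rpe = rpe,
      no_response = FALSE
    )
  })
}

#' Replay observed choices to recover Q-values and prediction errors
#'
#' Deterministically replays the delta rule over an observed
#' choice/outcome sequence, yielding the trial-by-trial reward prediction
#' errors used as parametric regressors ("full RPE" across all trials;
#' gain-/loss-trial subsets are recovered by filtering on `trial_type`).
#' The first encounter of any stimulus has `rpe == outcome` because values
#' start at zero. No-response trials (flagged in `no_response`) neither
#' update values nor receive an RPE.
#'
#' @param params An [agent_params()].
#' @param trials Tibble with columns `trial_type`, `choice` (1/2),
#'   `outcome`, optionally `pair` (defaults to one pair per trial type) and
#'   `no_response`.
#' @return The input with `q_chosen` and `rpe` columns replaced/added.
#' @export
compute_rpe_trace <- function(params, trials) {
  stopifnot(inherits(params, "agent_params"))
  need <- c("trial_type", "choice", "outcome")
  if (!all(need %in% names(trials))) {
    stop("`trials` must have columns trial_type, choice, outcome.",
      call. = FALSE
    )
  }
  if (anyNA(trials$outcome[!(trials[["no_response"]] %||% FALSE)])) {
    stop("Outcomes must be observed on response trials.", call. = FALSE)
  }
  pair <- trials[["pair"]] %||%
    match(trials$trial_type, c("gain", "loss", "neutral"))
  if (length(pair) != nrow(trials) || length(trials$choice) != nrow(trials)) {
    stop("Choice/outcome columns must align with the session.", call. = FALSE)
  }
  noresp <- trials[["no_response"]] %||% rep(FALSE, nrow(trials))
  n <- nrow(trials)
  q <- matrix(0, nrow = max(pair), ncol = 2L)
  q_chosen <- rpe <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    if (noresp[t]) next
    p <- pair[t]
    ch <- trials$choice[t]
    q_chosen[t] <- q[p, ch]
    rpe[t] <- trials$outcome[t] - q[p, ch]
    a <- alpha_for_type(params, trials$trial_type[t])
    q[p, ch] <- q_update(q[p, ch], a, trials$outcome[t])
  }
  out <- trials
  out$q_chosen <- q_chosen
  out$rpe <- rpe
  tibble::as_tibble(out)
}

#' Behavioral compliance filter
#'
#' Flags subjects for exclusion when performance indicates task
#' non-compliance: correct-choice rate below 50% on gain **and** loss
#' trials (set `rule = "or"` for the stricter either-type reading), or a
#' session with no responses at all.
#'
#' @param records Behavioral records for one or more subjects (long tibble
#'   with `subject_id`, `trial_type`, `correct`, optionally `no_response`).
#' @param rule `"and"` (default) or `"or"`: combine the per-valence <50%
#'   criteria conjunctively or disjunctively.
#' @param threshold Correct-rate threshold (default 0.5).
#' @return Tibble: `subject_id`, `gain_correct`, `loss_correct`,
#'   `all_no_response`, `included`.
#' @export
compliance_filter <- function(records, rule = c("and", "or"), threshold = 0.5) {
  rule <- match.arg(rule)
  if (nrow(records) == 0L) stop("`records` is empty.", call. = FALSE)
  if (!"no_response" %in% names(records)) records$no_response <- FALSE
  records |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      gain_correct = mean(.data$correct[.data$trial_type == "gain" &
        !.data$no_response]),
      loss_correct = mean(.data$correct[.data$trial_type == "loss" &
        !.data$no_response]),
      all_no_response = all(.data$no_response),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      included = !.data$all_no_response &
        !(if (rule == "and") {
          (.data$gain_correct < threshold | is.nan(.data$gain_correct)) &
            (.data$loss_correct < threshold | is.nan(.data$loss_correct))
        } else {
          (.data$gain_correct < threshold | is.nan(.data$gain_correct)) |
            (.data$loss_correct < threshold | is.nan(.data$loss_correct))
        })
    )
}
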