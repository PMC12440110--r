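#' Configure the hub-network time-series simulator
#'
#' Subject-level multivariate "ROI" series follow a structural first-order
#' vector autoregression `x_t = A0 x_t + A1 x_{t-1} + e_t`,
#' `e_t ~ N(0, noise_sd^2 I)`: every node has an AR(1) self-decay (`A1 =
#' self_decay * I`) and the directed hub couplings act contemporaneously
#' (`A0` carries `hub_out_coupling` on hub-to-target entries and
#' `hub_in_coupling` on target-to-hub entries). The reduced form
#' `x_t = (I - A0)^{-1} (A1 x_{t-1} + e_t)` is an ordinary VAR(1) with
#' correlated innovations. Contemporaneous coupling is what makes the
#' hub's directed influence visible to zero-lag correlation methods:
#' sampled at hemodynamic timescales, an influence confined to the
#' previous timestep leaves the hub *less* correlated with its targets
#' than the targets are with each other, and no correlation-based method
#' could rank the hub first. Subjects in the second ("MDD-like") group
#' receive `group_coupling_delta` added to their outgoing hub coupling.
#' The default node set is the VTA plus its seven mesocorticolimbic
#' targets.
#'
#' @param n_nodes Number of nodes (>= 3).
#' @param node_names Node labels, length `n_nodes`.
#' @param n_timepoints Series length per subject.
#' @param hub_index Index of the hub node (default 1 = VTA).
#' @param hub_out_coupling,hub_in_coupling VAR weights hub->target and
#'   target->hub.
#' @param self_decay Diagonal AR(1) weight.
#' @param noise_sd Innovation standard deviation, > 0.
#' @param group_coupling_delta Additive hub-out coupling shift for the
#'   MDD-like group.
#' @param seed Optional integer seed.
#' @return A `netsim_config` list.
#' @export
netsim_config <- function(n_nodes = 8L,
                          node_names = c(
                            "VTA", "vmPFC", "dmPFC", "sgACC",
                            "plACC", "NAc", "BLA", "hippocampus"
                          ),
                          n_timepoints = 300L,
                          hub_index = 1L,
                          hub_out_coupling = 0.4,
                          hub_in_coupling = 0.05,
                          self_decay = 0.3,
                          noise_sd = 1,
                          group_coupling_delta = 0.1,
                          seed = NULL) {
  if (n_nodes < 3L) stop("`n_nodes` must be >= 3.", call. = FALSE)
  if (length(node_names) != n_nodes) {
    node_names <- paste0("node", seq_len(n_nodes))
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("`noise_sd` must be > 0.", call. = FALSE)
  }
  if (hub_index < 1L || hub_index > n_nodes) {
    stop("`hub_index` out of range.", call. = FALSE)
  }
  cfg <- structure(
    list(
      n_nodes = as.integer(n_nodes), node_names = node_names,
      n_timepoints = as.integer(n_timepoints),
      hub_index = as.integer(hub_index),
      hub_out_coupling = hub_out_coupling,
      hub_in_coupling = hub_in_coupling,
      self_decay = self_decay, noise_sd = noise_sd,
      group_coupling_delta = group_coupling_delta,
      seed = seed
    ),
    class = "netsim_config"
  )
  # fail fast on non-stationary defaults for either group
  var_transition(cfg, mdd = FALSE)
  var_transition(cfg, mdd = TRUE)
  cfg
}

# Build one subject's structural matrices and the reduced-form VAR(1)
# transition; enforce invertibility of (I - A0) and stationarity
# (spectral radius of the reduced-form transition strictly < 1).
var_transition <- function(cfg, mdd = FALSE, extra_out = 0) {
  n <- cfg$n_nodes
  h <- cfg$hub_index
  out_w <- cfg$hub_out_coupling + if (mdd) cfg$group_coupling_delta else 0
  out_w <- out_w + extra_out
  A0 <- matrix(0, n, n)
  A0[-h, h] <- out_w
  A0[h, -h] <- cfg$hub_in_coupling
  IA <- diag(n) - A0
  if (abs(det(IA)) < 1e-8) {
    stop("Degenerate contemporaneous coupling: (I - A0) is singular.",
      call. = FALSE
    )
  }
  M <- solve(IA)
  Ar <- M %*% diag(cfg$self_decay, n)
  rho <- max(Mod(eigen(Ar, only.values = TRUE)$values))
  if (rho >= 1) {
    stop(
      "Non-stationary VAR transition (spectral radius ", round(rho, 3),
      " >= 1); reduce the couplings or self-decay.",
      call. = FALSE
    )
  }
  list(transition = Ar, innovation_mix = M)
}

#' Simulate a panel of subject time series
#'
#' One `n_timepoints x n_nodes` matrix per subject, drawn from the VAR(1)
#' in [netsim_config()] after a discarded burn-in. Deterministic given
#' `seed`.
#'
#' @param cfg A [netsim_config()].
#' @param group_labels Character vector, one label (`"HC"`/`"MDD"`) per
#'   subject; `"MDD"` subjects get the group coupling shift.
#' @param subject_ids Optional ids (default `sub01`, ...).
#' @param extra_out_coupling Optional numeric vector, per-subject additive
#'   shift to the hub-out coupling (used to plant covariate associations).
#' @param seed Seed; defaults to `cfg$seed`.
#' @param burn_in Discarded initial steps (default 100).
#' @return A nested tibble: `subject_id`, `group`, `series` (list-column of
#'   timepoint-by-node matrices with node-name columns).
#' @export
simulate_timeseries_panel <- function(cfg, group_labels,
                                      subject_ids = NULL,
                                      extra_out_coupling = NULL,
                                      seed = cfg$seed, burn_in = 100L) {
  stopifnot(inherits(cfg, "netsim_config"))
  n_sub <- length(group_labels)
  if (n_sub < 1L) stop("Need at least one subject.", call. = FALSE)
  subject_ids <- subject_ids %||% sprintf("sub%02d", seq_len(n_sub))
  extra_out_coupling <- extra_out_coupling %||% rep(0, n_sub)
  stopifnot(length(extra_out_coupling) == n_sub)
  with_seed(seed, {
    series <- purrr::map(seq_len(n_sub), function(s) {
      vt <- var_transition(cfg,
        mdd = group_labels[s] == "MDD",
        extra_out = extra_out_coupling[s]
      )
      tt <- cfg$n_timepoints + burn_in
      x <- matrix(0, nrow = tt, ncol = cfg$n_nodes)
      # reduced form: x_t = M (A1 x_{t-1} + e_t), innovations mixed by M
      eps <- matrix(rnorm(tt * cfg$n_nodes, sd = cfg$noise_sd),
        nrow = tt
      ) %*% t(vt$innovation_mix)
      x[1L, ] <- eps[1L, ]
      for (t in 2:tt) x[t, ] <- vt$transition %*% x[t - 1L, ] + eps[t, ]
      x <- x[(burn_in + 1L):tt, , drop = FALSE]
      colnames(x) <- cfg$node_names
      x
    })
    tibble::tibble(
      subject_id = subject_ids,
      group = group_labels,
      series = series
    )
  })
}

#' Population-level generative parameters for a synthetic cohort
#'
#' Subject Q-learning parameters are drawn per clinical group from the same
#' hierarchy the group-split model assumes: probit-scale normals for the
#' learning rates (`alpha = pnorm(z)`), a log-scale normal for `beta`. The
#' default gain-learning means (HC 0.35, MDD 0.20 on the probability scale)
#' plant the reward-learning deficit; loss learning and outcome sensitivity
#' are matched across groups.
#'
#' @param alpha_gain_mean Named probability-scale means, `c(HC=, MDD=)`.
#' @param alpha_loss_mean Same for loss learning.
#' @param alpha_sd Probit-scale SD of both learning rates.
#' @param beta_mean Mean inverse temperature (natural scale).
#' @param beta_log_sd Log-scale SD of `beta`.
#' @param planted List of linear ground-truth effects used by
#'   [simulate_cohort()]: `estradiol_to_coupling` and `teps_to_coupling`
#'   scale standardized covariates into additive hub-out coupling shifts
#'   (defaults 0 = no association).
#' @return A `population_spec` list.
#' @export
population_spec <- function(alpha_gain_mean = c(HC = 0.35, MDD = 0.20),
                            alpha_loss_mean = c(HC = 0.30, MDD = 0.30),
                            alpha_sd = 0.4,
                            beta_mean = 5,
                            beta_log_sd = 0.3,
                            planted = list(
                              estradiol_to_coupling = 0,
                              teps_to_coupling = 0
                            )) {
  chk <- function(m, nm) {
    if (any(m <= 0) || any(m >= 1)) {
      stop("`", nm, "` must lie strictly inside (0, 1).", call. = FALSE)
    }
  }
  chk(alpha_gain_mean, "alpha_gain_mean")
  chk(alpha_loss_mean, "alpha_loss_mean")
  if (beta_mean <= 0) stop("`beta_mean` must be > 0.", call. = FALSE)
  structure(
    list(
      alpha_gain_mean = alpha_gain_mean,
      alpha_loss_mean = alpha_loss_mean,
      alpha_sd = alpha_sd,
      beta_mean = beta_mean,
      beta_log_sd = beta_log_sd,
      planted = utils::modifyList(
        list(estradiol_to_coupling = 0, teps_to_coupling = 0),
        planted %||% list()
      )
    ),
    class = "population_spec"
  )
}

# Draw the covariate table. Covariates are mutually independent except for
# planted group shifts; score ranges follow the instruments' usual scales.
draw_covariates <- function(n_hc, n_mdd) {
  n <- n_hc + n_mdd
  group <- c(rep("HC", n_hc), rep("MDD", n_mdd))
  mdd <- group == "MDD"
  tibble::tibble(
    subject_id = sprintf("sub%02d", seq_len(n)),
    group = group,
    age = round(pmin(pmax(rnorm(n, 35, 12), 18), 65), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    medicated = mdd & runif(n) < 0.5,
    daw = rnorm(n),
    teps_a = round(pmin(pmax(rnorm(n, ifelse(mdd, 35, 45), 6), 10), 60), 1),
    teps_c = round(pmin(pmax(rnorm(n, ifelse(mdd, 33, 42), 6), 8), 48), 1),
    madrs = round(pmin(pmax(
      ifelse(mdd, rnorm(n, 25, 6), runif(n, 0, 8)), 0
    ), 50), 1),
    sticsa = round(pmin(pmax(rnorm(n, ifelse(mdd, 45, 30), 8), 21), 84), 1),
    estradiol = round(rlnorm(n, meanlog = 3.5, sdlog = 0.8), 1),
    testosterone = round(rlnorm(n, meanlog = 4.5, sdlog = 0.9), 1)
  )
}

#' Simulate a full synthetic cohort
#'
#' Generates, with one seed, everything the downstream pipeline consumes:
#' a covariate table, per-subject network time series with a directed hub
#' and planted group/covariate effects on the hub coupling, per-subject
#' bandit behavior from Q-learning agents whose parameters are drawn from
#' group-level distributions, and the ground truth needed to score
#' recovery.
#'
#' @param cfg_net A [netsim_config()].
#' @param cfg_task A [task_config()].
#' @param cfg_pop A [population_spec()].
#' @param n_hc,n_mdd Subjects per group (defaults 34 and 35).
#' @param seed Master seed for the cohort.
#' @return A `synthetic_cohort` list: `cohort` (tibble), `panel` (nested
#'   tibble from [simulate_timeseries_panel()]), `behavior` (one row per
#'   trial across subjects), `sessions` (nested schedule per subject),
#'   `ground_truth` (list: per-subject true parameters and planted
#'   coefficients).
#' @export
simulate_cohort <- function(cfg_net = netsim_config(),
                            cfg_task = task_config(),
                            cfg_pop = population_spec(),
                            n_hc = 34L, n_mdd = 35L, seed = 1L) {
  stopifnot(
    inherits(cfg_net, "netsim_config"),
    inherits(cfg_task, "task_config"),
    inherits(cfg_pop, "population_spec")
  )
  if (n_hc < 1L || n_mdd < 1L) {
    stop("Each group needs at least one subject.", call. = FALSE)
  }
  with_seed(seed, {
    cohort <- draw_covariates(n_hc, n_mdd)
    n <- nrow(cohort)

    # true agent parameters from the group hierarchy
    mu_g <- qnorm(cfg_pop$alpha_gain_mean[cohort$group])
    mu_l <- qnorm(cfg_pop$alpha_loss_mean[cohort$group])
    truth <- tibble::tibble(
      subject_id = cohort$subject_id,
      group = cohort$group,
      alpha_gain = pnorm(rnorm(n, mu_g, cfg_pop$alpha_sd)),
      alpha_loss = pnorm(rnorm(n, mu_l, cfg_pop$alpha_sd)),
      beta = exp(rnorm(n, log(cfg_pop$beta_mean), cfg_pop$beta_log_sd))
    )

    # planted covariate -> coupling shifts (standardized covariates)
    pl <- cfg_pop$planted
    extra <- pl$estradiol_to_coupling * as.numeric(scale(cohort$estradiol)) +
      pl$teps_to_coupling * as.numeric(scale(cohort$teps_a))

    panel <- simulate_timeseries_panel(
      cfg_net, cohort$group,
      subject_ids = cohort$subject_id,
      extra_out_coupling = extra,
      seed = derive_seed(seed, "simulate_network")
    )

    beh_seed <- derive_seed(seed, "simulate_behavior")
    sessions <- purrr::map(seq_len(n), function(s) {
      generate_schedule(cfg_task, seed = beh_seed + 2L * s)
    })
    behavior <- purrr::map2(seq_len(n), sessions, function(s, sess) {
      p <- agent_params(
        beta = truth$beta[s],
        alpha_gain = truth$alpha_gain[s],
        alpha_loss = truth$alpha_loss[s],
        model_id = 2L
      )
      simulate_agent(p, sess,
        seed = beh_seed + 2L * s + 1L,
        subject_id = cohort$subject_id[s]
      )
    }) |>
      purrr::list_rbind()

    structure(
      list(
        cohort = cohort,
        panel = panel,
        behavior = behavior,
        sessions = tibble::tibble(
          subject_id = cohort$subject_id,
          session = sessions
        ),
        ground_truth = list(
          agent_params = truth,
          planted = c(
            list(group_coupling_delta = cfg_net$group_coupling_delta),
            pl
          ),
          seed = seed
        )
      ),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(
    "<synthetic_cohort> ", nrow(x$cohort), " subjects (",
    sum(x$cohort$group == "HC"), " HC, ", sum(x$cohort$group == "MDD"),
    " MDD); ", nrow(x$panel$series[[1]]), " timepoints x ",
    ncol(x$panel$series[[1]]), " nodes; ",
    nrow(x$behavior) / nrow(x$cohort), " trials/subject\n",
    sep = ""
  )
  invisible(x)
}

#' Write / read a synthetic cohort as plain-text files
#'
#' Layout: `cohort.csv`, `behavior.csv` (one row per trial),
#' `ground_truth.json`, and `timeseries/<subject_id>.tsv` (rows =
#' timepoints, columns = node labels). Ground truth round-trips losslessly.
#'
#' @param x A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_cohort"))
  dir.create(file.path(dir, "timeseries"),
    recursive = TRUE,
    showWarnings = FALSE
  )
  readr::write_csv(x$cohort, file.path(dir, "cohort.csv"))
  readr::write_csv(x$behavior, file.path(dir, "behavior.csv"))
  jsonlite::write_json(
    list(
      agent_params = x$ground_truth$agent_params,
      planted = x$ground_truth$planted,
      seed = x$ground_truth$seed
    ),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  purrr::walk2(x$panel$subject_id, x$panel$series, function(id, m) {
    readr::write_tsv(
      tibble::as_tibble(m),
      file.path(dir, "timeseries", paste0(id, ".tsv"))
    )
  })
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  cohort <- readr::read_csv(file.path(dir, "cohort.csv"),
    show_col_types = FALSE
  )
  behavior <- readr::read_csv(file.path(dir, "behavior.csv"),
    show_col_types = FALSE
  )
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
    simplifyVector = TRUE
  )
  gt$agent_params <- tibble::as_tibble(gt$agent_params)
  series <- purrr::map(cohort$subject_id, function(id) {
    as.matrix(readr::read_tsv(
      file.path(dir, "timeseries", paste0(id, ".tsv")),
      show_col_types = FALSE
    ))
  })
  structure(
    list(
      cohort = cohort, behavior = behavior,
      panel = tibble::tibble(
        subject_id = cohort$subject_id,
        group = cohort$group, series = series
      ),
      sessions = NULL,
      ground_truth = gt
    ),
    class = "synthetic_cohort"
  )
}
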