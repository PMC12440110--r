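#' Widely Applicable Information Criterion
#'
#' Computed from the pointwise log-likelihood matrix (draws x trials):
#' `lppd = sum_t log mean_s exp(ll_st)` (evaluated stably),
#' `p_waic = sum_t var_s(ll_st)`, and `waic = -2 (lppd - p_waic)` on the
#' deviance scale. Trials are the exchangeable likelihood units, so the
#' pointwise terms are per trial. No-response trials carry zero
#' log-likelihood in every draw and contribute nothing.
#'
#' @param fit An `hbfit`, or a draws-by-trials log-likelihood matrix.
#' @return A `waic_result` list: `lppd`, `p_waic`, `waic`, `pointwise`
#'   tibble (per-trial elpd contributions), `n_draws`, `n_points`.
#' @export
compute_waic <- function(fit) {
  ll <- if (inherits(fit, "hbfit")) fit$log_lik else as.matrix(fit)
  s <- nrow(ll)
  # stable log-mean-exp per column
  mx <- apply(ll, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2, mx)))) # log mean exp
  p_i <- apply(ll, 2, var)
  elpd_i <- lppd_i - p_i
  structure(
    list(
      lppd = sum(lppd_i),
      p_waic = sum(p_i),
      waic = -2 * (sum(lppd_i) - sum(p_i)),
      pointwise = tibble::tibble(
        lppd = lppd_i, p_waic = p_i, elpd = elpd_i
      ),
      n_draws = s,
      n_points = ncol(ll)
    ),
    class = "waic_result"
  )
}

#' @export
print.waic_result <- function(x, ...) {
  cat("WAIC ", round(x$waic, 2), " (lppd ", round(x$lppd, 2),
    ", p_waic ", round(x$p_waic, 2), "; ", x$n_points, " points, ",
    x$n_draws, " draws)\n",
    sep = ""
  )
  invisible(x)
}

#' Compare fitted models by WAIC
#'
#' Ranks models by WAIC (lower is better) and reports each model's WAIC
#' difference from the best model with the standard error of that
#' difference (`sqrt(n) * sd` of the pointwise elpd differences; both fits
#' must share the same trials).
#'
#' @param ... Named `hbfit` objects or `waic_result`s (or a single list of
#'   them).
#' @return A `waic_comparison` tibble: `model`, `waic`, `p_waic`, `lppd`,
#'   `delta_waic`, `se_delta`.
#' @export
compare_waic <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) &&
    !inherits(fits[[1]], c("hbfit", "waic_result"))) {
    fits <- fits[[1]]
  }
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  ws <- purrr::map(fits, function(f) {
    if (inherits(f, "waic_result")) f else compute_waic(f)
  })
  np <- purrr::map_int(ws, "n_points")
  if (length(unique(np)) != 1L) {
    stop("Models were fitted to different numbers of trials; ",
      "WAIC differences are undefined.",
      call. = FALSE
    )
  }
  waics <- unname(purrr::map_dbl(ws, "waic"))
  best <- which.min(waics)
  out <- tibble::tibble(
    model = names(fits),
    waic = waics,
    p_waic = unname(purrr::map_dbl(ws, "p_waic")),
    lppd = unname(purrr::map_dbl(ws, "lppd")),
    delta_waic = waics - waics[best],
    se_delta = unname(purrr::map_dbl(ws, function(w) {
      d <- w$pointwise$elpd - ws[[best]]$pointwise$elpd
      if (all(abs(d) < 1e-12)) 0 else 2 * sqrt(length(d) * var(d))
    }))
  )
  out <- dplyr::arrange(out, .data$waic)
  class(out) <- c("waic_comparison", class(out))
  out
}

#' @export
tidy.waic_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
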