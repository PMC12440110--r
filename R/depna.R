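#' Pearson correlation matrix of a subject's node time series
#'
#' @param x Numeric matrix (or data frame), rows = timepoints, columns =
#'   labeled nodes; at least 3 timepoints and no constant series.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("Need at least 3 timepoints.", call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0] %||% which(sds == 0)
    stop("Constant time series for node(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  cor(x)
}

# Fisher z with the clipping policy reused everywhere: correlations at (or
# numerically beyond) |r| = 1 are replaced by sign(r) * 0.99 before atanh,
# mirroring the diagonal 0.99 rule, so the transform stays finite.
fisher_z <- function(r, clip = 0.99) {
  r <- ifelse(abs(r) > clip, sign(r) * clip, r)
  atanh(r)
}

#' Partial correlation of two nodes controlling a third
#'
#' `PC(j, k | i) = (C_jk - C_ji * C_ki) / sqrt((1 - C_ji^2)(1 - C_ki^2))`,
#' the correlation between nodes `j` and `k` after removing the linear
#' influence of node `i`.
#'
#' @param C Correlation matrix.
#' @param j,k,i Distinct node indices or names.
#' @return Scalar partial correlation.
#' @export
partial_correlation <- function(C, j, k, i) {
  if (length(unique(list(j, k, i))) != 3L) {
    stop("`j`, `k`, `i` must be distinct.", call. = FALSE)
  }
  den <- (1 - C[j, i]^2) * (1 - C[k, i]^2)
  if (den <= .Machine$double.eps) {
    stop("Degenerate partial correlation: node ", i,
      " is collinear with ", j, " or ", k, ".",
      call. = FALSE
    )
  }
  (C[j, k] - C[j, i] * C[k, i]) / sqrt(den)
}

#' Correlation influence of one node on a pair's connection
#'
#' The influence of node `i` on the `j`-`k` connection is the drop from the
#' full to the partial correlation, Fisher-z transformed before
#' differencing, and clamped at zero (negative influences are set to 0):
#' `d(j, k | i) = max(0, z(C_jk) - z(PC(j, k | i)))`.
#'
#' @inheritParams partial_correlation
#' @param fisher Apply the Fisher-z transform before differencing
#'   (default TRUE); `FALSE` gives the raw-difference variant.
#' @return Scalar influence, >= 0.
#' @export
correlation_influence <- function(C, j, k, i, fisher = TRUE) {
  pc <- partial_correlation(C, j, k, i)
  d <- if (fisher) {
    fisher_z(C[j, k]) - fisher_z(pc)
  } else {
    C[j, k] - pc
  }
  max(0, d)
}

#' Node-by-node dependency matrix
#'
#' `D[j, i]` is the average correlation influence of node `i` on node `j`'s
#' connections: the mean of `d(j, R | i)` over every other node `R` (the
#' degenerate self pair `R = j` is excluded from the sum while the
#' `1/(n-1)` normalization is retained; set
#' `normalization = "n_minus_2"` to average over the terms actually
#' summed). The diagonal is zero by construction. Before any Fisher-z
#' step the unit diagonal is treated as 0.99 so the transform is finite;
#' reported correlations keep their unit diagonal.
#'
#' @param C Correlation matrix for >= 3 nodes.
#' @param fisher Passed to [correlation_influence()].
#' @param normalization `"n_minus_1"` (default, as printed) or
#'   `"n_minus_2"` (mean over included terms). Group contrasts are
#'   invariant to this constant.
#' @return `n x n` matrix of average correlation influences.
#' @export
dependency_matrix <- function(C, fisher = TRUE,
                              normalization = c("n_minus_1", "n_minus_2")) {
  normalization <- match.arg(normalization)
  n <- nrow(C)
  if (n < 3L) stop("Need at least 3 nodes.", call. = FALSE)
  denom <- if (normalization == "n_minus_1") n - 1 else n - 2
  D <- matrix(0, n, n, dimnames = dimnames(C))
  zC <- fisher_z(C)
  for (i in seq_len(n)) {
    ci <- C[, i]
    v <- 1 - ci^2
    if (any(v[-i] <= .Machine$double.eps)) {
      bad <- setdiff(which(v <= .Machine$double.eps), i)[1]
      stop("Degenerate partial correlation: node ", i,
        " is collinear with node ", bad, ".",
        call. = FALSE
      )
    }
    # all pairwise partial correlations given node i at once
    pc <- (C - outer(ci, ci)) / sqrt(outer(v, v))
    dm <- if (fisher) zC - fisher_z(pc) else C - pc
    dm[!is.na(dm) & dm < 0] <- 0 # negative influences clamped
    dm[, i] <- 0 # conditioning node is never a pair member
    dm[i, ] <- 0 # D[i, i] is undefined; row i cleared of NaNs
    diag(dm) <- 0 # degenerate self pair R = j excluded
    D[, i] <- rowSums(dm) / denom
    D[i, i] <- 0
  }
  D
}

#' Influencing and influenced degrees
#'
#' From a dependency matrix `D` (with `D[j, i]` the influence of `i` on
#' `j`): `influencing(i) = sum_{N != i} D[N, i]` (total influence a node
#' exerts) and `influenced(i) = sum_{N != i} D[i, N]` (total influence it
#' receives). Both sums equal the grand off-diagonal total of `D`, so the
#' two degree vectors always share the same sum.
#'
#' @param D Dependency matrix from [dependency_matrix()].
#' @return Tibble: `node`, `influencing`, `influenced`.
#' @export
influence_degrees <- function(D) {
  nodes <- colnames(D) %||% paste0("node", seq_len(ncol(D)))
  diag(D) <- 0
  tibble::tibble(
    node = nodes,
    influencing = unname(colSums(D)),
    influenced = unname(rowSums(D))
  )
}

#' Run DEPNA over a panel of subjects
#'
#' Computes, per subject, the correlation matrix, dependency matrix and
#' node degrees.
#'
#' @param panel Nested tibble from [simulate_timeseries_panel()] (columns
#'   `subject_id`, `series`), or any tibble with those columns.
#' @inheritParams dependency_matrix
#' @return A list: `degrees` (long tibble `subject_id`, `node`,
#'   `influencing`, `influenced`) and `dependency` (long tibble
#'   `subject_id`, `source`, `target`, `influence` with `influence` =
#'   `D[target, source]`).
#' @export
depna <- function(panel, fisher = TRUE,
                  normalization = c("n_minus_1", "n_minus_2")) {
  normalization <- match.arg(normalization)
  per_sub <- purrr::map2(panel$subject_id, panel$series, function(id, m) {
    D <- dependency_matrix(correlation_matrix(m),
      fisher = fisher, normalization = normalization
    )
    nodes <- colnames(D)
    list(
      degrees = dplyr::mutate(influence_degrees(D), subject_id = id),
      # D[target, source]; as.vector(t(D)) runs source fastest
      dependency = tibble::tibble(
        subject_id = id,
        source = rep(nodes, times = length(nodes)),
        target = rep(nodes, each = length(nodes)),
        influence = as.vector(t(D))
      ) |>
        dplyr::filter(.data$source != .data$target)
    )
  })
  list(
    degrees = purrr::list_rbind(purrr::map(per_sub, "degrees")) |>
      dplyr::select("subject_id", dplyr::everything()),
    dependency = purrr::list_rbind(purrr::map(per_sub, "dependency"))
  )
}

#' Standard-deviation outlier mask
#'
#' Inclusion mask computed once on the full sample (non-iterative):
#' values more than `k` standard deviations from the mean are excluded.
#' Zero-variance input keeps everything.
#'
#' @param values Numeric vector (>= 3 values).
#' @param k SD multiplier (default 3).
#' @return Logical inclusion mask.
#' @export
exclude_outliers <- function(values, k = 3) {
  if (length(values) < 3L) stop("Need at least 3 values.", call. = FALSE)
  s <- sd(values)
  if (s == 0) return(rep(TRUE, length(values)))
  abs(values - mean(values)) <= k * s
}

# Shared covariate-adjusted OLS engine. Returns the predictor row of the
# coefficient table plus bookkeeping.
adjusted_ols <- function(df, response, predictor, covariates,
                         analysis = response) {
  keep <- complete.cases(df[, c(response, predictor, covariates)])
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) stop("No complete cases.", call. = FALSE)
  fm <- stats::reformulate(c(predictor, covariates), response = response)
  fit <- lm(fm, data = df)
  if (any(is.na(coef(fit)))) {
    stop("Rank-deficient design; collinear columns: ",
      paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
      call. = FALSE
    )
  }
  ct <- summary(fit)$coefficients
  row <- grep(paste0("^", predictor), rownames(ct))[1]
  tibble::tibble(
    analysis = analysis,
    predictor = predictor,
    estimate = ct[row, 1],
    statistic = ct[row, 3],
    p_value = ct[row, 4],
    n = nrow(df),
    covariates = paste(covariates, collapse = ",")
  )
}

#' Covariate-adjusted regression of influence degrees
#'
#' OLS of a per-subject degree (influencing or influenced) on a predictor
#' of interest plus nuisance covariates; the single-node analysis carries
#' no multiple-comparison correction. Subjects flagged by
#' [exclude_outliers()] can be removed beforehand via `outlier_k`.
#'
#' @param degrees Long degrees tibble from [depna()].
#' @param cohort Cohort tibble keyed by `subject_id`.
#' @param predictor Column of `cohort` to test (e.g. `"group"`).
#' @param covariates Character vector of nuisance columns
#'   (default `c("age", "sex", "medicated", "daw")`).
#' @param node Node whose degrees are analyzed (default `"VTA"`).
#' @param direction `"influencing"` or `"influenced"`.
#' @param outlier_k SD multiplier for pre-analysis exclusion
#'   (default 3; `Inf` disables it).
#' @return One-row association tibble: `analysis`, `predictor`,
#'   `estimate`, `statistic`, `p_value`, `n`, `covariates`.
#' @export
influence_regression <- function(degrees, cohort, predictor,
                                 covariates = c("age", "sex", "medicated", "daw"),
                                 node = "VTA",
                                 direction = c("influencing", "influenced"),
                                 outlier_k = 3) {
  direction <- match.arg(direction)
  if (!predictor %in% names(cohort)) {
    stop("`predictor` not found in the cohort.", call. = FALSE)
  }
  vals <- degrees |>
    dplyr::filter(.data$node == !!node) |>
    dplyr::select("subject_id", value = dplyr::all_of(direction))
  if (nrow(vals) == 0L) stop("Node not found in `degrees`.", call. = FALSE)
  if (is.finite(outlier_k)) {
    vals <- vals[exclude_outliers(vals$value, k = outlier_k), ]
  }
  df <- dplyr::inner_join(vals, cohort, by = "subject_id")
  adjusted_ols(df, "value", predictor, covariates,
    analysis = paste0(direction, "(", node, ")~", predictor)
  )
}

#' Directed influence graph around the hub
#'
#' For every hub-target pair, in both directions (hub influences target:
#' `D[target, hub]`; target influences hub: `D[hub, target]`), regresses
#' the per-subject average correlation influence on the predictor with
#' covariate adjustment. Edges are retained at uncorrected p < `alpha`;
#' Benjamini-Hochberg q-values over the full tested family are always
#' attached.
#'
#' @param dependency Long dependency tibble from [depna()].
#' @param cohort Cohort tibble.
#' @inheritParams influence_regression
#' @param hub Hub node label (default `"VTA"`).
#' @param alpha Uncorrected edge threshold (default 0.05).
#' @return An `influence_graph`: tibble `from`, `to`, `estimate`,
#'   `statistic`, `p_value`, `q_fdr`, `edge` (logical), with the node set
#'   in `attr(, "nodes")`.
#' @export
edge_graph <- function(dependency, cohort, predictor,
                       covariates = c("age", "sex", "medicated", "daw"),
                       hub = "VTA", alpha = 0.05) {
  if (nrow(cohort) == 0L) stop("`cohort` is empty.", call. = FALSE)
  nodes <- unique(c(dependency$source, dependency$target))
  if (!hub %in% nodes) stop("Hub not present in the dependency table.",
    call. = FALSE
  )
  pairs <- dependency |>
    dplyr::filter(.data$source == hub | .data$target == hub) |>
    dplyr::distinct(.data$source, .data$target)
  res <- purrr::pmap(pairs, function(source, target) {
    df <- dependency |>
      dplyr::filter(.data$source == !!source, .data$target == !!target) |>
      dplyr::inner_join(cohort, by = "subject_id")
    out <- adjusted_ols(df, "influence", predictor, covariates,
      analysis = paste0(source, "->", target)
    )
    dplyr::mutate(out, from = source, to = target, .before = 1)
  }) |>
    purrr::list_rbind()
  res$q_fdr <- bh_fdr(res$p_value)
  res$edge <- res$p_value < alpha
  out <- dplyr::select(
    res, "from", "to", "estimate", "statistic",
    "p_value", "q_fdr", "edge", "n"
  )
  attr(out, "nodes") <- nodes
  attr(out, "predictor") <- predictor
  class(out) <- c("influence_graph", class(out))
  out
}

#' Export an influence graph
#'
#' Writes the edge list as CSV and, via igraph, as GraphML. Only rows with
#' `edge == TRUE` become graph edges; FDR annotation travels as edge
#' attributes.
#'
#' @param graph An `influence_graph`.
#' @param csv,graphml Output paths (either may be `NULL` to skip).
#' @return Invisibly, the igraph object.
#' @export
write_influence_graph <- function(graph, csv = NULL, graphml = NULL) {
  stopifnot(inherits(graph, "influence_graph"))
  if (!is.null(csv)) readr::write_csv(tibble::as_tibble(graph), csv)
  edges <- dplyr::filter(tibble::as_tibble(graph), .data$edge)
  g <- igraph::graph_from_data_frame(
    edges,
    directed = TRUE,
    vertices = data.frame(name = attr(graph, "nodes"))
  )
  if (!is.null(graphml)) {
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(g)
}
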