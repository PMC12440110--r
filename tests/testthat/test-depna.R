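test_that("correlation matrices match the textbook computation", {
  set.seed(1)
  x <- matrix(rnorm(60 * 5), 60, 5)
  colnames(x) <- paste0("n", 1:5)
  C <- correlation_matrix(x)
  # two-pass oracle
  xc <- sweep(x, 2, colMeans(x))
  oracle <- crossprod(xc) / outer(
    sqrt(colSums(xc^2)), sqrt(colSums(xc^2))
  )
  expect_lt(max(abs(C - oracle)), 1e-12)
  expect_equal(diag(C), setNames(rep(1, 5), colnames(x)))
})

test_that("degenerate series are rejected by name", {
  x <- cbind(a = rnorm(20), b = rep(1, 20), c = rnorm(20))
  expect_error(correlation_matrix(x), "b")
  expect_error(correlation_matrix(x[1:2, ]), "3 timepoints")
})

test_that("independent white noise yields near-zero off-diagonals", {
  set.seed(2)
  x <- matrix(rnorm(5000 * 4), 5000, 4)
  C <- correlation_matrix(x)
  expect_true(all(abs(C[upper.tri(C)]) < 0.05))
})

test_that("partial correlation follows the closed form and symmetry", {
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- 0.8
  C[1, 3] <- C[3, 1] <- 0.6
  C[2, 3] <- C[3, 2] <- 0.6
  expect_equal(partial_correlation(C, 1, 2, 3), 0.6875)
  expect_equal(
    partial_correlation(C, 1, 2, 3),
    partial_correlation(C, 2, 1, 3)
  )
  # uncorrelated third node leaves the correlation untouched
  C0 <- diag(3)
  C0[1, 2] <- C0[2, 1] <- 0.5
  expect_equal(partial_correlation(C0, 1, 2, 3), 0.5)
  expect_error(partial_correlation(C, 1, 2, 2), "distinct")
})

test_that("matrix partial correlation equals raw-series residualization", {
  set.seed(3)
  n <- 400
  z <- rnorm(n)
  x <- cbind(
    a = 0.7 * z + rnorm(n),
    b = 0.5 * z + rnorm(n),
    c = z
  )
  C <- correlation_matrix(x)
  expect_equal(
    partial_correlation(C, "a", "b", "c"),
    resid_partial_cor(x, "a", "b", "c"),
    tolerance = 1e-10
  )
})

test_that("correlation influence is the clamped Fisher-z drop", {
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- 0.8
  C[1, 3] <- C[3, 1] <- 0.6
  C[2, 3] <- C[3, 2] <- 0.6
  # hand evaluation: atanh(.8) - atanh(.6875)
  expect_equal(correlation_influence(C, 1, 2, 3),
    atanh(0.8) - atanh(0.6875),
    tolerance = 1e-12
  )
  expect_equal(correlation_influence(C, 1, 2, 3), 0.25541,
    tolerance = 1e-4
  )
  # uncorrelated third node: exact zero after clamping
  C0 <- diag(3)
  C0[1, 2] <- C0[2, 1] <- 0.5
  expect_equal(correlation_influence(C0, 1, 2, 3), 0)
  # suppression (PC > C) clamps to exactly zero
  Cs <- diag(3)
  Cs[1, 2] <- Cs[2, 1] <- 0.1
  Cs[1, 3] <- Cs[3, 1] <- 0.7
  Cs[2, 3] <- Cs[3, 2] <- -0.7
  expect_identical(correlation_influence(Cs, 1, 2, 3), 0)
})

test_that("dependency matrix equals the naive triple loop on random SPD input", {
  set.seed(4)
  for (rep in 1:5) {
    x <- matrix(rnorm(120 * 8), 120, 8) %*% matrix(rnorm(64, sd = .4), 8, 8)
    x <- x + matrix(rnorm(120 * 8), 120, 8)
    colnames(x) <- paste0("n", 1:8)
    C <- correlation_matrix(x)
    D <- dependency_matrix(C)
    expect_lt(max(abs(D - naive_dependency(C))), 1e-12)
    expect_true(all(D >= 0))
    expect_true(all(diag(D) == 0))
  }
})

test_that("three-node dependency reduces to the single valid term", {
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- 0.8
  C[1, 3] <- C[3, 1] <- 0.6
  C[2, 3] <- C[3, 2] <- 0.6
  D <- dependency_matrix(C)
  expect_equal(D[1, 3], correlation_influence(C, 1, 2, 3) / 2)
  Dm <- dependency_matrix(C, normalization = "n_minus_2")
  expect_equal(Dm[1, 3], correlation_influence(C, 1, 2, 3))
})

test_that("a node independent of a pair exerts no influence on it", {
  set.seed(5)
  z <- rnorm(1500)
  x <- cbind(
    a = z + 0.5 * rnorm(1500),
    b = z + 0.5 * rnorm(1500),
    c = rnorm(1500)
  )
  D <- dependency_matrix(correlation_matrix(x))
  expect_lt(D["a", "c"], 0.02)
})

test_that("degrees follow the row/column orientation and conserve totals", {
  D <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  D[2, 1] <- 0.4 # node 1 influences node 2
  D[3, 1] <- 0.2
  D[1, 2] <- 0.1
  deg <- influence_degrees(D)
  expect_equal(deg$influencing[deg$node == "a"], 0.6)
  expect_equal(deg$influenced[deg$node == "a"], 0.1)
  expect_equal(sum(deg$influencing), sum(deg$influenced))
  expect_true(all(influence_degrees(matrix(0, 3, 3))$influencing == 0))
})

test_that("relabeling nodes permutes dependency output identically", {
  set.seed(6)
  x <- matrix(rnorm(200 * 5), 200, 5)
  colnames(x) <- paste0("n", 1:5)
  D <- dependency_matrix(correlation_matrix(x))
  perm <- c(3, 1, 5, 2, 4)
  xp <- x[, perm]
  Dp <- dependency_matrix(correlation_matrix(xp))
  expect_equal(Dp, D[perm, perm], tolerance = 1e-12)
})

test_that("outlier exclusion is non-iterative full-sample z-scoring", {
  expect_true(all(exclude_outliers(c(0, 0, 0, 100)))) # |z| ~ 1.5 at n = 4
  expect_true(all(exclude_outliers(rep(2, 5))))
  # constructed vectors with one and two genuine outliers
  set.seed(7)
  v1 <- c(rnorm(40), 30)
  expect_equal(sum(!exclude_outliers(v1)), 1L)
  v2 <- c(rnorm(40), 30, -28)
  expect_equal(sum(!exclude_outliers(v2)), 2L)
  expect_error(exclude_outliers(c(1, 2)), "3 values")
})

test_that("influence regression reduces to the simple slope and validates", {
  set.seed(8)
  ids <- sprintf("s%02d", 1:40)
  deg <- tibble::tibble(
    subject_id = ids, node = "VTA",
    influencing = rnorm(40), influenced = rnorm(40)
  )
  x <- rnorm(40)
  co <- tibble::tibble(subject_id = ids, score = x)
  res <- influence_regression(deg, co, "score",
    covariates = character(0), outlier_k = Inf
  )
  expect_equal(res$estimate,
    unname(coef(lm(deg$influencing ~ x))[2]),
    tolerance = 1e-12
  )
  # collinear covariate triggers a named rank-deficiency error
  co2 <- dplyr::mutate(co, score2 = score)
  expect_error(
    influence_regression(deg, co2, "score",
      covariates = "score2", outlier_k = Inf
    ),
    "collinear"
  )
  expect_error(
    influence_regression(deg, co, "missing_col", character(0)),
    "not found"
  )
})

test_that("null influence regressions are calibrated", {
  set.seed(9)
  ps <- replicate(200, {
    deg <- tibble::tibble(
      subject_id = sprintf("s%02d", 1:30), node = "VTA",
      influencing = rnorm(30), influenced = rnorm(30)
    )
    co <- tibble::tibble(
      subject_id = deg$subject_id, score = rnorm(30)
    )
    influence_regression(deg, co, "score",
      covariates = character(0), outlier_k = Inf
    )$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("edge graphs recover a planted hub-target dependence", {
  set.seed(10)
  n <- 60
  ids <- sprintf("s%02d", 1:n)
  score <- rnorm(n)
  nodes <- c("VTA", "NAc", "BLA", "vmPFC")
  dep <- tidyr::expand_grid(
    subject_id = ids,
    source = nodes, target = nodes
  ) |>
    dplyr::filter(source != target) |>
    dplyr::mutate(influence = abs(rnorm(dplyr::n(), sd = 0.05)))
  # plant: VTA -> NAc influence increases with the score
  idx <- dep$source == "VTA" & dep$target == "NAc"
  dep$influence[idx] <- dep$influence[idx] + 0.3 * score[match(
    dep$subject_id[idx], ids
  )]
  co <- tibble::tibble(subject_id = ids, score = score)
  g <- edge_graph(dep, co, "score", covariates = character(0))
  tab <- tibble::as_tibble(g)
  planted <- tab[tab$from == "VTA" & tab$to == "NAc", ]
  expect_true(planted$edge)
  expect_equal(which.min(tab$p_value), which(tab$from == "VTA" &
    tab$to == "NAc"))
  expect_true(all(tab$q_fdr >= tab$p_value - 1e-12))
  expect_error(edge_graph(dep, co[0, ], "score"), "empty")
})

test_that("influence graphs serialize to edge-list CSV and GraphML", {
  set.seed(11)
  ids <- sprintf("s%02d", 1:30)
  nodes <- c("VTA", "NAc", "BLA")
  dep <- tidyr::expand_grid(subject_id = ids, source = nodes, target = nodes) |>
    dplyr::filter(source != target) |>
    dplyr::mutate(influence = abs(rnorm(dplyr::n(), 0.2, 0.05)))
  co <- tibble::tibble(subject_id = ids, score = rnorm(30))
  g <- edge_graph(dep, co, "score", covariates = character(0))
  csv <- withr::local_tempfile(fileext = ".csv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  ig <- write_influence_graph(g, csv = csv, graphml = gml)
  expect_true(file.exists(csv) && file.exists(gml))
  expect_s3_class(ig, "igraph")
  expect_equal(igraph::vcount(ig), 3)
})
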