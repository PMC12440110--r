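# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL.", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Named per-stage seed derivation: stage streams never collide and adding a
# stage never perturbs earlier ones. Keeps results under 2^31 - 1.
derive_seed <- function(master_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  offsets <- c(
    simulate_network = 11L, simulate_behavior = 23L, simulate_cohort = 37L,
    fit = 101L, ppc = 211L, recovery = 307L, waic = 401L,
    depna = 503L, associate = 601L, report = 701L, acceptance = 811L
  )
  if (!stage %in% names(offsets)) {
    stop("Unknown pipeline stage: ", stage, call. = FALSE)
  }
  s <- (as.double(master_seed) * 7919 + as.double(offsets[[stage]])) %%
    2147483629
  as.integer(s)
}

assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a single probability in [0, 1].", call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
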