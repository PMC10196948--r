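# Small shared fixtures, generated once per test run and memoized.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_control = 3L, n_ltle = 3L, n_rtle = 2L,
         t = 60L, a = 48L, b = 200L, seed = 11L,
         batch_assignment = rep(c("protocol1", "protocol2"), each = 4L)),
    list(...))
  do.call(simulation_config, args)
}

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

tiny_cohort <- function() {
  memo("tiny_cohort", suppressWarnings(generate_cohort(tiny_config())))
}

tiny_stack <- function() {
  memo("tiny_stack", {
    coh <- tiny_cohort()
    gs <- cohort_gradients(coh, n_components = 6L)
    align_cohort(gs, covariates = coh$covariates, k = 6L)
  })
}

# a small, connected, strictly positive affinity for embedding tests
random_affinity <- function(a = 30L, seed = 5L, kernel = "gaussian") {
  set.seed(seed)
  x <- matrix(rnorm(a * 8L), a, 8L)
  compute_affinity(structure(x, class = c("connectivity_fingerprint",
                                          "matrix", "array")),
                   kernel = kernel)
}
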