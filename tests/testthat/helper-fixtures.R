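# Shared fixtures: small designs, ground truths, and minimal fit stubs
# (hand-built posterior draws) used where a full MCMC run is unnecessary.

one_cell_design <- function(n_trials = 20, gaps = seq(0, 1.6, by = 0.2)) {
  crowding_design(
    tibble::tibble(subject = "S1", optical = "AO", stroke = 0.5),
    gaps = gaps, n_trials = n_trials)
}

ref_params <- function() {
  crowding_params(A = 0.95, mu = 0.5, sigma = 0.2, m = -0.4, b = 0.8)
}

# A single-cell crowding_fit with given draws (columns A, b, sigma, mu, m),
# bypassing MCMC; enough structure for cs_interval / spacing_summary.
make_fit_stub <- function(draws, subject = "S1", optical = "AO",
                          stroke = 0.5, gamma = 0.25) {
  stopifnot(all(c("A", "b", "sigma", "mu", "m") %in% colnames(draws)))
  d <- as.matrix(draws[, c("A", "b", "sigma", "mu", "m")])
  structure(list(
    draws = d, chain = rep(1L, nrow(d)), gamma = gamma,
    cells = tibble::tibble(subject = subject, optical = optical,
                           stroke = stroke),
    slot_of = list(A = 1L, b = 2L, sigma = 3L, mu = 4L, m = 5L),
    spec = model_spec("N", "N", "N"),
    diagnostics = list(rhat = rep(1, 5), converged = TRUE)
  ), class = "crowding_fit")
}

# Draws matrix with every row equal to the given parameter set.
constant_draws <- function(params, n = 100) {
  matrix(rep(c(params$A, params$b, params$sigma, params$mu, params$m),
             each = n),
         nrow = n, dimnames = list(NULL, c("A", "b", "sigma", "mu", "m")))
}

expect_tables_equal_files <- function(path1, path2) {
  expect_identical(readLines(path1), readLines(path2))
}
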