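test_that("the model lattice has the twelve conventional members", {
  fam <- enumerate_models()
  expect_length(fam, 12)
  codes <- vapply(fam, function(m) paste0(m$sigma, m$mu, m$m), character(1))
  expect_equal(length(unique(codes)), 12)
  expect_equal(unname(codes["5"]), "OOF")
  expect_equal(unname(codes["6"]), "OOO")
  expect_equal(unname(codes["0"]), "FFF")
  expect_equal(unname(codes["11"]), "NNN")
  expect_equal(unname(codes["1"]), "FOF")
  expect_equal(vapply(fam, `[[`, integer(1), "id"), setNames(0:11, names(fam)))
})

test_that("constraint codes map cells to the right slot counts", {
  cells <- expand.grid(subject = c("S1", "S2", "S3"),
                       optical = c("AO", "noAO"),
                       stroke = c(0.4, 0.5, 0.6, 0.7),
                       stringsAsFactors = FALSE)
  cells <- tibble::as_tibble(cells)
  pi_o <- parameter_index(model_spec("O", "F", "N"), cells)
  expect_equal(pi_o$sigma$n_slots, 3)  # one per observer
  expect_equal(pi_o$mu$n_slots, 1)     # fully shared
  expect_equal(pi_o$m$n_slots, 24)     # saturated
  expect_equal(pi_o$A$n_slots, 24)     # A and b always per cell
  expect_equal(pi_o$b$n_slots, 24)
  pi_c <- parameter_index(model_spec("C", "C", "C"), cells)
  expect_equal(pi_c$sigma$n_slots, 6)  # observer x optical
  # cells sharing a subject share the O-coded slot
  idx <- pi_o$sigma$index
  expect_equal(length(unique(idx[cells$subject == "S1"])), 1)
  # N-coded slots are all distinct
  expect_equal(length(unique(pi_o$m$index)), 24)
  # total free parameters of the fully yoked model on 24 cells
  expect_equal(n_parameters(model_spec("F", "F", "F"), cells), 3 + 2 * 24)
})

test_that("WAIC matches a naive double-loop oracle on a small fixture", {
  set.seed(8)
  ll <- matrix(log(runif(50, 0.05, 0.95)), nrow = 10, ncol = 5)
  naive <- local({
    lppd <- 0; pw <- 0
    for (i in 1:5) {
      s <- 0
      for (d in 1:10) s <- s + exp(ll[d, i])
      lppd <- lppd + log(s / 10)
      pw <- pw + var(ll[, i])
    }
    list(waic = -2 * (lppd - pw), p_waic = pw, lppd = lppd)
  })
  w <- waic(ll)
  expect_equal(w$waic, naive$waic, tolerance = 1e-10)
  expect_equal(w$p_waic, naive$p_waic, tolerance = 1e-10)
  expect_equal(w$lppd, naive$lppd, tolerance = 1e-10)
  # hand-worked 2 points x 2 draws
  h <- matrix(c(log(0.5), log(0.25), log(0.8), log(0.4)), nrow = 2)
  wh <- waic(h)
  expect_equal(wh$lppd, log(0.375) + log(0.6), tolerance = 1e-12)
  expect_equal(wh$p_waic, var(h[, 1]) + var(h[, 2]), tolerance = 1e-12)
})

test_that("WAIC degenerate and additivity properties hold", {
  ll <- matrix(rep(c(-0.5, -1.2, -0.3), each = 4), nrow = 4)
  w <- waic(ll)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * w$lppd)
  set.seed(10)
  ll2 <- matrix(log(runif(40)), nrow = 8)
  dup <- waic(cbind(ll2, ll2))
  one <- waic(ll2)
  expect_equal(dup$lppd, 2 * one$lppd, tolerance = 1e-12)
  expect_equal(dup$p_waic, 2 * one$p_waic, tolerance = 1e-12)
  # weighted points equal explicit duplication
  wtd <- waic(ll2, weights = rep(2, ncol(ll2)))
  expect_equal(wtd$waic, dup$waic, tolerance = 1e-12)
  expect_error(waic(ll[1, , drop = FALSE]), "2 posterior draws")
  # pWAIC >= 0 and WAIC >= -2 lppd on random matrices
  for (i in 1:5) {
    m <- matrix(log(runif(60)), nrow = 6)
    wi <- waic(m)
    expect_gte(wi$p_waic, 0)
    expect_gte(wi$waic, -2 * wi$lppd)
  }
})

test_that("model ranking sorts by WAIC with pWAIC then id tie-breaks", {
  stub <- function(id, codes, ll) {
    cc <- strsplit(codes, "")[[1]]
    f <- make_fit_stub(constant_draws(ref_params(), 4))
    f$spec <- model_spec(cc[1], cc[2], cc[3], id = id)
    f$pointwise <- ll
    f$point_weights <- rep(1, ncol(ll))
    f$total_loglik <- rowSums(ll)
    f
  }
  set.seed(12)
  ll_a <- matrix(log(runif(20, 0.2, 0.9)), nrow = 4)
  ll_b <- ll_a + rnorm(20, sd = 0.3)
  f1 <- stub(3L, "OFO", ll_a)
  f2 <- stub(1L, "FOF", ll_b)
  f3 <- stub(7L, "FCF", ll_a)  # identical fit to f1: tie on WAIC and pWAIC
  tab <- compare_models(list(f1, f2, f3))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$rank, 1:3)
  expect_true(!is.unsorted(tab$waic))
  tied <- tab[tab$codes %in% c("OFO", "FCF"), ]
  expect_equal(tied$model_id, c(3L, 7L))  # lower id first on full tie
  expect_error(compare_models(list(f1)), "at least 2")
})

test_that("a saturated single-cell family fit reduces to the condition fit", {
  des <- one_cell_design(n_trials = 60)
  tr <- simulate_trials(des, flat_truth(des, ref_params()), seed = 71)
  fc <- fit_condition(tr, chains = 2, iter = 400, warmup = 400, seed = 72)
  ff <- fit_family(tr, model_spec("N", "N", "N"), chains = 2, iter = 400,
                   warmup = 400, seed = 73)
  mc <- colMeans(fc$draws)
  mf <- colMeans(ff$draws)
  expect_equal(sort(names(mc)), sort(names(mf)))
  # posterior means agree within Monte-Carlo error across independent seeds
  for (nm in names(mc)) {
    mcse <- sd(fc$draws[, nm]) / sqrt(50)  # conservative effective size
    expect_lt(abs(mc[nm] - mf[nm]), 6 * mcse + 0.02)
  }
})

test_that("joint fits recover a shared sigma across an observer's sizes", {
  cells <- tibble::tibble(subject = rep(c("O1", "O2"), each = 2),
                          optical = "AO", stroke = rep(c(0.4, 0.6), 2))
  des <- crowding_design(cells, n_trials = 150)
  truth <- dplyr::mutate(des$cells,
    A = rep(c(0.88, 0.95), 2),
    mu = ifelse(subject == "O1", 0.45, 0.6),
    sigma = ifelse(subject == "O1", 0.18, 0.25),
    m = -0.4, b = pmax(0, A - 0.2), gamma = 0.25)
  hits <- sapply(1:3, function(r) {
    tr <- simulate_trials(des, truth, seed = 800 + r)
    f <- fit_family(tr, model_spec("O", "O", "F"), chains = 2, iter = 500,
                    warmup = 500, seed = 900 + r)
    s <- summary(f)
    row <- s[s$param == "sigma[O1]", ]
    row$q2.5 <= 0.18 && 0.18 <= row$q97.5
  })
  expect_gte(sum(hits), 2)
})

test_that("the saturated model attains the highest fitted log-likelihood", {
  cells <- tibble::tibble(subject = c("O1", "O1"), optical = "AO",
                          stroke = c(0.4, 0.6))
  des <- crowding_design(cells, n_trials = 80)
  truth <- dplyr::mutate(des$cells, A = c(0.85, 0.95), mu = 0.5,
                         sigma = 0.2, m = -0.4, b = A - 0.2, gamma = 0.25)
  tr <- simulate_trials(des, truth, seed = 81)
  f_sat <- fit_family(tr, model_spec("N", "N", "N"), chains = 2, iter = 400,
                      warmup = 400, seed = 82)
  f_yok <- fit_family(tr, model_spec("F", "F", "F"), chains = 2, iter = 400,
                      warmup = 400, seed = 83)
  expect_gte(max(f_sat$total_loglik), max(f_yok$total_loglik) - 0.5)
})
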