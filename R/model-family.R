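# The hierarchical model lattice: the crowding-sigmoid width (sigma),
# location (mu) and recovery slope (m) may each be shared across
# conditions according to a constraint code, while the asymptote A and
# recovery intercept b always vary freely with every
# (observer, optical condition, stimulus size) cell. Codes:
#   F - one value shared across all observers, optical conditions, sizes
#   O - one per observer (shared across optical conditions and sizes)
#   C - one per observer x optical condition (shared across sizes)
#   N - one per cell (no constraint)

#' Define one member of the hierarchical model family
#'
#' @param sigma,mu,m constraint codes (`"F"`, `"O"`, `"C"`, or `"N"`) for
#'   the sigmoid width, sigmoid location, and recovery slope.
#' @param id optional integer id (assigned by [enumerate_models()]).
#' @return A `model_spec` object.
#' @export
model_spec <- function(sigma, mu, m, id = NA_integer_) {
  codes <- c(sigma = sigma, mu = mu, m = m)
  if (!all(codes %in% c("F", "O", "C", "N")))
    stop("constraint codes must be one of F, O, C, N", call. = FALSE)
  structure(list(id = as.integer(id), sigma = sigma, mu = mu, m = m),
            class = "model_spec")
}

model_code <- function(spec) paste0(spec$sigma, spec$mu, spec$m)

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> #%s %s (sigma=%s, mu=%s, m=%s)\n",
              ifelse(is.na(x$id), "?", x$id), model_code(x),
              x$sigma, x$mu, x$m), sep = "")
  invisible(x)
}

#' Enumerate the twelve-member model family
#'
#' The lattice of constraint-code triples over (sigma, mu, m), with their
#' conventional ids: #0 FFF (fully yoked) through #11 NNN (saturated,
#' equivalent to independent per-cell fits).
#'
#' @return A named list of twelve [model_spec()] objects
#'   (`"0"` ... `"11"`).
#' @export
enumerate_models <- function() {
  codes <- c("FFF", "FOF", "OFF", "OFO", "FFO", "OOF",
             "OOO", "FCF", "CCF", "CCC", "NOF", "NNN")
  out <- lapply(seq_along(codes), function(i) {
    cc <- strsplit(codes[i], "")[[1]]
    model_spec(cc[1], cc[2], cc[3], id = i - 1L)
  })
  names(out) <- as.character(0:11)
  out
}

#' Map design cells to shared-parameter slots
#'
#' For each of sigma, mu and m, assigns every (subject, optical, stroke)
#' cell to a parameter slot according to the model's constraint code.
#' `A` and `b` always get one slot per cell.
#'
#' @param spec a [model_spec()].
#' @param cells tibble with columns `subject`, `optical`, `stroke`.
#' @return list with, per parameter, `index` (slot of each cell),
#'   `labels` (slot names) and `n_slots`.
#' @export
parameter_index <- function(spec, cells) {
  stopifnot(inherits(spec, "model_spec"), nrow(cells) > 0)
  slot_for <- function(code, base) {
    key <- switch(code,
      F = rep("", nrow(cells)),
      O = cells$subject,
      C = paste(cells$subject, cells$optical, sep = ","),
      N = paste(cells$subject, cells$optical, format(cells$stroke),
                sep = ","))
    u <- unique(key)
    labels <- if (length(u) == 1) base else paste0(base, "[", u, "]")
    list(index = match(key, u), labels = labels, n_slots = length(u))
  }
  cell_key <- paste(cells$subject, cells$optical, format(cells$stroke),
                    sep = ",")
  per_cell <- list(
    index = seq_len(nrow(cells)),
    labels = if (nrow(cells) == 1) NULL else cell_key,
    n_slots = nrow(cells))
  list(A = c(per_cell, list(base = "A")),
       b = c(per_cell, list(base = "b")),
       sigma = slot_for(spec$sigma, "sigma"),
       mu = slot_for(spec$mu, "mu"),
       m = slot_for(spec$m, "m"))
}

#' Total free-parameter count of a model on a design
#'
#' @inheritParams parameter_index
#' @return integer: slots for sigma, mu, m plus `2 * nrow(cells)` for the
#'   per-cell `A` and `b`.
#' @export
n_parameters <- function(spec, cells) {
  pi <- parameter_index(spec, cells)
  pi$sigma$n_slots + pi$mu$n_slots + pi$m$n_slots + 2L * nrow(cells)
}

#' Fit one family model jointly across all conditions
#'
#' Builds the joint parameter vector implied by the constraint codes
#' (hard equality sharing across the cells each slot covers), samples the
#' posterior under uniform priors, and retains pointwise log-likelihoods
#' for WAIC. With code NNN on a single cell this is exactly the
#' single-condition fit.
#'
#' @inheritParams fit_condition
#' @param spec a [model_spec()].
#' @return A `crowding_fit` (see [fit_condition()]).
#' @export
fit_family <- function(trials, spec, priors = prior_spec(), chains = 4,
                       iter = 1000, warmup = 1000, seed = 1, gamma = 0.25) {
  stopifnot(inherits(spec, "model_spec"), inherits(priors, "prior_spec"))
  if (chains < 1 || iter < 1 || warmup < 0)
    stop("chains and iter must be >= 1, warmup >= 0", call. = FALSE)
  if (nrow(trials) == 0) stop("no trials to fit", call. = FALSE)
  fd <- build_fit_data(trials)
  nc <- nrow(fd$cells)
  pidx <- parameter_index(spec, fd$cells)

  finite_gaps <- unique(unlist(lapply(fd$per_cell,
                                      function(pc) pc$gaps[is.finite(pc$gaps)])))
  has_unf <- any(vapply(fd$per_cell,
                        function(pc) any(is.infinite(pc$gaps)), logical(1)))
  if (length(finite_gaps) < 2 || !has_unf)
    warning("fewer than 2 distinct finite gaps or no unflanked trials; the fit may be poorly constrained",
            call. = FALSE)
  degenerate <- local({
    k <- sum(unlist(lapply(fd$per_cell, `[[`, "k")))
    n <- sum(unlist(lapply(fd$per_cell, `[[`, "n")))
    k == 0 || k == n
  })
  if (degenerate)
    warning("all responses identical; posterior will be prior-dominated",
            call. = FALSE)

  # --- parameter layout: [A slots | b slots | sigma | mu | m] -------------
  off <- c(A = 0L, b = nc, sigma = 2L * nc,
           mu = 2L * nc + pidx$sigma$n_slots,
           m = 2L * nc + pidx$sigma$n_slots + pidx$mu$n_slots)
  P <- off[["m"]] + pidx$m$n_slots
  slot_of <- list(A = pidx$A$index,
                  b = nc + pidx$b$index,
                  sigma = off[["sigma"]] + pidx$sigma$index,
                  mu = off[["mu"]] + pidx$mu$index,
                  m = off[["m"]] + pidx$m$index)
  cell_lab <- if (nc == 1) NULL else
    paste(fd$cells$subject, fd$cells$optical, format(fd$cells$stroke),
          sep = ",")
  par_names <- c(
    if (nc == 1) "A" else paste0("A[", cell_lab, "]"),
    if (nc == 1) "b" else paste0("b[", cell_lab, "]"),
    pidx$sigma$labels, pidx$mu$labels, pidx$m$labels)

  lower <- numeric(P); upper <- numeric(P)
  log_scale <- logical(P)
  put <- function(lo, up, idx, logs = FALSE) {
    lower[idx] <<- lo; upper[idx] <<- up; log_scale[idx] <<- logs
  }
  put(priors$A[1], priors$A[2], seq_len(nc))
  put(priors$b[1], priors$b[2], nc + seq_len(nc))
  put(priors$sigma[1], priors$sigma[2],
      off[["sigma"]] + seq_len(pidx$sigma$n_slots), logs = TRUE)
  put(priors$mu[1], priors$mu[2],
      off[["mu"]] + seq_len(pidx$mu$n_slots))
  put(priors$m[1], priors$m[2],
      off[["m"]] + seq_len(pidx$m$n_slots))

  # which data cells each parameter touches (for incremental updates)
  cells_of <- vector("list", P)
  for (i in seq_len(nc)) {
    for (g in c("A", "b", "sigma", "mu", "m")) {
      j <- slot_of[[g]][i]
      cells_of[[j]] <- c(cells_of[[j]], i)
    }
  }

  cell_ll_fun <- function(theta, idx) {
    vapply(idx, function(i) {
      pc <- fd$per_cell[[i]]
      cell_loglik(pc$gaps, pc$k, pc$n,
                  A = theta[slot_of$A[i]], mu = theta[slot_of$mu[i]],
                  sigma = theta[slot_of$sigma[i]], m = theta[slot_of$m[i]],
                  b = theta[slot_of$b[i]], gamma = gamma)
    }, numeric(1))
  }

  # --- data-informed, per-chain jittered initial values -------------------
  interior <- function(x, lo, up) pmin(up - 1e-4 * (up - lo),
                                       pmax(lo + 1e-4 * (up - lo), x))
  cell_stat <- function(i, what) {
    pc <- fd$per_cell[[i]]
    uf <- is.infinite(pc$gaps)
    if (what == "A") {
      if (any(uf)) sum(pc$k[uf]) / sum(pc$n[uf])
      else max(pc$k / pc$n)
    } else {
      j <- which.min(pc$gaps)
      pc$k[j] / pc$n[j]
    }
  }
  base_init <- numeric(P)
  base_init[seq_len(nc)] <-
    vapply(seq_len(nc), cell_stat, numeric(1), what = "A")
  base_init[nc + seq_len(nc)] <-
    vapply(seq_len(nc), cell_stat, numeric(1), what = "b")
  base_init[off[["sigma"]] + seq_len(pidx$sigma$n_slots)] <- 0.2
  base_init[off[["mu"]] + seq_len(pidx$mu$n_slots)] <- 0.4
  base_init[off[["m"]] + seq_len(pidx$m$n_slots)] <- -0.3

  set.seed(seed %% 2147483647)
  inits <- lapply(seq_len(chains), function(ch) {
    th <- base_init +
      stats::runif(P, -0.05, 0.05) * (upper - lower) * !log_scale
    th[log_scale] <- base_init[log_scale] *
      exp(stats::runif(sum(log_scale), -0.3, 0.3))
    interior(th, lower, upper)
  })

  res <- mwg_sample(cell_ll_fun, nc,
                    par = list(lower = lower, upper = upper,
                               log_scale = log_scale, cells = cells_of),
                    inits = inits, chains = chains, iter = iter,
                    warmup = warmup)
  colnames(res$draws) <- par_names

  pw <- pointwise_loglik(res$draws, fd, slot_of, gamma)
  rhat <- split_rhat(res$draws, res$chain)
  near <- 0.01 * (upper - lower)
  boundary <- vapply(seq_len(P), function(j) {
    mean(res$draws[, j] < lower[j] + near[j] |
         res$draws[, j] > upper[j] - near[j]) > 0.05
  }, logical(1))

  structure(list(
    draws = res$draws, chain = res$chain,
    total_loglik = res$total_loglik,
    pointwise = pw$ll, point_weights = pw$weights, point_meta = pw$meta,
    cells = fd$cells, spec = spec, priors = priors, gamma = gamma,
    slot_of = slot_of,
    settings = list(chains = chains, iter = iter, warmup = warmup,
                    seed = seed),
    diagnostics = list(
      rhat = rhat,
      converged = all(rhat <= 1.01),
      accept_rate = res$accept_rate,
      boundary_flag = stats::setNames(boundary, par_names),
      prior_dominated = degenerate)
  ), class = "crowding_fit")
}

# Pointwise Bernoulli log-likelihoods over unique (cell, gap, outcome)
# points, with multiplicities as weights: trials sharing a point have
# identical likelihood terms, so WAIC over trials is a weighted sum over
# points. Fully vectorized across draws.
pointwise_loglik <- function(draws, fd, slot_of, gamma) {
  S <- nrow(draws)
  ll_cols <- list(); w <- integer(0); meta <- list()
  for (i in seq_len(nrow(fd$cells))) {
    pc <- fd$per_cell[[i]]
    A <- draws[, slot_of$A[i]]; b <- draws[, slot_of$b[i]]
    sg <- draws[, slot_of$sigma[i]]; mu <- draws[, slot_of$mu[i]]
    m <- draws[, slot_of$m[i]]
    G <- length(pc$gaps)
    X <- matrix(pc$gaps, S, G, byrow = TRUE)
    p_rec <- pmin(pmax(m * X + b, 0), 1)        # recycles by column: [s,g]
    p_crw <- gamma + (A - gamma) * stats::pnorm((X - mu) / sg)
    p <- pmax(p_rec, p_crw)
    uf <- is.infinite(pc$gaps)
    if (any(uf)) p[, uf] <- A
    for (g in seq_len(G)) {
      if (pc$k[g] > 0) {
        ll_cols <- c(ll_cols, list(log(p[, g])))
        w <- c(w, pc$k[g])
        meta <- c(meta, list(c(i, pc$gaps[g], 1)))
      }
      if (pc$n[g] - pc$k[g] > 0) {
        ll_cols <- c(ll_cols, list(log1p(-p[, g])))
        w <- c(w, pc$n[g] - pc$k[g])
        meta <- c(meta, list(c(i, pc$gaps[g], 0)))
      }
    }
  }
  mm <- do.call(rbind, meta)
  list(ll = do.call(cbind, ll_cols), weights = w,
       meta = tibble::tibble(cell = mm[, 1], gap = mm[, 2],
                             outcome = mm[, 3], count = w))
}

#' Widely applicable information criterion
#'
#' `lppd = sum_i log(mean_s exp l_is)` (computed with log-sum-exp
#' stabilization), `pWAIC = sum_i Var_s(l_is)` (the variance form), and
#' `WAIC = -2 (lppd - pWAIC)`. The pointwise unit is the individual
#' Bernoulli trial; trials with identical likelihood terms may be passed
#' once with an integer weight.
#'
#' @param x a `crowding_fit`, or an `S x N` matrix of pointwise
#'   log-likelihoods (draws in rows, data points in columns).
#' @param weights optional per-point multiplicities (matrix input only).
#' @return list with `waic`, `p_waic`, `lppd`.
#' @export
waic <- function(x, weights = NULL) {
  if (inherits(x, "crowding_fit")) {
    ll <- x$pointwise
    weights <- x$point_weights
  } else {
    ll <- as.matrix(x)
  }
  if (nrow(ll) < 2)
    stop("WAIC requires at least 2 posterior draws per point", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, ncol(ll))
  stopifnot(length(weights) == ncol(ll))
  mx <- apply(ll, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2, mx))))
  # columns that are constant at -Inf: lppd -Inf, variance 0
  lppd_i[!is.finite(mx)] <- -Inf
  var_i <- apply(ll, 2, stats::var)
  var_i[!is.finite(mx)] <- 0
  lppd <- sum(weights * lppd_i)
  p_waic <- sum(weights * var_i)
  list(waic = -2 * (lppd - p_waic), p_waic = p_waic, lppd = lppd)
}

#' Rank fitted family models by WAIC
#'
#' @param fits list of `crowding_fit` objects (typically one per
#'   [model_spec()] in [enumerate_models()]).
#' @return tibble sorted ascending by WAIC (ties broken by lower pWAIC,
#'   then id): `model_id, codes, waic, p_waic, lppd, loglik_max, rank`.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fitted models", call. = FALSE)
  rows <- lapply(fits, function(f) {
    w <- waic(f)
    tibble::tibble(model_id = f$spec$id, codes = model_code(f$spec),
                   waic = w$waic, p_waic = w$p_waic, lppd = w$lppd,
                   loglik_max = max(f$total_loglik))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$waic, out$p_waic, out$model_id), ]
  out$rank <- seq_len(nrow(out))
  out
}
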