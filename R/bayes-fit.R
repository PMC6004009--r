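# Bayesian estimation of the compound crowding model. The posterior is
# sampled with an adaptive Metropolis-within-Gibbs scheme: componentwise
# Gaussian proposals whose step sizes are tuned toward a 0.44 acceptance
# rate during warmup (diminishing adaptation), frozen afterwards. The
# width parameter sigma is proposed multiplicatively (a random walk on
# log sigma) with the change-of-variables correction, while its uniform
# prior applies on the natural scale.

#' Uniform prior bounds for the five model parameters
#'
#' Weak uniform priors: `A` in (0, 1), `sigma` in (0, 5), `mu` in (-1, 1),
#' `m` in (-1, 0), `b` in (0, 1). All bounds are configurable; note the
#' default `mu` upper bound can pinch fits whose true location approaches
#' 1 arcmin (boundary-hugging posteriors are flagged in diagnostics).
#'
#' @param A,sigma,mu,m,b length-2 numeric `(lower, upper)` bounds.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(A = c(0, 1), sigma = c(0, 5), mu = c(-1, 1),
                       m = c(-1, 0), b = c(0, 1)) {
  pr <- list(A = A, sigma = sigma, mu = mu, m = m, b = b)
  for (nm in names(pr)) {
    if (length(pr[[nm]]) != 2 || !(pr[[nm]][1] < pr[[nm]][2]))
      stop(sprintf("prior for %s must be (lower, upper) with lower < upper", nm),
           call. = FALSE)
  }
  structure(pr, class = "prior_spec")
}

#' Bernoulli log-likelihood of trials under fixed parameters
#'
#' Sums `c_i log psi(x_i) + (1 - c_i) log(1 - psi(x_i))` over trials;
#' unflanked trials enter at probability `A`. Probabilities of exactly 0
#' or 1 with a contradicting outcome yield `-Inf` (returned, not raised).
#'
#' @param trials trial tibble (`gap`, `correct`; other columns ignored).
#' @param params a [crowding_params()] object.
#' @return list with `total` (scalar) and `pointwise` (per-trial vector).
#' @export
trial_loglik <- function(trials, params) {
  stopifnot(nrow(trials) > 0)
  p <- psi(trials$gap, params)
  ll <- ifelse(trials$correct == 1, log(p), log1p(-p))
  list(total = sum(ll), pointwise = ll)
}

# ---- internal: aggregated data representation ------------------------------

# Collapse trials to per-cell binomial counts on the gap grid; the
# Bernoulli likelihood only depends on (k, n) per (cell, gap).
build_fit_data <- function(trials) {
  agg <- aggregate_trials(trials)
  cells <- dplyr::distinct(agg, .data$subject, .data$optical, .data$stroke)
  cells <- dplyr::arrange(cells, .data$subject, .data$optical, .data$stroke)
  per_cell <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- agg[agg$subject == cells$subject[i] &
               agg$optical == cells$optical[i] &
               agg$stroke == cells$stroke[i], ]
    sub <- sub[order(sub$gap), ]
    list(gaps = sub$gap, k = sub$n_correct, n = sub$n_total)
  })
  list(cells = cells, per_cell = per_cell)
}

# Vectorized per-cell binomial log-likelihood for scalar parameters.
cell_loglik <- function(gaps, k, n, A, mu, sigma, m, b, gamma) {
  p_rec <- pmin(1, pmax(0, m * gaps + b))
  p_crw <- gamma + (A - gamma) * stats::pnorm((gaps - mu) / sigma)
  p <- pmax(p_rec, p_crw)
  p[is.infinite(gaps)] <- A
  ll <- numeric(length(p))
  pos <- k > 0
  neg <- n - k > 0
  ll[pos] <- k[pos] * log(p[pos])
  ll[neg] <- ll[neg] + (n - k)[neg] * log1p(-p[neg])
  sum(ll)
}

# ---- internal: adaptive Metropolis-within-Gibbs ----------------------------

# par: list(lower, upper, log_scale, cells) with cells a list of integer
# vectors (which data cells each parameter touches). cell_ll_fun(theta, idx)
# returns the per-cell log-likelihood for cells idx at natural-scale theta.
#
# Each iteration performs a componentwise Metropolis sweep (step sizes
# adapted toward 0.44 acceptance during warmup) plus, from mid-warmup on,
# one joint Metropolis proposal whose covariance is the empirical
# covariance of the warmup history on the sampling scale (log for
# positive-only parameters), scaled 2.38/sqrt(P) and tuned toward 0.234
# acceptance. The joint move follows the posterior's correlation
# structure (the sigmoid width and location, and the recovery slope and
# intercept, are strongly correlated), which componentwise moves cannot.
mwg_sample <- function(cell_ll_fun, n_cells, par, inits, chains, iter,
                       warmup, adapt_batch = 25, target = 0.44,
                       joint_target = 0.234) {
  P <- length(par$lower)
  S <- chains * iter
  draws <- matrix(NA_real_, S, P)
  total_ll <- numeric(S)
  chain_id <- rep(seq_len(chains), each = iter)
  accept <- matrix(0, chains, P)
  ls <- par$log_scale

  to_samp <- function(th) { s <- th; s[ls] <- log(s[ls]); s }
  to_nat <- function(s) { th <- s; th[ls] <- exp(th[ls]); th }

  joint_start <- max(100L, floor(warmup / 2))
  for (ch in seq_len(chains)) {
    theta <- inits[[ch]]
    cll <- cell_ll_fun(theta, seq_len(n_cells))
    lstep <- log(ifelse(ls, 0.3, 0.05 * (par$upper - par$lower)))
    batch_acc <- numeric(P)
    batch_n <- 0
    hist <- matrix(NA_real_, warmup, P)
    chol_L <- NULL
    joint_lscale <- log(2.38 / sqrt(P))
    joint_acc <- 0; joint_n <- 0
    row0 <- (ch - 1) * iter

    for (it in seq_len(warmup + iter)) {
      for (j in seq_len(P)) {
        if (ls[j]) {
          z <- exp(lstep[j]) * stats::rnorm(1)
          nat <- theta[j] * exp(z)
          ljac <- z
        } else {
          nat <- theta[j] + exp(lstep[j]) * stats::rnorm(1)
          ljac <- 0
        }
        if (nat > par$lower[j] && nat < par$upper[j]) {
          idx <- par$cells[[j]]
          th2 <- theta
          th2[j] <- nat
          new_ll <- cell_ll_fun(th2, idx)
          dll <- sum(new_ll) - sum(cll[idx])
          if (is.finite(dll) && log(stats::runif(1)) < dll + ljac) {
            theta <- th2
            cll[idx] <- new_ll
            batch_acc[j] <- batch_acc[j] + 1
            if (it > warmup) accept[ch, j] <- accept[ch, j] + 1
          }
        }
      }

      if (!is.null(chol_L)) {
        s_cur <- to_samp(theta)
        s_new <- s_cur +
          exp(joint_lscale) * drop(chol_L %*% stats::rnorm(P))
        th2 <- to_nat(s_new)
        if (all(th2 > par$lower & th2 < par$upper)) {
          new_cll <- cell_ll_fun(th2, seq_len(n_cells))
          ljac <- sum(s_new[ls] - s_cur[ls])
          dll <- sum(new_cll) - sum(cll)
          if (is.finite(dll) && log(stats::runif(1)) < dll + ljac) {
            theta <- th2
            cll <- new_cll
            joint_acc <- joint_acc + 1
          }
        }
        joint_n <- joint_n + 1
      }

      if (it <= warmup) {
        hist[it, ] <- to_samp(theta)
        batch_n <- batch_n + 1
        if (batch_n == adapt_batch) {
          delta <- min(0.25, 1 / sqrt(it / adapt_batch))
          lstep <- lstep + delta * (batch_acc / adapt_batch - target)
          if (joint_n > 0) {
            joint_lscale <- joint_lscale +
              delta * (joint_acc / joint_n - joint_target)
            joint_acc <- 0; joint_n <- 0
          }
          batch_acc[] <- 0
          batch_n <- 0
        }
        if (it >= joint_start && (it %% 50 == 0 || it == warmup)) {
          cv <- stats::cov(hist[seq(floor(it / 2), it), , drop = FALSE])
          chol_L <- tryCatch(
            t(chol(cv + diag(1e-8 + 1e-6 * diag(cv), P))),
            error = function(e) chol_L)
        }
      } else {
        draws[row0 + it - warmup, ] <- theta
        total_ll[row0 + it - warmup] <- sum(cll)
      }
    }
  }
  list(draws = draws, chain = chain_id, total_loglik = total_ll,
       accept_rate = accept / iter)
}

# Split-R-hat (rank-free version): each chain is split in half; between-
# and within-sequence variances are combined in the usual way.
split_rhat <- function(draws, chain) {
  apply(draws, 2, function(x) {
    seqs <- list()
    for (ch in unique(chain)) {
      xs <- x[chain == ch]
      h <- floor(length(xs) / 2)
      seqs <- c(seqs, list(xs[1:h]), list(xs[(h + 1):(2 * h)]))
    }
    L <- length(seqs[[1]])
    means <- vapply(seqs, mean, numeric(1))
    vars <- vapply(seqs, stats::var, numeric(1))
    W <- mean(vars)
    B <- L * stats::var(means)
    if (!is.finite(W) || W <= 0) return(1)
    sqrt(((L - 1) / L * W + B / L) / W)
  })
}

# ---- fitting ---------------------------------------------------------------

#' Fit the five-parameter model to one condition's trials
#'
#' Samples the posterior of `(A, mu, sigma, m, b)` for a single
#' (subject, optical, stroke) cell under uniform priors, with the guess
#' rate fixed. Unflanked trials enter the likelihood directly at
#' probability `A`, so the asymptote is estimated jointly with the curve.
#'
#' @param trials trial tibble for exactly one condition cell.
#' @param priors a [prior_spec()].
#' @param chains,iter,warmup MCMC settings (post-warmup draws per chain).
#' @param seed integer seed; seeded runs are exactly reproducible.
#' @param gamma fixed guess rate.
#' @return A `crowding_fit` object: posterior `draws` (matrix, natural
#'   scale, named columns), pointwise log-likelihoods for WAIC, and
#'   convergence diagnostics (split R-hat, acceptance rates, flags).
#' @export
fit_condition <- function(trials, priors = prior_spec(), chains = 4,
                          iter = 1000, warmup = 1000, seed = 1,
                          gamma = 0.25) {
  fd <- build_fit_data(trials)
  if (nrow(fd$cells) != 1)
    stop("fit_condition expects trials from exactly one (subject, optical, stroke) cell; use fit_family for several",
         call. = FALSE)
  fit_family(trials, model_spec("N", "N", "N"), priors = priors,
             chains = chains, iter = iter, warmup = warmup, seed = seed,
             gamma = gamma)
}

#' Posterior summaries of a fit
#'
#' Per-parameter mean, median, and central 95% credible interval computed
#' from pooled post-warmup draws, with split R-hat.
#'
#' @param object a `crowding_fit`.
#' @param ... unused.
#' @return tibble: `param, mean, median, q2.5, q97.5, rhat`.
#' @export
summary.crowding_fit <- function(object, ...) {
  d <- object$draws
  tibble::tibble(
    param = colnames(d),
    mean = unname(colMeans(d)),
    median = unname(apply(d, 2, stats::median)),
    q2.5 = unname(apply(d, 2, stats::quantile, probs = 0.025, names = FALSE)),
    q97.5 = unname(apply(d, 2, stats::quantile, probs = 0.975, names = FALSE)),
    rhat = unname(object$diagnostics$rhat))
}

#' @rdname summary.crowding_fit
#' @param fit a `crowding_fit`.
#' @export
posterior_summary <- function(fit) summary(fit)

#' @export
print.crowding_fit <- function(x, ...) {
  cat(sprintf("<crowding_fit> model %s | %d cell(s) | %d draws (%d chains)\n",
              model_code(x$spec), nrow(x$cells), nrow(x$draws),
              length(unique(x$chain))))
  if (!x$diagnostics$converged)
    cat("  WARNING: not converged (max split R-hat ",
        sprintf("%.3f", max(x$diagnostics$rhat)), ")\n", sep = "")
  print(summary(x), n = 12)
  invisible(x)
}

#' Extract per-cell parameter draws from a fit
#'
#' Maps the fit's shared-slot draws back to the five-parameter set of one
#' condition cell.
#'
#' @param fit a `crowding_fit`.
#' @param subject,optical,stroke cell key; may be omitted for
#'   single-cell fits.
#' @return matrix of draws with columns `A, mu, sigma, m, b`.
#' @export
cell_draws <- function(fit, subject = NULL, optical = NULL, stroke = NULL) {
  i <- locate_cell(fit, subject, optical, stroke)
  cols <- c(A = fit$slot_of$A[i], b = fit$slot_of$b[i],
            sigma = fit$slot_of$sigma[i], mu = fit$slot_of$mu[i],
            m = fit$slot_of$m[i])
  d <- fit$draws[, cols, drop = FALSE]
  colnames(d) <- c("A", "b", "sigma", "mu", "m")
  d[, c("A", "mu", "sigma", "m", "b"), drop = FALSE]
}

locate_cell <- function(fit, subject, optical, stroke) {
  if (is.null(subject)) {
    if (nrow(fit$cells) != 1)
      stop("multi-cell fit: specify subject, optical and stroke", call. = FALSE)
    return(1L)
  }
  i <- which(fit$cells$subject == subject & fit$cells$optical == optical &
             abs(fit$cells$stroke - stroke) < 1e-9)
  if (length(i) != 1) stop("cell not found in fit", call. = FALSE)
  i
}
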