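#' Compound crowding psychometric model parameters
#'
#' Bundles the five parameters of the performance-versus-flanker-spacing
#' model together with the fixed guess rate. Performance as a function of
#' the edge-to-edge gap `x` (arcmin) is the pointwise maximum of two
#' branches: a guess-corrected cumulative-Gaussian crowding sigmoid
#' \deqn{\Psi_{crowding}(x) = \gamma + (A - \gamma)\,\Phi((x - \mu)/\sigma)}
#' and a linear recovery branch \eqn{\Psi_{recovery}(x) = m x + b} describing
#' the performance rebound at the very nearest spacings.
#'
#' @param A asymptotic (unflanked) proportion correct, in `[gamma, 1]`
#'   (`A = gamma` gives the degenerate flat chance-level curve).
#' @param mu location of the crowding sigmoid (arcmin).
#' @param sigma width of the crowding sigmoid (arcmin, > 0).
#' @param m slope of the recovery line (proportion per arcmin, <= 0).
#' @param b intercept of the recovery line at gap 0 (abutting), in `[0, 1]`.
#' @param gamma guess rate; 0.25 for the four-alternative Tumbling-E task.
#'
#' @return An object of class `crowding_params`.
#' @examples
#' p <- crowding_params(A = 0.95, mu = 0.5, sigma = 0.2, m = -0.4, b = 0.8)
#' psi(c(0, 0.4, 1.2, unflanked()), p)
#' @export
crowding_params <- function(A, mu, sigma, m, b, gamma = 0.25) {
  stopifnot(is.numeric(A), is.numeric(mu), is.numeric(sigma),
            is.numeric(m), is.numeric(b), is.numeric(gamma))
  if (!(sigma > 0)) stop("sigma must be > 0", call. = FALSE)
  if (!(A >= gamma && A <= 1))
    stop("A must satisfy gamma <= A <= 1", call. = FALSE)
  if (m > 0) stop("m must be <= 0", call. = FALSE)
  if (b < 0 || b > 1) stop("b must lie in [0, 1]", call. = FALSE)
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)", call. = FALSE)
  structure(list(A = A, mu = mu, sigma = sigma, m = m, b = b, gamma = gamma),
            class = "crowding_params")
}

#' @export
print.crowding_params <- function(x, ...) {
  cat(sprintf(
    "<crowding_params> A=%.3f mu=%.3f sigma=%.3f m=%.3f b=%.3f (gamma=%.2f)\n",
    x$A, x$mu, x$sigma, x$m, x$b, x$gamma))
  invisible(x)
}

#' Unflanked gap marker
#'
#' The unflanked (no-flanker) condition is modelled as the large-spacing
#' limit of the crowding sigmoid and is represented numerically as `Inf`,
#' so that it compares greater than any finite gap. In trial CSV files it
#' is written as the literal token `UNFLANKED`.
#'
#' @return `Inf` (the unflanked marker).
#' @export
unflanked <- function() Inf

#' @rdname unflanked
#' @param gap numeric gap vector (arcmin, `Inf` = unflanked).
#' @export
is_unflanked <- function(gap) is.infinite(gap) & gap > 0

#' Linear recovery branch of the crowding model
#'
#' Evaluates `m * x + b`, clipped to `[0, 1]` to preserve probability
#' semantics (the clip never bites over fitted regions since `b <= 1` and
#' `m <= 0` keep the line in range at tested gaps).
#'
#' @param x edge-to-edge gap(s), arcmin, finite and >= 0.
#' @param params a [crowding_params()] object.
#' @return proportion correct, same length as `x`.
#' @export
psi_recovery <- function(x, params) {
  stopifnot(inherits(params, "crowding_params"))
  pmin(1, pmax(0, params$m * x + params$b))
}

#' Crowding sigmoid branch of the model
#'
#' Guess-corrected cumulative Gaussian:
#' `gamma + (A - gamma) * pnorm((x - mu) / sigma)`. The unflanked marker
#' (`Inf`) returns the asymptote `A` exactly.
#'
#' @inheritParams psi_recovery
#' @return proportion correct, same length as `x`.
#' @export
psi_crowding <- function(x, params) {
  stopifnot(inherits(params, "crowding_params"))
  if (params$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  out <- params$gamma +
    (params$A - params$gamma) * stats::pnorm((x - params$mu) / params$sigma)
  out[is_unflanked(x)] <- params$A
  out
}

#' Full compound psychometric function
#'
#' The pointwise maximum of the recovery line and the crowding sigmoid for
#' finite gaps; the unflanked marker returns `A` exactly (the recovery
#' branch does not extend to the unflanked condition).
#'
#' @inheritParams psi_recovery
#' @param x edge-to-edge gap(s) in arcmin; `Inf` marks unflanked.
#' @return proportion correct, same length as `x`.
#' @export
psi <- function(x, params) {
  stopifnot(inherits(params, "crowding_params"))
  if (params$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  uf <- is_unflanked(x)
  out <- numeric(length(x))
  if (any(!uf)) {
    xf <- x[!uf]
    out[!uf] <- pmax(psi_recovery(xf, params), psi_crowding(xf, params))
  }
  out[uf] <- params$A
  out
}

#' Correct a proportion for guessing
#'
#' Rescales proportion correct from the chance-limited range
#' `[gamma, 1]` to `[0, 1]`: `(p - gamma) / (1 - gamma)`.
#' Cells below chance are a domain error and are reported, not clipped.
#'
#' @param p proportion(s) correct, each in `[gamma, 1]`.
#' @param gamma guess rate.
#' @return corrected proportion(s) in `[0, 1]`.
#' @export
correct_for_guessing <- function(p, gamma = 0.25) {
  bad <- which(p < gamma)
  if (length(bad) > 0) {
    stop(sprintf("proportion(s) below guess rate %.3g at position(s) %s",
                 gamma, paste(bad, collapse = ", ")), call. = FALSE)
  }
  (p - gamma) / (1 - gamma)
}

#' Proportion to Z-score (probit units)
#'
#' Inverse standard-normal CDF of a proportion, the sensitivity-like scale
#' on which equal performance drops are comparable across the psychometric
#' function. Proportions are clamped to `[eps, 1 - eps]` with a warning so
#' that empirical cells at exactly 0 or 1 map to finite Z values; pass
#' `clamp = FALSE` to get infinite values instead.
#'
#' @param p proportion(s) in `[0, 1]`.
#' @param eps clamping epsilon (default `1e-6`).
#' @param clamp clamp before transforming? (default `TRUE`).
#' @return Z-score(s), `qnorm(p)`.
#' @export
to_z <- function(p, eps = 1e-6, clamp = TRUE) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (clamp) {
    hit <- p < eps | p > 1 - eps
    if (any(hit, na.rm = TRUE)) {
      warning(sprintf("%d proportion(s) clamped to [%g, %g] before probit",
                      sum(hit, na.rm = TRUE), eps, 1 - eps), call. = FALSE)
      p <- pmin(1 - eps, pmax(eps, p))
    }
  }
  stats::qnorm(p)
}

#' Z-score reduction from the fitted asymptote
#'
#' Expresses a proportion correct as its change in probit units relative
#' to the asymptotic performance level `A`: `to_z(p') - to_z(A')`, a
#' non-positive number for `p <= A`. With `mode = "guess_corrected"` both
#' proportions are first corrected for guessing; the default `"raw"`
#' transforms the proportions directly (this reproduces the conventional
#' worked arithmetic, e.g. a drop from 0.95 to 0.90 is
#' `qnorm(0.95) - qnorm(0.90) = 0.363` Z-units).
#'
#' @param p observed proportion(s) correct.
#' @param A asymptotic proportion correct.
#' @param mode `"raw"` or `"guess_corrected"`.
#' @param gamma guess rate (used by `"guess_corrected"`).
#' @inheritParams to_z
#' @return change in Z-units, `<= 0` when `p <= A`.
#' @export
z_reduction <- function(p, A, mode = c("raw", "guess_corrected"),
                        gamma = 0.25, eps = 1e-6) {
  mode <- match.arg(mode)
  if (mode == "guess_corrected") {
    p <- correct_for_guessing(p, gamma)
    A <- correct_for_guessing(A, gamma)
  }
  to_z(p, eps = eps) - to_z(A, eps = eps)
}

#' Invert a Z-score reduction back to a proportion
#'
#' Exact inverse of [z_reduction()]: given a (non-positive) change in
#' probit units and the asymptote, recovers the proportion correct.
#'
#' @param dz change in Z-units (`<= 0`).
#' @inheritParams z_reduction
#' @return proportion(s) correct.
#' @export
from_z_reduction <- function(dz, A, mode = c("raw", "guess_corrected"),
                             gamma = 0.25, eps = 1e-6) {
  mode <- match.arg(mode)
  Ac <- if (mode == "guess_corrected") correct_for_guessing(A, gamma) else A
  p <- stats::pnorm(dz + to_z(Ac, eps = eps))
  if (mode == "guess_corrected") p <- gamma + (1 - gamma) * p
  if (any(p < 0)) stop("inverted proportion below 0", call. = FALSE)
  p
}
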