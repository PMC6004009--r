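# Synthetic trial generation emulating the crowding experiment design:
# 3 observers x 2 optical conditions (AO / noAO), 2-5 stroke sizes per
# condition, edge-to-edge gaps from abutting (0) to 1.6 arcmin plus an
# unflanked condition, binomial responses drawn from the compound model.

#' Default experimental design
#'
#' Three observers, each tested with and without adaptive-optics (AO)
#' correction at the published per-observer stroke sizes (arcmin; letter
#' height is five strokes), over a gap grid from abutting to 1.6 arcmin in
#' 0.2-arcmin steps plus the unflanked condition, with 20 trials per cell
#' (10 per block over at least two sessions).
#'
#' @param gaps finite edge-to-edge gap grid, arcmin (sorted, >= 0).
#' @param include_unflanked add the unflanked condition to every cell?
#' @param n_trials trials per (subject, optical, stroke, gap) cell.
#' @return A `crowding_design`: list with `cells` (tibble of
#'   subject/optical/stroke), `gaps`, and `n_trials`.
#' @export
default_design <- function(gaps = seq(0, 1.6, by = 0.2),
                           include_unflanked = TRUE,
                           n_trials = 20) {
  strokes <- list(
    S1 = list(AO = c(0.61, 0.73),
              noAO = c(0.85, 0.97)),
    S2 = list(AO = c(0.37, 0.42, 0.47, 0.53, 0.58),
              noAO = c(0.63, 0.69, 0.79)),
    S3 = list(AO = c(0.53, 0.58, 0.63, 0.69),
              noAO = c(0.63, 0.69, 0.74, 0.79))
  )
  cells <- dplyr::bind_rows(lapply(names(strokes), function(s) {
    dplyr::bind_rows(lapply(c("AO", "noAO"), function(o) {
      tibble::tibble(subject = s, optical = o, stroke = strokes[[s]][[o]])
    }))
  }))
  crowding_design(cells, gaps = gaps,
                  include_unflanked = include_unflanked, n_trials = n_trials)
}

#' Construct a design from an explicit cell table
#'
#' @param cells tibble/data.frame with columns `subject`, `optical`
#'   (`"AO"`/`"noAO"`), `stroke` (arcmin, > 0); one row per condition cell.
#' @inheritParams default_design
#' @return A `crowding_design` object.
#' @export
crowding_design <- function(cells, gaps = seq(0, 1.6, by = 0.2),
                            include_unflanked = TRUE, n_trials = 20) {
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("subject", "optical", "stroke") %in% names(cells)),
            nrow(cells) > 0)
  if (!all(cells$optical %in% c("AO", "noAO")))
    stop("optical must be 'AO' or 'noAO'", call. = FALSE)
  if (!all(cells$stroke > 0)) stop("stroke sizes must be > 0", call. = FALSE)
  if (length(gaps) < 1 || is.unsorted(gaps) || any(gaps < 0) || any(!is.finite(gaps)))
    stop("gaps must be a non-empty sorted grid of finite non-negative values",
         call. = FALSE)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  all_gaps <- if (include_unflanked) c(gaps, unflanked()) else gaps
  structure(list(cells = cells, gaps = all_gaps, n_trials = n_trials),
            class = "crowding_design")
}

#' @export
print.crowding_design <- function(x, ...) {
  cat(sprintf("<crowding_design> %d cells x %d gaps x %d trials/cell\n",
              nrow(x$cells), length(x$gaps), x$n_trials))
  invisible(x)
}

#' Ground-truth parameter tables for simulation
#'
#' `flat_truth()` assigns one parameter set to every design cell;
#' `default_truth()` produces a realistic heterogeneous truth: within each
#' (subject, optical) condition the asymptote rises with stroke size from
#' 0.80 to 0.97, the recovery intercept sits 0.2 below the asymptote
#' (abutting flankers cost about 20 percentage points), the sigmoid
#' location is observer-specific (0.45/0.50/0.55 arcmin) with width 0.2
#' arcmin, and the recovery slope is -0.4 per arcmin — the regime in which
#' critical spacings land around 0.75-1.3 arcmin at 80-95% asymptotes.
#'
#' @param design a `crowding_design`.
#' @param params a [crowding_params()] object (for `flat_truth`).
#' @return tibble keyed by (subject, optical, stroke) with columns
#'   `A, mu, sigma, m, b, gamma`.
#' @export
flat_truth <- function(design, params) {
  stopifnot(inherits(design, "crowding_design"),
            inherits(params, "crowding_params"))
  dplyr::mutate(design$cells, A = params$A, mu = params$mu,
                sigma = params$sigma, m = params$m, b = params$b,
                gamma = params$gamma)
}

#' @rdname flat_truth
#' @export
default_truth <- function(design) {
  stopifnot(inherits(design, "crowding_design"))
  mu_by_subject <- function(s) {
    idx <- match(s, sort(unique(design$cells$subject)))
    c(0.45, 0.50, 0.55)[((idx - 1) %% 3) + 1]
  }
  out <- design$cells
  out <- dplyr::group_by(out, .data$subject, .data$optical)
  out <- dplyr::mutate(out,
    A = if (dplyr::n() == 1) 0.9
        else 0.80 + 0.17 * (rank(.data$stroke) - 1) / (dplyr::n() - 1))
  out <- dplyr::ungroup(out)
  dplyr::mutate(out,
    mu = vapply(.data$subject, mu_by_subject, numeric(1)),
    sigma = 0.2, m = -0.4, b = pmax(0, .data$A - 0.2), gamma = 0.25)
}

# FNV-1a 32-bit hash of a string, reduced mod 2^31 - 1: derives stable
# per-cell RNG substreams from the top-level seed so that adding a cell
# leaves every other cell's draws unchanged.
fnv1a <- function(s) {
  h <- 2166136261
  for (byte in utf8ToInt(s)) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(byte))
    # 32-bit multiply by the FNV prime 16777619, overflow-safe in doubles
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  h %% 2147483647
}

cell_seed <- function(seed, subject, optical, stroke, gap) {
  key <- paste(subject, optical, format(stroke), format(gap), sep = "|")
  (seed + fnv1a(key)) %% 2147483647
}

#' Simulate trial-level responses from a ground truth
#'
#' Draws each trial's correctness as an independent Bernoulli variable
#' with success probability `psi(gap, params)` for that cell's true
#' parameters. A single top-level seed deterministically derives a
#' substream per (subject, optical, stroke, gap) cell, so identical seeds
#' give byte-identical datasets and adding cells does not perturb others.
#'
#' @param design a `crowding_design`.
#' @param truth a truth tibble covering every design cell
#'   (see [flat_truth()]).
#' @param seed integer seed.
#' @return tibble of trials: `subject, optical, stroke, gap, correct`.
#' @export
simulate_trials <- function(design, truth, seed = 1) {
  stopifnot(inherits(design, "crowding_design"))
  key <- paste(design$cells$subject, design$cells$optical,
               format(design$cells$stroke))
  tkey <- paste(truth$subject, truth$optical, format(truth$stroke))
  miss <- setdiff(key, tkey)
  if (length(miss) > 0)
    stop("ground truth missing design cell(s): ",
         paste(miss, collapse = "; "), call. = FALSE)
  rows <- vector("list", nrow(design$cells) * length(design$gaps))
  k <- 0
  for (i in seq_len(nrow(design$cells))) {
    cell <- design$cells[i, ]
    tr <- truth[tkey == key[i], ][1, ]
    pars <- crowding_params(tr$A, tr$mu, tr$sigma, tr$m, tr$b, tr$gamma)
    for (g in design$gaps) {
      p <- psi(g, pars)
      set.seed(cell_seed(seed, cell$subject, cell$optical, cell$stroke, g))
      k <- k + 1
      rows[[k]] <- tibble::tibble(
        subject = cell$subject, optical = cell$optical,
        stroke = cell$stroke, gap = g,
        correct = stats::rbinom(design$n_trials, 1, p))
    }
  }
  dplyr::bind_rows(rows)
}

#' Aggregate trials to per-cell counts
#'
#' @param trials trial tibble (`subject, optical, stroke, gap, correct`).
#' @return tibble keyed by (subject, optical, stroke, gap) with
#'   `n_correct` and `n_total`.
#' @export
aggregate_trials <- function(trials) {
  if (nrow(trials) == 0) {
    return(tibble::tibble(subject = character(), optical = character(),
                          stroke = numeric(), gap = numeric(),
                          n_correct = integer(), n_total = integer()))
  }
  out <- dplyr::group_by(trials, .data$subject, .data$optical,
                         .data$stroke, .data$gap)
  out <- dplyr::summarise(out, n_correct = sum(.data$correct),
                          n_total = dplyr::n(), .groups = "drop")
  out
}
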