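# Trial CSV dialect: header subject,optical,stroke_arcmin,gap_arcmin,correct
# with gap_arcmin a non-negative decimal or the literal token UNFLANKED,
# optical in {AO, noAO}, correct in {0, 1}. Comment lines beginning with
# '#' (used for provenance headers) are tolerated by the reader.

TRIAL_HEADER <- "subject,optical,stroke_arcmin,gap_arcmin,correct"

fmt_num <- function(x) {
  vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                               drop0trailing = TRUE), character(1))
}

#' Read a trial CSV file
#'
#' Parses and validates the trial-table dialect; malformed rows are
#' reported with their line numbers. The `UNFLANKED` token becomes the
#' numeric marker `Inf` (see [unflanked()]).
#'
#' @param path file path.
#' @return trial tibble: `subject, optical, stroke, gap, correct`.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty trial file: ", path, call. = FALSE)
  if (trimws(lines[1]) != TRIAL_HEADER)
    stop(sprintf("line %d: expected header '%s'", lineno[1], TRIAL_HEADER),
         call. = FALSE)
  lines <- lines[-1]; lineno <- lineno[-1]
  if (length(lines) == 0) {
    return(tibble::tibble(subject = character(), optical = character(),
                          stroke = numeric(), gap = numeric(),
                          correct = integer()))
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- character(0)
  note <- function(i, msg) bad <<- c(bad, sprintf("line %d: %s", lineno[i], msg))
  n <- length(parts)
  subject <- character(n); optical <- character(n)
  stroke <- numeric(n); gap <- numeric(n); correct <- integer(n)
  for (i in seq_len(n)) {
    f <- trimws(parts[[i]])
    if (length(f) != 5) { note(i, "expected 5 fields"); next }
    subject[i] <- f[1]
    if (!f[2] %in% c("AO", "noAO")) note(i, paste0("unknown optical token '", f[2], "'"))
    optical[i] <- f[2]
    s <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || s <= 0) note(i, paste0("invalid stroke '", f[3], "'"))
    stroke[i] <- s
    if (f[4] == "UNFLANKED") {
      gap[i] <- unflanked()
    } else {
      g <- suppressWarnings(as.numeric(f[4]))
      if (is.na(g) || g < 0 || !is.finite(g))
        note(i, paste0("invalid gap '", f[4], "' (non-negative number or UNFLANKED)"))
      gap[i] <- g
    }
    if (!f[5] %in% c("0", "1")) note(i, paste0("non-binary correct '", f[5], "'"))
    correct[i] <- suppressWarnings(as.integer(f[5]))
  }
  if (length(bad) > 0)
    stop("invalid trial file:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  tibble::tibble(subject = subject, optical = optical, stroke = stroke,
                 gap = gap, correct = correct)
}

#' Write a trial CSV file
#'
#' Inverse of [read_trials()]: a parse-then-write round trip is
#' byte-identical for canonical files (no comments). Optional provenance
#' comment lines (seed, package version, configuration digest) can be
#' prepended; readers skip them.
#'
#' @param trials trial tibble.
#' @param path output file path.
#' @param provenance optional named character/numeric vector written as
#'   leading `# key=value` comment lines.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, provenance = NULL) {
  rows <- paste(trials$subject, trials$optical, fmt_num(trials$stroke),
                ifelse(is_unflanked(trials$gap), "UNFLANKED",
                       fmt_num(trials$gap)),
                trials$correct, sep = ",")
  writeLines(c(provenance_lines(provenance), TRIAL_HEADER, rows), path)
  invisible(path)
}

provenance_lines <- function(provenance) {
  if (is.null(provenance)) return(character(0))
  paste0("# ", names(provenance), "=", unlist(provenance))
}

default_provenance <- function(seed, extra = NULL) {
  c(package = paste0("crowdfit ",
                     as.character(utils::packageVersion("crowdfit"))),
    seed = seed, extra)
}

write_table_csv <- function(df, path, provenance = NULL) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- vapply(df[[j]], function(v) {
    if (is.na(v)) "NA" else format(v, scientific = FALSE, trim = TRUE,
                                   digits = 15, drop0trailing = TRUE)
  }, character(1))
  lines <- c(provenance_lines(provenance),
             paste(names(out), collapse = ","),
             do.call(paste, c(unname(as.list(out)), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}
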