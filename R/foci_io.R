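#' Read a table of activation foci
#'
#' Foci are reported activation peaks in stereotactic millimetre coordinates,
#' grouped into experiments (one per contrast of one study) that carry
#' behavioural-domain labels. Two dialects are supported:
#'
#' * `sleuth_text`: BrainMap/Sleuth-style plain text. Header lines
#'   `// Study: <id>`, `// Experiment: <id>`, `// Domain: <labels>` precede
#'   one whitespace-separated `x y z` triple per line; a blank line separates
#'   experiments. Multiple domain labels are separated by `;`.
#' * `csv`: columns `study_id, experiment_id, domain, x, y, z`. Rows sharing
#'   an `experiment_id` belong to one experiment (foci are pooled).
#'
#' @param path Path to the foci file.
#' @param dialect `"sleuth_text"` or `"csv"`.
#' @return A tibble with columns `study_id`, `experiment_id`, `domain`
#'   (character, `;`-separated labels), `x`, `y`, `z` (mm), one row per
#'   focus. Row order follows the file.
#' @export
read_foci_table <- function(path, dialect = c("sleuth_text", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- switch(dialect,
    sleuth_text = read_foci_sleuth(path),
    csv = read_foci_csv(path))
  if (nrow(out) == 0L) abort(sprintf("no foci found in %s", path))
  out
}

read_foci_sleuth <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(trimws(lines)) || all(trimws(lines) == ""))
    abort(sprintf("empty foci file: %s", path))
  study <- experiment <- NA_character_
  domain <- ""
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { study <- experiment <- NA_character_; domain <- ""; next }
    if (startsWith(ln, "//")) {
      body <- trimws(sub("^//", "", ln))
      if (grepl("^Study:", body)) study <- trimws(sub("^Study:", "", body))
      else if (grepl("^Experiment:", body))
        experiment <- trimws(sub("^Experiment:", "", body))
      else if (grepl("^Domain:", body))
        domain <- trimws(sub("^Domain:", "", body))
      next
    }
    parts <- strsplit(ln, "[\t ]+")[[1]]
    xyz <- suppressWarnings(as.numeric(parts))
    if (length(xyz) != 3L || anyNA(xyz) || any(!is.finite(xyz)))
      abort(sprintf("malformed coordinate line %d in %s: \"%s\"",
                    i, path, lines[i]))
    rows[[i]] <- tibble(
      study_id = study %||% NA_character_,
      experiment_id = experiment %||% study,
      domain = domain, x = xyz[1], y = xyz[2], z = xyz[3])
  }
  out <- bind_rows(rows)
  if (nrow(out))
    out$experiment_id <- ifelse(is.na(out$experiment_id), out$study_id,
                                out$experiment_id)
  out
}

read_foci_csv <- function(path) {
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", strip.white = TRUE),
    error = function(e) abort(sprintf("cannot parse %s: %s", path,
                                      conditionMessage(e))))
  need <- c("study_id", "experiment_id", "domain", "x", "y", "z")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    abort(sprintf("%s is missing columns: %s", path,
                  paste(miss, collapse = ", ")))
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      abort(sprintf("malformed coordinate in %s, data row %d, column %s: \"%s\"",
                    path, bad[1], col, raw[[col]][bad[1]]))
    raw[[col]] <- v
  }
  as_tibble(raw[need])
}

#' Write a table of activation foci
#'
#' Inverse of [read_foci_table()]; writing and re-reading a foci tibble is
#' lossless for both dialects.
#'
#' @param foci A foci tibble (see [read_foci_table()]).
#' @param path Output path.
#' @param dialect `"sleuth_text"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_foci_table <- function(foci, path, dialect = c("sleuth_text", "csv")) {
  dialect <- match.arg(dialect)
  check_foci(foci)
  if (dialect == "csv") {
    utils::write.csv(
      foci[, c("study_id", "experiment_id", "domain", "x", "y", "z")],
      path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  blocks <- foci %>%
    group_by(.data$experiment_id) %>%
    group_split()
  txt <- purrr::map_chr(blocks, function(b) {
    paste(c(sprintf("// Study: %s", b$study_id[1]),
            sprintf("// Experiment: %s", b$experiment_id[1]),
            sprintf("// Domain: %s", b$domain[1]),
            sprintf("%g\t%g\t%g", b$x, b$y, b$z)),
          collapse = "\n")
  })
  writeLines(paste(txt, collapse = "\n\n"), path)
  invisible(path)
}

check_foci <- function(foci) {
  if (!is.data.frame(foci)) abort("`foci` must be a data frame")
  need <- c("study_id", "experiment_id", "x", "y", "z")
  miss <- setdiff(need, names(foci))
  if (length(miss))
    abort(sprintf("foci table is missing columns: %s",
                  paste(miss, collapse = ", ")))
  if (!nrow(foci)) abort("foci table is empty")
  co <- as.matrix(foci[, c("x", "y", "z")])
  if (!is.numeric(co) || any(!is.finite(co)))
    abort("foci coordinates must be finite numbers")
  if (!"domain" %in% names(foci)) foci$domain <- ""
  foci
}

#' Flag out-of-mask foci
#'
#' Adds an `in_mask` column and reports how many foci fall outside the mask.
#' Out-of-mask foci are never silently dropped: downstream kernel placement
#' excludes them, but they stay visible in the table for quality control.
#'
#' @param foci A foci tibble.
#' @param mask A `volume_map` whose mask defines the analysis volume.
#' @param quiet Suppress the QC message.
#' @return `foci` with a logical `in_mask` column.
#' @export
flag_foci <- function(foci, mask, quiet = FALSE) {
  foci <- check_foci(foci)
  foci$in_mask <- in_mask(mask, as.matrix(foci[, c("x", "y", "z")]))
  n_out <- sum(!foci$in_mask)
  if (n_out > 0 && !quiet)
    message(sprintf("%d of %d foci fall outside the mask and will be excluded from kernels",
                    n_out, nrow(foci)))
  foci
}
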