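#' Read a Sparky/POKY ".list" peak list
#'
#' Parses the whitespace-delimited peak-list export of Sparky/POKY: an optional
#' header line starting with "Assignment", then one line per peak with an
#' assignment label followed by K numeric chemical shifts. Peaks keep file
#' order and `peak_id` equals the data-line number.
#'
#' @param path Path to the `.list` file.
#' @param sigmas Per-dimension positional uncertainties (ppm); length fixes the
#'   expected dimensionality K.
#' @param nuclei Optional axis nucleus labels (length K).
#' @param extra_columns How to treat numeric columns beyond the first K after
#'   the label: `0` (default) requires exactly K numeric columns and raises a
#'   dimension error otherwise; `"drop"` ignores trailing columns (heights,
#'   volumes).
#' @param spectrum_id Optional spectrum identifier; defaults to the file name.
#' @return A [peak_list()].
#' @export
read_sparky_list <- function(path, sigmas, nuclei = NULL, extra_columns = 0,
                             spectrum_id = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  raw <- lines[keep]
  lineno <- which(keep)
  if (length(raw) && grepl("^Assignment\\b", raw[[1]], ignore.case = TRUE)) {
    raw <- raw[-1]; lineno <- lineno[-1]
  }
  if (!length(raw)) stopf("no peaks in %s", path)
  k <- length(sigmas)
  toks <- strsplit(raw, "[[:space:]]+")
  first_num <- suppressWarnings(vapply(toks, function(t) !is.na(as.numeric(t[[1]])),
                                       logical(1)))
  labels <- character(length(toks))
  vals <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    t <- toks[[i]]
    if (first_num[[i]]) {
      labels[[i]] <- NA_character_
    } else {
      labels[[i]] <- t[[1]]
      t <- t[-1]
    }
    v <- suppressWarnings(as.numeric(t))
    if (anyNA(v)) {
      stopf("parse error: non-numeric shift on line %d of %s", lineno[[i]], path)
    }
    vals[[i]] <- v
  }
  ncols <- lengths(vals)
  if (length(unique(ncols)) > 1L) {
    bad <- which(ncols != ncols[[1]])[[1]]
    stopf("format error: line %d of %s has %d shift columns but line %d has %d",
          lineno[[bad]], path, ncols[[bad]], lineno[[1]], ncols[[1]])
  }
  nc <- ncols[[1]]
  if (identical(extra_columns, "drop")) {
    if (nc < k) stopf("dimension error: %d shift columns but %d sigmas", nc, k)
    vals <- lapply(vals, function(v) v[seq_len(k)])
  } else if (nc != k) {
    stopf("dimension error: %d shift columns but %d sigmas supplied", nc, k)
  }
  shifts <- as.data.frame(do.call(rbind, vals))
  names(shifts) <- if (!is.null(nuclei)) nuclei else paste0("w", seq_len(k))
  peak_list(shifts, sigmas = sigmas, labels = labels, nuclei = nuclei,
            spectrum_id = spectrum_id %||% basename(path))
}

#' Read a delimited (CSV/TSV) peak table
#'
#' The delimiter is auto-detected between comma and tab from the header line.
#' A column named `label` is used for assignment labels if present.
#'
#' @param path Path to the file.
#' @param shift_columns Character vector naming the K shift columns, in axis
#'   order.
#' @inheritParams read_sparky_list
#' @return A [peak_list()].
#' @export
read_peak_table <- function(path, shift_columns, sigmas, nuclei = NULL,
                            spectrum_id = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1L, warn = FALSE)
  has_tab <- grepl("\t", header, fixed = TRUE)
  has_comma <- grepl(",", header, fixed = TRUE)
  if (has_tab == has_comma) {
    stopf("ambiguous delimiter in %s: expected exactly one of comma or tab in the header",
          path)
  }
  reader <- if (has_tab) readr::read_tsv else readr::read_csv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(shift_columns, names(df))
  if (length(missing)) {
    stopf("missing column(s) in %s: %s", path, paste(missing, collapse = ", "))
  }
  labels <- if ("label" %in% names(df)) as.character(df$label) else NULL
  peak_list(df[, shift_columns, drop = FALSE], sigmas = sigmas, labels = labels,
            nuclei = nuclei, spectrum_id = spectrum_id %||% basename(path))
}

#' Write or read a match report
#'
#' The report CSV has one row per reference peak with columns `reference_id`,
#' `reference_label`, `target_id` (the literal string `"NO_MATCH"` for
#' unmatched peaks), `target_label`, `posterior_probability`, `csp_ppm` (empty
#' for NO_MATCH), `csp_posterior_mass`, `csp_estimate_mean`, and
#' `csp_estimate_sd`. Values round-trip at full double precision.
#'
#' @param report A match-report tibble as produced by [tidy()] on a fit from
#'   [match_peaks()] (or [best_matches()]).
#' @param path Output path.
#' @return `write_match_report()` returns `path` invisibly;
#'   `read_match_report()` returns the report tibble.
#' @export
write_match_report <- function(report, path) {
  cols <- c("reference_id", "reference_label", "target_id", "target_label",
            "posterior_probability", "csp_ppm", "csp_posterior_mass",
            "csp_estimate_mean", "csp_estimate_sd")
  missing <- setdiff(cols, names(report))
  if (length(missing)) stopf("report is missing column(s): %s",
                             paste(missing, collapse = ", "))
  out <- report[, cols]
  out$target_id <- ifelse(is.na(report$target_id), "NO_MATCH",
                          as.character(report$target_id))
  tryCatch(readr::write_csv(out, path, na = ""),
           error = function(e) stopf("cannot write report to %s: %s",
                                     path, conditionMessage(e)))
  invisible(path)
}

#' @rdname write_match_report
#' @export
read_match_report <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          reference_id = readr::col_integer(),
                          reference_label = readr::col_character(),
                          target_id = readr::col_character(),
                          target_label = readr::col_character(),
                          .default = readr::col_double()))
  df$target_id <- suppressWarnings(
    ifelse(df$target_id == "NO_MATCH", NA_integer_, as.integer(df$target_id)))
  tibble::as_tibble(df)
}
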