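#' Build a peak list
#'
#' A peak list is a tibble with one row per cross-peak, a `peak_id` column
#' (1-based input order), an optional `label` column, and one numeric column of
#' chemical shifts (ppm) per spectral dimension. The per-dimension positional
#' uncertainties of the spectrum (ppm) and optional axis nucleus labels travel
#' as attributes so the list can be piped through dplyr verbs that preserve
#' attributes.
#'
#' @param shifts A data frame or matrix of chemical shifts, one column per
#'   dimension, in ppm.
#' @param sigmas Numeric vector of per-dimension positional uncertainties
#'   (ppm), one per dimension; all strictly positive.
#' @param labels Optional character vector of assignment labels (e.g.
#'   `"K27N-H"`), one per peak.
#' @param nuclei Optional character vector of axis nucleus labels, e.g.
#'   `c("H", "N")`; used to resolve combined-CSP scale factors and to validate
#'   that the reference and target spectra share axis order.
#' @param spectrum_id Optional identifier string for the spectrum.
#'
#' @return A `peak_list` tibble with columns `peak_id`, `label`, and one shift
#'   column per dimension.
#' @examples
#' peak_list(data.frame(H = c(8.1, 7.95), N = c(120.5, 118.2)),
#'           sigmas = c(0.0015, 0.015), nuclei = c("H", "N"))
#' @export
peak_list <- function(shifts, sigmas, labels = NULL, nuclei = NULL,
                      spectrum_id = NULL) {
  if (is.matrix(shifts)) shifts <- as.data.frame(shifts)
  if (!is.data.frame(shifts) || ncol(shifts) < 1L) {
    stopf("`shifts` must be a data frame or matrix with at least one column")
  }
  if (nrow(shifts) < 1L) stopf("no peaks: a peak list needs at least one peak")
  k <- ncol(shifts)
  if (!is.numeric(sigmas) || length(sigmas) != k) {
    stopf("dimension error: `sigmas` must have one entry per shift dimension (K = %d)", k)
  }
  if (any(!is.finite(sigmas)) || any(sigmas <= 0)) {
    stopf("`sigmas` must all be finite and > 0")
  }
  bad <- !vapply(shifts, is.numeric, logical(1))
  if (any(bad)) stopf("shift column(s) %s are not numeric",
                      paste(names(shifts)[bad], collapse = ", "))
  if (any(!is.finite(as.matrix(shifts)))) stopf("all shifts must be finite")
  if (!is.null(nuclei) && length(nuclei) != k) {
    stopf("dimension error: `nuclei` must have length K = %d", k)
  }
  if (is.null(labels)) labels <- rep(NA_character_, nrow(shifts))
  if (length(labels) != nrow(shifts)) stopf("one label per peak required")

  if (is.null(names(shifts)) || any(names(shifts) == "")) {
    names(shifts) <- paste0("w", seq_len(k))
  }
  out <- tibble::tibble(peak_id = seq_len(nrow(shifts)),
                        label = as.character(labels))
  out <- dplyr::bind_cols(out, tibble::as_tibble(shifts))
  structure(out,
            sigmas = as.numeric(sigmas),
            nuclei = if (is.null(nuclei)) NULL else as.character(nuclei),
            spectrum_id = spectrum_id,
            shift_cols = names(shifts),
            class = c("peak_list", class(out)))
}

#' Peak-list accessors
#'
#' `peak_sigmas()` returns the per-dimension uncertainties (ppm),
#' `peak_nuclei()` the axis nucleus labels (or `NULL`), `n_dims()` the
#' dimensionality K, and `shift_matrix()` the peaks-by-dimensions shift matrix.
#'
#' @param x A `peak_list`.
#' @return See each function's description.
#' @export
peak_sigmas <- function(x) attr(x, "sigmas", exact = TRUE)

#' @rdname peak_sigmas
#' @export
peak_nuclei <- function(x) attr(x, "nuclei", exact = TRUE)

#' @rdname peak_sigmas
#' @export
n_dims <- function(x) length(attr(x, "shift_cols", exact = TRUE))

#' @rdname peak_sigmas
#' @export
shift_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[, attr(x, "shift_cols", exact = TRUE), drop = FALSE])
  rownames(m) <- NULL
  m
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("# A peak list: %d peaks, %d dimensions\n", nrow(x), n_dims(x)))
  if (!is.null(attr(x, "spectrum_id"))) {
    cat(sprintf("# spectrum: %s\n", attr(x, "spectrum_id")))
  }
  nuc <- peak_nuclei(x)
  cat(sprintf("# sigmas (ppm): %s\n",
              paste(sprintf("%g", peak_sigmas(x)), collapse = ", ")))
  if (!is.null(nuc)) cat(sprintf("# nuclei: %s\n", paste(nuc, collapse = ", ")))
  NextMethod()
}

# shared precondition for every two-list operation: equal K and, where both
# provide axis nuclei, identical axis order
validate_peak_pair <- function(ref, tgt) {
  if (!inherits(ref, "peak_list") || !inherits(tgt, "peak_list")) {
    stopf("`ref` and `tgt` must be peak lists (see `peak_list()`)")
  }
  if (n_dims(ref) != n_dims(tgt)) {
    stopf("dimension error: reference has K = %d but target has K = %d",
          n_dims(ref), n_dims(tgt))
  }
  nr <- peak_nuclei(ref); nt <- peak_nuclei(tgt)
  if (!is.null(nr) && !is.null(nt) && !identical(nr, nt)) {
    stopf("axis nuclei differ between spectra: [%s] vs [%s]",
          paste(nr, collapse = ","), paste(nt, collapse = ","))
  }
  invisible(TRUE)
}
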