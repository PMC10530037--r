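#' Marker matrix container
#'
#' Holds biallelic SNP dosages (counted-allele copies, 0/1/2 or NA) for a set
#' of samples together with the physical marker map and, once quality control
#' has run, the per-marker missing-call rate recorded before imputation.
#' Markers are kept sorted by (chromosome, position).
#'
#' @param dosage numeric matrix, samples in rows, markers in columns; values
#'   in \{0, 1, 2\} or NA. Row and column names are required and unique.
#' @param chrom chromosome label per marker (recycled along columns).
#' @param pos 1-based physical position per marker, in base pairs.
#' @param pre_imputation_missing_rate optional per-marker fraction of missing
#'   calls recorded before imputation (NA until QC has run).
#'
#' @return An object of class \code{marker_matrix} with elements
#'   \code{dosage}, \code{map} (data.frame: marker, chrom, pos,
#'   pre_imputation_missing_rate).
#' @export
marker_matrix <- function(dosage, chrom, pos,
                          pre_imputation_missing_rate = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage must carry sample (row) and marker (column) names")
  if (anyDuplicated(rownames(dosage)))
    stop("duplicated sample identifiers")
  if (anyDuplicated(colnames(dosage)))
    stop("duplicated marker identifiers")
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok))
    stop("dosage values must be 0, 1, 2 or NA")
  p <- ncol(dosage)
  chrom <- rep_len(as.character(chrom), p)
  pos <- rep_len(as.numeric(pos), p)
  if (any(!is.finite(pos)) || any(pos < 1))
    stop("positions must be finite and >= 1")
  if (is.null(pre_imputation_missing_rate)) {
    pre_imputation_missing_rate <- rep(NA_real_, p)
  } else {
    pre_imputation_missing_rate <- rep_len(pre_imputation_missing_rate, p)
    bad <- !is.na(pre_imputation_missing_rate) &
      (pre_imputation_missing_rate < 0 | pre_imputation_missing_rate > 1)
    if (any(bad)) stop("pre_imputation_missing_rate must lie in [0, 1]")
  }
  map <- data.frame(marker = colnames(dosage), chrom = chrom, pos = pos,
                    pre_imputation_missing_rate = pre_imputation_missing_rate,
                    stringsAsFactors = FALSE)
  ord <- order(map$chrom, map$pos, map$marker)
  dosage <- dosage[, ord, drop = FALSE]
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  structure(list(dosage = dosage, map = map), class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d samples x %d markers on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$dosage)

#' Marker and sample counts of a marker matrix
#' @param m a \code{marker_matrix}.
#' @return Integer count.
#' @export
n_markers <- function(m) ncol(m$dosage)

#' @rdname n_markers
#' @export
n_samples <- function(m) nrow(m$dosage)

#' Subset a marker matrix
#'
#' @param m a \code{marker_matrix}.
#' @param samples,markers character vectors of identifiers (or logical/integer
#'   indices) to keep; NULL keeps all.
#' @return A \code{marker_matrix}.
#' @export
subset_markers <- function(m, samples = NULL, markers = NULL) {
  stopifnot(inherits(m, "marker_matrix"))
  d <- m$dosage
  map <- m$map
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, map$marker)
    d <- d[, markers, drop = FALSE]
    map <- map[markers, , drop = FALSE]
  }
  marker_matrix(d, map$chrom, map$pos, map$pre_imputation_missing_rate)
}

#' Minor allele frequency per marker
#'
#' Computed on non-missing calls; NA for markers with no usable calls.
#' With \code{exclude_het = TRUE} only homozygous calls enter the
#' frequency — the basis used by the quality filter, since heterozygotes
#' (artifacts in inbred panels) are converted to missing before any
#' downstream use.
#'
#' @param m a \code{marker_matrix} (or a bare dosage matrix).
#' @param exclude_het drop heterozygous calls from the computation.
#' @return Named numeric vector of MAF values in [0, 0.5].
#' @export
marker_maf <- function(m, exclude_het = FALSE) {
  d <- if (inherits(m, "marker_matrix")) m$dosage else m
  if (exclude_het) d[d == 1] <- NA
  f <- colMeans(d, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

call_rate <- function(m) {
  d <- if (inherits(m, "marker_matrix")) m$dosage else m
  colMeans(!is.na(d))
}

het_rate <- function(m) {
  d <- if (inherits(m, "marker_matrix")) m$dosage else m
  colSums(d == 1, na.rm = TRUE) / pmax(colSums(!is.na(d)), 1L)
}
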