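#' Marker quality-control thresholds
#'
#' Defaults follow the usual GBS panel filters: markers with a call rate
#' below 75\%, a heterozygosity rate above 10\% (rice accessions are inbred,
#' so excess heterozygosity flags paralogs or calling artifacts), or a minor
#' allele frequency below 5\% are discarded.
#'
#' @param min_call_rate minimum fraction of non-missing calls.
#' @param max_het_rate maximum fraction of heterozygous calls among
#'   non-missing calls.
#' @param min_maf minimum minor allele frequency (non-missing calls).
#' @return A list of class \code{filter_thresholds}.
#' @export
filter_thresholds <- function(min_call_rate = 0.75, max_het_rate = 0.10,
                              min_maf = 0.05) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            max_het_rate >= 0, max_het_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  structure(list(min_call_rate = min_call_rate, max_het_rate = max_het_rate,
                 min_maf = min_maf), class = "filter_thresholds")
}

#' Quality-filter markers
#'
#' Removes markers failing the call-rate, heterozygosity or MAF thresholds
#' (a marker failing several criteria is attributed to the first in that
#' order), then converts the surviving heterozygous calls to missing and
#' records the per-marker missing rate at that point as the pre-imputation
#' missing rate.
#'
#' @param m a \code{\link{marker_matrix}}.
#' @param thresholds a \code{\link{filter_thresholds}}.
#' @return A list with elements \code{matrix} (filtered
#'   \code{marker_matrix}) and \code{report} (class \code{filter_report}:
#'   counts plus per-marker disposition).
#' @export
filter_markers <- function(m, thresholds = filter_thresholds()) {
  stopifnot(inherits(m, "marker_matrix"))
  t <- thresholds
  cr <- call_rate(m)
  het <- het_rate(m)
  maf <- marker_maf(m, exclude_het = TRUE)
  fail_cr <- cr < t$min_call_rate
  fail_het <- !fail_cr & het > t$max_het_rate
  fail_maf <- !fail_cr & !fail_het &
    ((is.na(maf) & t$min_maf > 0) | (!is.na(maf) & maf < t$min_maf))
  disposition <- rep("pass", n_markers(m))
  disposition[fail_maf] <- "fail_maf"
  disposition[fail_het] <- "fail_het"
  disposition[fail_cr] <- "fail_call_rate"
  keep <- disposition == "pass"
  report <- structure(list(
    n_in = n_markers(m),
    n_fail_call_rate = sum(fail_cr),
    n_fail_het = sum(fail_het),
    n_fail_maf = sum(fail_maf),
    n_out = sum(keep),
    disposition = data.frame(marker = m$map$marker,
                             disposition = disposition,
                             call_rate = cr, het_rate = het, maf = maf,
                             stringsAsFactors = FALSE)),
    class = "filter_report")
  if (!any(keep)) stop("no markers survive the filters")
  d <- m$dosage[, keep, drop = FALSE]
  d[d == 1] <- NA_real_  # remaining heterozygotes to missing
  out <- marker_matrix(d, m$map$chrom[keep], m$map$pos[keep],
                       pre_imputation_missing_rate = colMeans(is.na(d)))
  list(matrix = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("filter_report: %d in, %d out ",
                     "(call rate: -%d, het: -%d, MAF: -%d)\n"),
              x$n_in, x$n_out, x$n_fail_call_rate, x$n_fail_het, x$n_fail_maf))
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a \code{filter_report}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report$disposition, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Naive per-marker imputation
#'
#' Fills missing calls with a per-marker summary of the non-missing calls:
#' the modal dosage or the rounded mean. This is deliberately simple
#' plumbing so that downstream kernels have complete data; haplotype-based
#' imputation is out of scope.
#'
#' @param m a \code{\link{marker_matrix}}.
#' @param method \code{"mode"} or \code{"mean_rounded"}.
#' @return A complete \code{marker_matrix}; the recorded pre-imputation
#'   missing rates are preserved unchanged.
#' @export
impute_naive <- function(m, method = c("mode", "mean_rounded")) {
  method <- match.arg(method)
  stopifnot(inherits(m, "marker_matrix"))
  d <- m$dosage
  nm <- colSums(!is.na(d))
  if (any(nm == 0))
    stop("all calls missing for marker(s): ",
         paste(utils::head(m$map$marker[nm == 0]), collapse = ", "))
  for (j in which(colSums(is.na(d)) > 0)) {
    v <- d[, j]
    obs <- v[!is.na(v)]
    fill <- if (method == "mode") {
      tab <- tabulate(obs + 1L, nbins = 3L)
      which.max(tab) - 1  # ties broken toward the lower dosage
    } else {
      round(mean(obs))
    }
    d[is.na(v), j] <- fill
  }
  pim <- m$map$pre_imputation_missing_rate
  if (all(is.na(pim))) pim <- colMeans(is.na(m$dosage))
  marker_matrix(d, m$map$chrom, m$map$pos, pim)
}

# Canonical signature of a dosage column under affine equivalence:
# standardized, sign-fixed, rounded. Two columns share a signature
# iff their squared correlation is 1 (constant columns are kept apart).
column_signature <- function(v) {
  mu <- mean(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-12) return("const")
  z <- (v - mu) / s
  i <- which(abs(z) > 1e-9)[1]
  if (z[i] < 0) z <- -z
  paste(round(z, 9), collapse = ",")
}

#' Prune markers in complete linkage disequilibrium
#'
#' Partitions markers into clusters of pairwise r-squared = 1 (identical or
#' perfectly (anti-)correlated dosage columns on the imputed matrix) and
#' keeps one representative per cluster: lowest pre-imputation missing rate,
#' then highest MAF, then smallest (chromosome, position).
#'
#' @param m a complete (imputed) \code{\link{marker_matrix}}.
#' @return A list with \code{matrix} (pruned) and \code{clusters}
#'   (data.frame: marker, cluster id, representative flag).
#' @export
prune_redundant <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  if (anyNA(m$dosage))
    stop("missing dosages present; run impute_naive first")
  d <- m$dosage
  p <- ncol(d)
  sig <- vapply(seq_len(p), function(j) column_signature(d[, j]), character(1))
  # constant columns never correlate with anything: singleton clusters
  const <- sig == "const"
  sig[const] <- paste0("const", seq_len(p)[const])
  cluster <- match(sig, unique(sig))
  pim <- m$map$pre_imputation_missing_rate
  pim[is.na(pim)] <- 0
  maf <- marker_maf(m)
  ord <- order(cluster, pim, -maf, m$map$chrom, m$map$pos, m$map$marker)
  rep_idx <- ord[!duplicated(cluster[ord])]
  keep <- sort(rep_idx)
  clusters <- data.frame(marker = m$map$marker, cluster = cluster,
                         representative = seq_len(p) %in% rep_idx,
                         stringsAsFactors = FALSE)
  list(matrix = subset_markers(m, markers = keep), clusters = clusters)
}

#' Marker-map spacing summary
#'
#' Gaps are computed only between adjacent markers on the same chromosome.
#'
#' @param m a \code{\link{marker_matrix}} (map sorted by construction).
#' @param gap_threshold_kb report the number of adjacent gaps exceeding
#'   this size (kb).
#' @return A list of class \code{map_summary}: \code{mean_adjacent_kb},
#'   \code{max_gap_kb}, \code{max_gap_chrom}, \code{n_gaps_over},
#'   \code{per_chromosome} (data.frame of gap counts).
#' @export
map_summary <- function(m, gap_threshold_kb = 500) {
  stopifnot(inherits(m, "marker_matrix"))
  map <- m$map
  gaps <- numeric(0)
  gap_chrom <- character(0)
  for (ch in unique(map$chrom)) {
    pos <- sort(map$pos[map$chrom == ch])
    if (length(pos) >= 2) {
      g <- diff(pos)
      gaps <- c(gaps, g)
      gap_chrom <- c(gap_chrom, rep(ch, length(g)))
    }
  }
  if (length(gaps) == 0) {
    return(structure(list(mean_adjacent_kb = NA_real_, max_gap_kb = NA_real_,
                          max_gap_chrom = NA_character_, n_gaps_over = 0L,
                          gap_threshold_kb = gap_threshold_kb,
                          per_chromosome = data.frame(chrom = character(0),
                                                      n_gaps_over = integer(0))),
                     class = "map_summary"))
  }
  kb <- gaps / 1000
  over <- kb > gap_threshold_kb
  per <- stats::aggregate(list(n_gaps_over = over),
                          by = list(chrom = gap_chrom), FUN = sum)
  structure(list(mean_adjacent_kb = mean(kb),
                 max_gap_kb = max(kb),
                 max_gap_chrom = gap_chrom[which.max(kb)],
                 n_gaps_over = sum(over),
                 gap_threshold_kb = gap_threshold_kb,
                 per_chromosome = per),
            class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  cat(sprintf("map_summary: mean adjacent distance %.1f kb, max gap %.1f kb (%s), %d gaps > %.0f kb\n",
              x$mean_adjacent_kb, x$max_gap_kb, x$max_gap_chrom,
              x$n_gaps_over, x$gap_threshold_kb))
  invisible(x)
}
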