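#' Read SNP genotypes into a marker matrix
#'
#' Supports biallelic VCF (via vcfR), HapMap text, and CSV dosage (rows =
#' samples, header = marker IDs, with a side map of chromosome/position).
#' Heterozygous calls are retained as dosage 1; conversion to missing happens
#' later in \code{\link{filter_markers}}. Records that are not biallelic are
#' dropped with a warning giving their count.
#'
#' @param path path to the genotype file.
#' @param format one of \code{"vcf"}, \code{"hapmap"}, \code{"csv_dosage"}.
#' @param map_path for \code{csv_dosage}: CSV with columns marker, chrom, pos.
#' @return A \code{\link{marker_matrix}}.
#' @export
read_genotypes <- function(path, format = c("vcf", "hapmap", "csv_dosage"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         vcf = read_genotypes_vcf(path),
         hapmap = read_genotypes_hapmap(path),
         csv_dosage = read_genotypes_csv(path, map_path))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1
  n_drop <- sum(!biallelic)
  if (n_drop > 0)
    warning(sprintf("dropped %d non-biallelic record(s)", n_drop))
  if (!any(biallelic)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  if (anyDuplicated(ids)) stop("duplicated marker identifiers in VCF")
  # allele dosage from GT strings; any separator, missing as "."
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- suppressWarnings(as.numeric(a1) + as.numeric(a2))
  dos <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
  marker_matrix(t(dos), chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]))
}

IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

read_genotypes_hapmap <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 12) stop("not a HapMap table: fewer than 12 columns")
  alleles <- strsplit(tab[[2]], "/", fixed = TRUE)
  biallelic <- lengths(alleles) == 2 &
    vapply(alleles, function(a) all(nchar(a) == 1), logical(1))
  n_drop <- sum(!biallelic)
  if (n_drop > 0)
    warning(sprintf("dropped %d non-biallelic record(s)", n_drop))
  if (!any(biallelic)) stop("no biallelic SNP records in ", path)
  tab <- tab[biallelic, , drop = FALSE]
  alleles <- alleles[biallelic]
  ids <- tab[[1]]
  if (anyDuplicated(ids)) stop("duplicated marker identifiers in HapMap file")
  calls <- as.matrix(tab[, -(1:11), drop = FALSE])
  samples <- colnames(calls)
  p <- nrow(calls)
  dos <- matrix(NA_real_, nrow = p, ncol = ncol(calls),
                dimnames = list(ids, samples))
  for (i in seq_len(p)) {
    a <- alleles[[i]][1]; b <- alleles[[i]][2]
    ci <- calls[i, ]
    # two-letter calls (AA/AG/..) or one-letter IUPAC
    ci[ci %in% c("NN", "N", "--", "..")] <- NA
    one <- !is.na(ci) & nchar(ci) == 1
    if (any(one)) {
      expand <- ifelse(ci[one] %in% names(IUPAC_HET),
                       IUPAC_HET[ci[one]], strrep(ci[one], 2))
      ci[one] <- expand
    }
    first <- substr(ci, 1, 1); second <- substr(ci, 2, 2)
    count_b <- (first == b) + (second == b)
    valid <- (first %in% c(a, b)) & (second %in% c(a, b))
    dos[i, ] <- ifelse(is.na(ci) | !valid, NA_real_, count_b)
  }
  marker_matrix(t(dos), chrom = as.character(tab[[3]]),
                pos = as.numeric(tab[[4]]))
}

read_genotypes_csv <- function(path, map_path) {
  if (is.null(map_path)) {
    map_path <- sub("\\.csv$", ".map.csv", path)
  }
  if (!file.exists(map_path))
    stop("marker map not found: ", map_path)
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  map <- utils::read.csv(map_path, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(map)))
    stop("map file must have columns marker, chrom, pos")
  d <- as.matrix(d)
  miss_map <- setdiff(colnames(d), map$marker)
  if (length(miss_map) > 0)
    stop("markers absent from map: ", paste(utils::head(miss_map), collapse = ", "))
  map <- map[match(colnames(d), map$marker), , drop = FALSE]
  pim <- if ("pre_imputation_missing_rate" %in% names(map))
    map$pre_imputation_missing_rate else NULL
  marker_matrix(d, map$chrom, map$pos, pim)
}

#' Write a marker matrix as CSV dosage plus a marker map
#'
#' The inverse of \code{read_genotypes(format = "csv_dosage")}: writes
#' \code{path} (samples x markers dosage CSV) and \code{map_path}
#' (marker/chrom/pos and, when recorded, the pre-imputation missing rate).
#'
#' @param m a \code{marker_matrix}.
#' @param path output CSV path for the dosage matrix.
#' @param map_path output CSV path for the map; defaults to
#'   \code{<path without .csv>.map.csv}.
#' @return Invisibly, \code{path}.
#' @export
write_genotypes <- function(m, path, map_path = NULL) {
  stopifnot(inherits(m, "marker_matrix"))
  if (is.null(map_path)) map_path <- sub("\\.csv$", ".map.csv", path)
  utils::write.csv(as.data.frame(m$dosage), path)
  utils::write.csv(m$map, map_path, row.names = FALSE)
  invisible(path)
}
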