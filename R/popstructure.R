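#' Simple-matching dissimilarity between individuals
#'
#' d(i, j) = fraction of markers at which the two genotype calls differ
#' (heterozygous dosage 1 mismatches both homozygotes). Computed via three
#' indicator cross-products, so it scales to panel-sized matrices.
#'
#' @param m a complete \code{\link{marker_matrix}}.
#' @return A symmetric n x n matrix of dissimilarities in [0, 1] with zero
#'   diagonal.
#' @export
simple_matching <- function(m) {
  d <- if (inherits(m, "marker_matrix")) m$dosage else as.matrix(m)
  if (anyNA(d)) stop("missing dosages present; run impute_naive first")
  p <- ncol(d)
  matches <- matrix(0, nrow(d), nrow(d))
  for (lev in c(0, 1, 2)) {
    ind <- (d == lev) * 1
    matches <- matches + tcrossprod(ind)
  }
  out <- 1 - matches / p
  out[out < 0] <- 0
  diag(out) <- 0
  dimnames(out) <- list(rownames(d), rownames(d))
  out
}

#' Unweighted neighbor-joining tree from a dissimilarity matrix
#'
#' Saitou-Nei neighbor joining (via ape), with negative branch lengths
#' clamped to zero, returned as a newick string.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @param path optional file to write the newick string to.
#' @return The newick string (invisibly also written to \code{path} when
#'   given); the \code{phylo} object is attached as attribute
#'   \code{"tree"}.
#' @export
nj_tree <- function(d, path = NULL) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 samples")
  if (max(abs(d - t(d))) > 1e-8) stop("dissimilarity matrix not symmetric")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  nwk <- ape::write.tree(tr)
  if (!is.null(path)) writeLines(nwk, path)
  attr(nwk, "tree") <- tr
  nwk
}

#' Assign individuals to genetic groups by PCA + k-means
#'
#' Principal components are computed on the centered dosage matrix; the
#' fewest components explaining at least \code{var_explained} of the
#' variance are retained and k-means (multiple seeded restarts, lowest
#' within-cluster sum of squares kept) clusters the scores. This is the
#' clustering step of discriminant analysis of principal components; the
#' discriminant projection itself is omitted as downstream use needs
#' assignments only.
#'
#' @param m a complete \code{\link{marker_matrix}}.
#' @param k number of groups (3 separates temperate, tropical and admixed
#'   japonica material).
#' @param var_explained minimum proportion of variance retained.
#' @param n_restarts k-means restarts.
#' @param seed RNG seed.
#' @return A list of class \code{group_assignment}: \code{groups} (named
#'   integer vector), \code{k}, \code{n_components},
#'   \code{var_retained}.
#' @export
assign_groups <- function(m, k = 3, var_explained = 0.90, n_restarts = 10,
                          seed = NULL) {
  d <- if (inherits(m, "marker_matrix")) m$dosage else as.matrix(m)
  if (anyNA(d)) stop("missing dosages present; run impute_naive first")
  if (k > nrow(d)) stop("k exceeds the number of samples")
  if (!is.null(seed)) set.seed(seed)
  pc <- stats::prcomp(d, center = TRUE, scale. = FALSE)
  cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- which(cumvar >= var_explained)[1]
  if (is.na(ncomp)) ncomp <- length(cumvar)
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  cl <- if (k == 1) {
    list(cluster = rep(1L, nrow(d)))
  } else {
    stats::kmeans(scores, centers = k, nstart = n_restarts)
  }
  groups <- stats::setNames(as.integer(cl$cluster), rownames(d))
  structure(list(groups = groups, k = k, n_components = ncomp,
                 var_retained = cumvar[ncomp]),
            class = "group_assignment")
}

#' Write a distance matrix as square tab-delimited text with an ID header
#' @param d symmetric matrix with sample IDs as dimnames.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
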