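#' Center a genotype matrix by marker
#'
#' Subtracts the column (marker) mean from each dosage column, producing the
#' centered matrix X used by the linear genomic kernel K = XX'/p.
#'
#' @param m a complete \code{\link{marker_matrix}} or a numeric matrix.
#' @return A list of class \code{centered_matrix}: \code{values} (n x p),
#'   \code{p}, \code{samples}.
#' @export
center_genotypes <- function(m) {
  d <- if (inherits(m, "marker_matrix")) m$dosage else as.matrix(m)
  if (anyNA(d))
    stop("missing dosages present; run impute_naive first")
  x <- sweep(d, 2, colMeans(d))
  structure(list(values = x, p = ncol(x), samples = rownames(x)),
            class = "centered_matrix")
}

new_kernel <- function(values, kind, bandwidth = NULL) {
  structure(list(values = values, kind = kind, bandwidth = bandwidth,
                 samples = rownames(values)),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix (%s%s): %d x %d\n", x$kind,
              if (!is.null(x$bandwidth)) sprintf(", h = %.4g", x$bandwidth) else "",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Linear genomic kernel K = XX'/p
#'
#' @param x a \code{centered_matrix} (see \code{\link{center_genotypes}})
#'   or a \code{marker_matrix} (centered internally).
#' @return A \code{kernel_matrix} of kind \code{"linear"}.
#' @export
linear_kernel <- function(x) {
  if (inherits(x, "marker_matrix")) x <- center_genotypes(x)
  stopifnot(inherits(x, "centered_matrix"), x$p >= 1)
  K <- tcrossprod(x$values) / x$p
  dimnames(K) <- list(x$samples, x$samples)
  new_kernel(K, "linear")
}

#' Pairwise squared Euclidean distances between genotype rows
#'
#' Invariant to column centering, so raw dosages and centered dosages give
#' identical distances.
#'
#' @param m a \code{marker_matrix}, \code{centered_matrix}, or matrix.
#' @return An n x n matrix of squared distances (zero diagonal).
#' @export
squared_distance_matrix <- function(m) {
  x <- if (inherits(m, "marker_matrix")) m$dosage
       else if (inherits(m, "centered_matrix")) m$values
       else as.matrix(m)
  if (anyNA(x)) stop("missing dosages present; run impute_naive first")
  q <- rowSums(x^2)
  d2 <- outer(q, q, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  dimnames(d2) <- list(rownames(x), rownames(x))
  d2
}

#' Gaussian (RKHS) kernel exp(-h d^2)
#'
#' @param d2 squared-distance matrix from
#'   \code{\link{squared_distance_matrix}}.
#' @param h bandwidth, > 0.
#' @return A \code{kernel_matrix} of kind \code{"gaussian"} with unit
#'   diagonal and the bandwidth recorded.
#' @export
gaussian_kernel <- function(d2, h) {
  if (!is.numeric(h) || length(h) != 1 || h <= 0)
    stop("bandwidth h must be a single positive number")
  K <- exp(-h * d2)
  diag(K) <- 1
  new_kernel(K, "gaussian", bandwidth = h)
}

#' Check kernel symmetry and positive semi-definiteness
#'
#' @param k a \code{kernel_matrix}.
#' @param tol relative eigenvalue tolerance.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_kernel <- function(k, tol = 1e-8) {
  K <- k$values
  if (max(abs(K - t(K))) > 1e-8) stop("kernel not symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  lower <- -tol * sum(diag(K)) / nrow(K)
  if (min(ev) < lower) stop("kernel not positive semi-definite")
  invisible(TRUE)
}

#' Write / read a kernel as tab-delimited text with an ID header
#' @param k a \code{kernel_matrix}.
#' @param path file path.
#' @return \code{write_kernel}: invisibly the path; \code{read_kernel}: a
#'   \code{kernel_matrix} (kind and bandwidth restored from a comment line).
#' @export
write_kernel <- function(k, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s bandwidth=%s", k$kind,
                     ifelse(is.null(k$bandwidth), "NA", format(k$bandwidth, digits = 17))),
             con)
  utils::write.table(k$values, con, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  header <- readLines(path, n = 1)
  kind <- sub(".*kind=(\\S+).*", "\\1", header)
  bw <- sub(".*bandwidth=(\\S+).*", "\\1", header)
  bw <- if (bw == "NA") NULL else as.numeric(bw)
  vals <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                      row.names = 1, skip = 1,
                                      check.names = FALSE))
  new_kernel(vals, kind, bw)
}

# Log marginal density of y under y = 1 mu + u + eps with
# u ~ N(0, s2u * K_h), eps ~ N(0, phi * s2u * I); mu integrated flat,
# s2u integrated under a scaled-inverse-chi-square(df0, S0) prior.
# Computed from the eigendecomposition of K_h.
log_marginal_y <- function(y, eK, phi, df0 = 5, S0 = NULL) {
  n <- length(y)
  d <- eK$values
  U <- eK$vectors
  if (is.null(S0)) S0 <- stats::var(y)
  w <- d + phi                      # eigenvalues of K + phi I
  if (any(w <= 0)) return(-Inf)
  z <- crossprod(U, y)[, 1]
  o <- crossprod(U, rep(1, n))[, 1]
  a11 <- sum(o^2 / w)               # 1' Sigma^-1 1
  a1y <- sum(o * z / w)
  ayy <- sum(z^2 / w)
  S <- ayy - a1y^2 / a11            # profiled quadratic form in mu
  if (S <= 0) return(-Inf)
  -0.5 * sum(log(w)) - 0.5 * log(a11) -
    0.5 * (n - 1 + df0) * log(S + df0 * S0)
}

#' Estimate the Gaussian-kernel bandwidth by posterior mode
#'
#' Maximizes, over a 2-D grid in (h, phi) refined by golden-section search in
#' h, the sum of the log marginal density of the phenotype under the
#' one-kernel RKHS model (intercept integrated flat, genetic variance
#' integrated under a conjugate scaled-inverse-chi-square prior; phi is the
#' residual-to-genetic variance ratio) and the log Gamma(shape, scale) prior
#' on h. The prior on phi is flat on log phi over the grid.
#'
#' @param d2 squared-distance matrix between genotypes.
#' @param y phenotype vector aligned to the rows of \code{d2}.
#' @param prior_shape,prior_scale Gamma prior on h (defaults 3.0, 1.5;
#'   prior mode (shape - 1) * scale = 3.0).
#' @param h_grid,phi_grid optional explicit grids; by default 50 log-spaced
#'   h values spanning [1e-4, 1e2] / median(d2) union the prior's effective
#'   support, and 21 log-spaced phi values in [1e-3, 1e3].
#' @param refine logical: golden-section refinement of h around the grid
#'   argmax (at the argmax phi).
#' @return A list of class \code{bandwidth_estimate}: \code{h}, \code{phi},
#'   \code{log_posterior_at_mode}, and the evaluated \code{trace}.
#' @export
estimate_bandwidth <- function(d2, y, prior_shape = 3.0, prior_scale = 1.5,
                               h_grid = NULL, phi_grid = NULL, refine = TRUE) {
  stopifnot(nrow(d2) == length(y))
  if (is.null(h_grid)) {
    h_bar <- 1 / stats::median(d2[upper.tri(d2)])
    lo <- min(1e-4 * h_bar,
              stats::qgamma(0.01, shape = prior_shape, scale = prior_scale))
    hi <- max(1e2 * h_bar,
              stats::qgamma(0.99, shape = prior_shape, scale = prior_scale))
    h_grid <- exp(seq(log(lo), log(hi), length.out = 50))
  }
  if (is.null(phi_grid)) phi_grid <- exp(seq(log(1e-3), log(1e3), length.out = 21))
  S0 <- stats::var(y)
  obj <- function(h, phi) {
    K <- exp(-h * d2); diag(K) <- 1
    eK <- eigen(K, symmetric = TRUE)
    log_marginal_y(y, eK, phi, S0 = S0) +
      stats::dgamma(h, shape = prior_shape, scale = prior_scale, log = TRUE)
  }
  trace <- expand.grid(h = h_grid, phi = phi_grid)
  trace$log_posterior <- NA_real_
  # one eigendecomposition per h, shared across the phi grid
  for (hi_ in seq_along(h_grid)) {
    h <- h_grid[hi_]
    K <- exp(-h * d2); diag(K) <- 1
    eK <- eigen(K, symmetric = TRUE)
    lp_h <- stats::dgamma(h, shape = prior_shape, scale = prior_scale, log = TRUE)
    rows <- which(trace$h == h)
    trace$log_posterior[rows] <- vapply(
      trace$phi[rows], function(phi) log_marginal_y(y, eK, phi, S0 = S0) + lp_h,
      numeric(1))
  }
  if (all(!is.finite(trace$log_posterior)))
    stop("log-posterior non-finite over the whole grid (h in [",
         format(min(h_grid)), ", ", format(max(h_grid)), "])")
  best <- which.max(trace$log_posterior)
  h_best <- trace$h[best]
  phi_best <- trace$phi[best]
  lp_best <- trace$log_posterior[best]
  if (refine) {
    i <- match(h_best, h_grid)
    lo <- h_grid[max(1, i - 1)]
    hi <- h_grid[min(length(h_grid), i + 1)]
    opt <- stats::optimize(function(h) obj(h, phi_best),
                           lower = lo, upper = hi, maximum = TRUE)
    if (opt$objective > lp_best) {
      h_best <- opt$maximum
      lp_best <- opt$objective
    }
  }
  structure(list(h = h_best, phi = phi_best,
                 log_posterior_at_mode = lp_best, trace = trace),
            class = "bandwidth_estimate")
}

#' @export
print.bandwidth_estimate <- function(x, ...) {
  cat(sprintf("bandwidth_estimate: h = %.4g (phi = %.4g, log posterior %.2f)\n",
              x$h, x$phi, x$log_posterior_at_mode))
  invisible(x)
}
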