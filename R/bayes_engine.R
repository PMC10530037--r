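#' Gibbs sampler configuration
#'
#' Defaults match common practice for kernel-based genomic prediction:
#' 35,000 iterations, a burn-in of 5,000 and thinning of 10, retaining
#' 3,000 draws. Variance components carry scaled-inverse-chi-square priors
#' with df0 degrees of freedom and scales set so that the prior mode
#' allocates a fraction R2 of the phenotypic variance to each genetic
#' component.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in discarded initial iterations.
#' @param thin keep one draw in \code{thin}.
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param seed master seed; chain c uses \code{seed + c - 1}.
#' @param df0 prior degrees of freedom for every variance component.
#' @param R2 prior proportion of phenotypic variance assigned to genetics.
#' @return A list of class \code{gibbs_config}.
#' @export
gibbs_config <- function(n_iter = 35000, burn_in = 5000, thin = 10,
                         n_chains = 1, seed = NULL, df0 = 5, R2 = 0.5) {
  stopifnot(n_iter > burn_in, thin >= 1, df0 > 0, R2 > 0, R2 < 1)
  retained <- floor((n_iter - burn_in) / thin)
  if (retained < 100)
    warning(sprintf("only %d retained draws; posterior summaries will be noisy",
                    retained))
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 n_chains = n_chains, seed = seed, df0 = df0, R2 = R2,
                 retained = retained),
            class = "gibbs_config")
}

# Eigendecomposition of a kernel for use in the sampler: checks PSD,
# drops eigenvalues below tol from the genetic-effect basis.
prep_eigen <- function(K, tol = 1e-10) {
  vals <- if (inherits(K, "kernel_matrix")) K$values else K
  e <- eigen(vals, symmetric = TRUE)
  lower <- -1e-8 * sum(diag(vals)) / nrow(vals)
  if (min(e$values) < lower)
    stop("kernel is not positive semi-definite")
  keep <- e$values > tol
  list(vectors = e$vectors[, keep, drop = FALSE], values = e$values[keep])
}

# Shared Gibbs core for the single- and multi-environment kernel models:
#   y_ij = mu_j + g0_i + u_ij + e_ij
#   g0 ~ N(0, s2u0 K0), u_.j ~ N(0, s2u_j K_j), e_.j ~ N(0, s2e_j I)
# Genetic effects are sampled in the eigenbasis of their kernels; missing
# phenotypes are handled by data augmentation.
gibbs_core <- function(Y, e0, e_env, include_env, cfg, chain_seed,
                       fixed = list(), pooled_residual = FALSE) {
  n <- nrow(Y); m <- ncol(Y)
  if (!is.null(chain_seed)) set.seed(chain_seed %% .Machine$integer.max)
  miss <- is.na(Y)
  env_names <- colnames(Y)
  U0 <- e0$vectors; d0 <- e0$values; q0 <- length(d0)
  tU0 <- t(U0)
  if (include_env) {
    Ue <- lapply(e_env, `[[`, "vectors")
    de <- lapply(e_env, `[[`, "values")
    tUe <- lapply(Ue, t)
  }
  vy <- stats::var(as.numeric(Y), na.rm = TRUE)
  if (!is.finite(vy) || vy == 0) vy <- 1
  df0 <- cfg$df0; R2 <- cfg$R2
  mdK0 <- mean(d0) * q0 / n              # ~ mean diagonal of K0
  n_gen <- if (include_env) 2 else 1
  Su0 <- vy * (R2 / n_gen) * (df0 + 2) / df0 / mdK0
  Se <- vy * (1 - R2) * (df0 + 2) / df0
  # initial values
  ybar <- colMeans(Y, na.rm = TRUE)
  ybar[is.na(ybar)] <- mean(Y, na.rm = TRUE)
  for (j in seq_len(m)) Y[miss[, j], j] <- ybar[j]
  mu <- ybar
  b0 <- rep(0, q0); g0 <- rep(0, n)
  u <- matrix(0, n, m)
  s2u0 <- if (!is.null(fixed$s2u0)) fixed$s2u0 else vy * R2 / n_gen / mdK0
  s2u_env <- if (!is.null(fixed$s2u_env)) rep_len(fixed$s2u_env, m)
             else rep(vy * R2 / n_gen, m)
  s2e <- if (!is.null(fixed$s2e)) rep_len(fixed$s2e, m)
         else rep(vy * (1 - R2), m)
  if (include_env) {
    Su_env <- vapply(seq_len(m), function(j) {
      md <- mean(de[[j]]) * length(de[[j]]) / n
      vy * (R2 / n_gen) * (df0 + 2) / df0 / md
    }, numeric(1))
  }
  keep_iters <- seq(cfg$burn_in + cfg$thin, cfg$n_iter, by = cfg$thin)
  n_keep <- length(keep_iters)
  draws_mu <- matrix(NA_real_, n_keep, m)
  draws_s2 <- matrix(NA_real_, n_keep, 1 + (if (include_env) m else 0) + m)
  draws_g0 <- matrix(NA_real_, n_keep, n)
  draws_u <- if (include_env) array(NA_real_, c(n_keep, n, m)) else NULL
  k <- 0L
  for (it in seq_len(cfg$n_iter)) {
    # data augmentation for masked records
    for (j in seq_len(m)) {
      mj <- miss[, j]
      if (any(mj))
        Y[mj, j] <- mu[j] + g0[mj] + u[mj, j] +
          stats::rnorm(sum(mj), 0, sqrt(s2e[j]))
    }
    # intercepts
    for (j in seq_len(m))
      mu[j] <- stats::rnorm(1, mean(Y[, j] - g0 - u[, j]), sqrt(s2e[j] / n))
    # main genetic effect in the eigenbasis of K0, pooling environments
    R <- Y - matrix(mu, n, m, byrow = TRUE) - u   # residuals without g0
    Z <- tU0 %*% R                                 # q0 x m
    prec <- rowSums(matrix(1 / s2e, q0, m, byrow = TRUE)) + 1 / (s2u0 * d0)
    mean_b0 <- (Z %*% (1 / s2e)) / prec
    b0 <- stats::rnorm(q0, mean_b0, sqrt(1 / prec))
    g0 <- drop(U0 %*% b0)
    # environment-specific effects
    if (include_env) {
      for (j in seq_len(m)) {
        z <- drop(tUe[[j]] %*% (Y[, j] - mu[j] - g0))
        pj <- 1 / s2e[j] + 1 / (s2u_env[j] * de[[j]])
        bj <- stats::rnorm(length(z), (z / s2e[j]) / pj, sqrt(1 / pj))
        u[, j] <- drop(Ue[[j]] %*% bj)
        if (is.null(fixed$s2u_env))
          s2u_env[j] <- (sum(bj^2 / de[[j]]) + df0 * Su_env[j]) /
            stats::rchisq(1, length(bj) + df0)
      }
    }
    # variance components
    if (is.null(fixed$s2u0))
      s2u0 <- (sum(b0^2 / d0) + df0 * Su0) / stats::rchisq(1, q0 + df0)
    if (is.null(fixed$s2e)) {
      E <- Y - matrix(mu, n, m, byrow = TRUE) - g0 - u
      if (pooled_residual) {
        s2e[] <- (sum(E^2) + df0 * Se) / stats::rchisq(1, n * m + df0)
      } else {
        for (j in seq_len(m))
          s2e[j] <- (sum(E[, j]^2) + df0 * Se) / stats::rchisq(1, n + df0)
      }
    }
    if (it > cfg$burn_in && (it - cfg$burn_in) %% cfg$thin == 0) {
      k <- k + 1L
      draws_mu[k, ] <- mu
      draws_s2[k, ] <- c(s2u0, if (include_env) s2u_env, s2e)
      draws_g0[k, ] <- g0
      if (include_env) draws_u[k, , ] <- u
    }
  }
  colnames(draws_mu) <- paste0("mu_", env_names)
  colnames(draws_s2) <- c("s2u0",
                          if (include_env) paste0("s2u_", env_names),
                          paste0("s2e_", env_names))
  list(mu = draws_mu, s2 = draws_s2, g0 = draws_g0, u = draws_u)
}

finish_samples <- function(chains, cfg, env_names, sample_ids, model) {
  structure(list(chains = chains, config = cfg, env = env_names,
                 samples = sample_ids, model = model),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("posterior_samples (%s): %d chain(s) x %d draws, %d genotypes, %d environment(s)\n",
              x$model, length(x$chains), nrow(x$chains[[1]]$g0),
              ncol(x$chains[[1]]$g0), length(x$env)))
  invisible(x)
}

#' Fit the single-environment kernel model by Gibbs sampling
#'
#' Model: y = 1 mu + u + e with u ~ N(0, s2u K) and e ~ N(0, s2e I). The
#' genetic effect is sampled in the eigenbasis of K (eigenvalues below
#' 1e-10 are dropped); variance components follow scaled-inverse-chi-square
#' full conditionals; missing phenotype entries (masked validation lines)
#' are imputed by data augmentation and therefore receive genomic
#' predictions through the kernel.
#'
#' @param y phenotype vector, names aligned to the kernel; NA = masked.
#' @param K a \code{kernel_matrix} (or plain PSD matrix).
#' @param cfg a \code{\link{gibbs_config}}.
#' @param fixed_variances optional list with any of \code{s2u0} (genetic)
#'   and \code{s2e} (residual) to hold fixed (for oracle checks).
#' @param eigen_K optional precomputed \code{prep_eigen(K)} (reused across
#'   cross-validation replicates).
#' @return A \code{posterior_samples} object.
#' @export
fit_single_env <- function(y, K, cfg = gibbs_config(),
                           fixed_variances = NULL, eigen_K = NULL) {
  Kv <- if (inherits(K, "kernel_matrix")) K$values else K
  stopifnot(length(y) == nrow(Kv))
  if (all(is.na(y))) stop("all phenotypes missing")
  if (is.null(eigen_K)) eigen_K <- prep_eigen(Kv)
  Y <- matrix(as.numeric(y), ncol = 1,
              dimnames = list(NULL, "env"))
  ids <- if (!is.null(names(y))) names(y) else rownames(Kv)
  fixed <- fixed_variances
  seeds <- chain_seeds(cfg)
  chains <- lapply(seq_len(cfg$n_chains), function(ch)
    gibbs_core(Y, eigen_K, NULL, include_env = FALSE, cfg = cfg,
               chain_seed = seeds[[ch]], fixed = fixed))
  finish_samples(chains, cfg, "env", ids, "single")
}

chain_seeds <- function(cfg) {
  if (is.null(cfg$seed)) rep(list(NULL), cfg$n_chains)
  else cfg$seed + seq_len(cfg$n_chains) - 1
}

#' Fit the multi-environment kernel model by Gibbs sampling
#'
#' Stacked model y = mu + u0 + uE + e: a main genetic effect shared across
#' environments (covariance s2u0 K0) plus environment-specific effects
#' (covariance s2u_j K_j), per-environment intercepts and, by default,
#' per-environment residual variances. With a single environment and
#' \code{include_env_effect = FALSE} this is exactly the single-environment
#' sampler.
#'
#' @param Y n x m phenotype matrix, one column per environment (condition);
#'   NA entries are masked and predicted. Column names label environments.
#' @param K0 main-effect kernel over the n genotypes.
#' @param K_env optional list of m per-environment kernels (default: K0).
#' @param cfg a \code{\link{gibbs_config}}.
#' @param fixed_variances optional list with any of \code{s2u0},
#'   \code{s2u_env}, \code{s2e} held fixed.
#' @param pooled_residual single residual variance across environments.
#' @param include_env_effect set FALSE to drop uE (nested single-env model).
#' @param eigen_K0,eigen_env optional precomputed eigendecompositions.
#' @return A \code{posterior_samples} object.
#' @export
fit_multi_env <- function(Y, K0, K_env = NULL, cfg = gibbs_config(),
                          fixed_variances = NULL, pooled_residual = FALSE,
                          include_env_effect = TRUE,
                          eigen_K0 = NULL, eigen_env = NULL) {
  Y <- as.matrix(Y)
  K0v <- if (inherits(K0, "kernel_matrix")) K0$values else K0
  stopifnot(nrow(Y) == nrow(K0v))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("env", seq_len(ncol(Y)))
  m <- ncol(Y)
  obs_per_env <- colSums(!is.na(Y))
  if (any(obs_per_env < 10 & obs_per_env > 0))
    warning("environment(s) with fewer than 10 observed lines: ",
            paste(colnames(Y)[obs_per_env < 10 & obs_per_env > 0], collapse = ", "))
  if (is.null(eigen_K0)) eigen_K0 <- prep_eigen(K0v)
  if (include_env_effect) {
    if (is.null(eigen_env)) {
      eigen_env <- if (is.null(K_env)) rep(list(eigen_K0), m)
      else lapply(K_env, function(k)
        prep_eigen(if (inherits(k, "kernel_matrix")) k$values else k))
    }
    stopifnot(length(eigen_env) == m)
  }
  ids <- if (!is.null(rownames(Y))) rownames(Y) else rownames(K0v)
  seeds <- chain_seeds(cfg)
  chains <- lapply(seq_len(cfg$n_chains), function(ch)
    gibbs_core(Y, eigen_K0, eigen_env, include_env = include_env_effect,
               cfg = cfg, chain_seed = seeds[[ch]], fixed = fixed_variances,
               pooled_residual = pooled_residual))
  finish_samples(chains, cfg, colnames(Y),
                 ids, if (include_env_effect) "multi" else "single")
}

#' Extract genomic estimated breeding values
#'
#' Posterior-mean genetic values (main plus environment-specific effect)
#' and predicted performances (intercept + genetic value) per genotype and
#' environment, pooling chains. Masked lines receive predictions through
#' the kernel covariance.
#'
#' @param samples a \code{posterior_samples} object.
#' @param genotypes optional subset of genotype identifiers.
#' @return data.frame: genotype, env, gebv, predicted.
#' @export
extract_gebv <- function(samples, genotypes = NULL) {
  stopifnot(inherits(samples, "posterior_samples"))
  ids <- samples$samples
  if (is.null(ids)) ids <- as.character(seq_len(ncol(samples$chains[[1]]$g0)))
  if (!is.null(genotypes)) {
    missing_ids <- setdiff(genotypes, ids)
    if (length(missing_ids) > 0)
      stop("genotype(s) absent from the fitted kernel: ",
           paste(utils::head(missing_ids), collapse = ", "))
  }
  g0 <- Reduce(rbind, lapply(samples$chains, `[[`, "g0"))
  mu <- Reduce(rbind, lapply(samples$chains, `[[`, "mu"))
  out <- do.call(rbind, lapply(seq_along(samples$env), function(j) {
    uj <- if (!is.null(samples$chains[[1]]$u))
      Reduce(rbind, lapply(samples$chains, function(ch) ch$u[, , j]))
    else 0
    gj <- colMeans(g0 + uj)
    data.frame(genotype = ids, env = samples$env[j], gebv = gj,
               predicted = mean(mu[, j]) + gj, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(genotypes)) out <- out[out$genotype %in% genotypes, , drop = FALSE]
  out
}

#' Scalar parameter draws from a fit
#'
#' @param samples a \code{posterior_samples} object.
#' @return A list (one element per chain) of draw matrices with columns for
#'   the intercept(s) and variance components.
#' @export
scalar_draws <- function(samples) {
  lapply(samples$chains, function(ch) cbind(ch$mu, ch$s2))
}

#' Gelman-Rubin potential scale reduction factor (split-chain)
#'
#' @param chains a \code{posterior_samples} object with >= 2 chains, or a
#'   list of draw matrices with identical column sets.
#' @return Named numeric vector of PSRF values; NA (with a warning) for
#'   parameters with zero within-chain variance.
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "posterior_samples")) chains <- scalar_draws(chains)
  stopifnot(is.list(chains), length(chains) >= 2)
  len <- unique(vapply(chains, nrow, integer(1)))
  if (length(len) != 1) stop("chains must have equal retained lengths")
  half <- floor(len / 2)
  split_chains <- unlist(lapply(chains, function(m)
    list(m[seq_len(half), , drop = FALSE],
         m[(len - half + 1):len, , drop = FALSE])), recursive = FALSE)
  nc <- length(split_chains)
  params <- colnames(chains[[1]])
  psrf <- vapply(seq_along(params), function(p) {
    xs <- vapply(split_chains, function(m) mean(m[, p]), numeric(1))
    vs <- vapply(split_chains, function(m) stats::var(m[, p]), numeric(1))
    W <- mean(vs)
    if (W <= .Machine$double.eps) return(NA_real_)
    B <- half * stats::var(xs)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
  names(psrf) <- params
  if (anyNA(psrf))
    warning("PSRF undefined (zero within-chain variance) for: ",
            paste(params[is.na(psrf)], collapse = ", "))
  psrf
}
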