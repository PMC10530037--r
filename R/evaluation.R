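#' CV1 cross-validation partitions
#'
#' Random 80/20 train/validation splits, reproducible under a seed, and
#' intended to be reused across every model x method x trait combination so
#' that comparisons are paired per partition. The training-set size is
#' \code{floor(fraction * n)}.
#'
#' @param n number of genotypes.
#' @param fraction training fraction (default 0.8).
#' @param n_reps number of random partitions (default 100).
#' @param seed RNG seed.
#' @return A list of class \code{cv_partitions}: \code{reps} (list of lists
#'   with integer \code{train}/\code{validation}), plus the settings.
#' @export
make_partitions <- function(n, fraction = 0.8, n_reps = 100, seed = NULL) {
  if (n < 10) stop("need at least 10 genotypes")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n_train <- floor(fraction * n)
  reps <- lapply(seq_len(n_reps), function(r) {
    train <- sort(sample.int(n, n_train))
    list(train = train, validation = setdiff(seq_len(n), train))
  })
  structure(list(reps = reps, n = n, fraction = fraction,
                 n_reps = n_reps, seed = seed),
            class = "cv_partitions")
}

#' Serialize / restore CV partitions as JSON
#' @param parts a \code{cv_partitions} object.
#' @param path file path.
#' @param ids optional sample identifiers; by default integer indices are
#'   stored.
#' @return \code{write_partitions}: invisibly the path;
#'   \code{read_partitions}: a \code{cv_partitions} object.
#' @export
write_partitions <- function(parts, path, ids = NULL) {
  reps <- lapply(parts$reps, function(r) {
    if (is.null(ids)) r else list(train = ids[r$train],
                                  validation = ids[r$validation])
  })
  jsonlite::write_json(list(n = parts$n, fraction = parts$fraction,
                            n_reps = parts$n_reps, seed = parts$seed,
                            ids = ids, reps = reps),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_partitions
#' @export
read_partitions <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  reps <- lapply(seq_len(x$n_reps), function(i) {
    tr <- x$reps$train[[i]]; va <- x$reps$validation[[i]]
    if (!is.null(x$ids)) {
      tr <- match(tr, x$ids); va <- match(va, x$ids)
    }
    list(train = as.integer(tr), validation = as.integer(va))
  })
  structure(list(reps = reps, n = x$n, fraction = x$fraction,
                 n_reps = x$n_reps, seed = x$seed),
            class = "cv_partitions")
}

#' Run CV1 cross-validation of genomic predictive ability
#'
#' For each partition the validation genotypes are masked in every
#' environment, the model is fitted, masked lines are predicted through the
#' kernel, and the predictive ability is the Pearson correlation between
#' their predictions and observed values, per condition. The kernel
#' eigendecomposition is computed once and reused across partitions.
#'
#' @param K a \code{kernel_matrix} over all genotypes (already linear or
#'   Gaussian, fixing the method).
#' @param pheno named list (or n x m matrix) of per-condition phenotype
#'   vectors aligned to the kernel (typically adjusted means).
#' @param partitions a \code{cv_partitions} object with \code{n} equal to
#'   the kernel dimension.
#' @param model \code{"single"} (per-condition fits) or \code{"multi"}
#'   (shared main effect + condition-specific effects).
#' @param cfg a \code{\link{gibbs_config}}; the per-partition chain seed is
#'   derived from \code{cfg$seed} and the partition index.
#' @param method label recorded in the result (e.g. "GBLUP", "RKHS").
#' @param trait label recorded in the result.
#' @return data.frame of class \code{cv_result}: rep, trait, condition,
#'   method, model, r (NA when undefined, with a warning).
#' @export
run_cv <- function(K, pheno, partitions, model = c("single", "multi"),
                   cfg = gibbs_config(), method = "GBLUP", trait = "trait") {
  model <- match.arg(model)
  Y <- if (is.matrix(pheno)) pheno else do.call(cbind, pheno)
  Kv <- if (inherits(K, "kernel_matrix")) K$values else K
  stopifnot(nrow(Y) == nrow(Kv), partitions$n == nrow(Kv))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("env", seq_len(ncol(Y)))
  eK <- prep_eigen(Kv)
  base_seed <- if (is.null(cfg$seed)) 0 else cfg$seed
  out <- list()
  for (r in seq_along(partitions$reps)) {
    val <- partitions$reps[[r]]$validation
    cfg_r <- cfg
    cfg_r$seed <- base_seed + 1000L * r
    Ymask <- Y
    Ymask[val, ] <- NA
    if (model == "multi") {
      fit <- fit_multi_env(Ymask, Kv, cfg = cfg_r, eigen_K0 = eK,
                           eigen_env = rep(list(eK), ncol(Y)))
      gebv <- extract_gebv(fit)
      for (j in colnames(Y)) {
        pred <- gebv$predicted[gebv$env == j][val]
        out[[length(out) + 1L]] <-
          data.frame(rep = r, trait = trait, condition = j, method = method,
                     model = model, r = safe_cor(pred, Y[val, j]))
      }
    } else {
      for (j in colnames(Y)) {
        fit <- fit_single_env(Ymask[, j], Kv, cfg = cfg_r, eigen_K = eK)
        gebv <- extract_gebv(fit)
        pred <- gebv$predicted[val]
        out[[length(out) + 1L]] <-
          data.frame(rep = r, trait = trait, condition = j, method = method,
                     model = model, r = safe_cor(pred, Y[val, j]))
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("cv_result", "data.frame")
  res
}

safe_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("predictive ability undefined (zero variance or too few pairs)")
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])
}

#' Summarize a CV result: mean and standard error per cell
#'
#' Undefined-r replicates are excluded from the cell mean and their count
#' reported.
#'
#' @param cv a \code{cv_result}.
#' @return data.frame: trait, condition, method, model, mean_pa, se_pa,
#'   n_reps, n_undefined.
#' @export
summarize_cv <- function(cv) {
  keys <- c("trait", "condition", "method", "model")
  agg <- do.call(rbind, lapply(split(cv, cv[keys], drop = TRUE), function(d) {
    r <- d$r[!is.na(d$r)]
    data.frame(d[1, keys, drop = FALSE],
               mean_pa = mean(r),
               se_pa = stats::sd(r) / sqrt(length(r)),
               n_reps = nrow(d), n_undefined = sum(is.na(d$r)))
  }))
  rownames(agg) <- NULL
  agg
}

#' Fisher Z transformation of a correlation
#'
#' Z = 0.5 * (ln(1 + r) - ln(1 - r)); the inverse is tanh.
#'
#' @param r correlation(s) with |r| < 1.
#' @param clamp if TRUE, values with |r| >= 1 are clamped to
#'   1 - 1e-12 in absolute value instead of raising an error.
#' @return Z value(s).
#' @export
fisher_z <- function(r, clamp = FALSE) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    if (!clamp) stop("|r| >= 1: Fisher Z undefined")
    r <- sign(r) * pmin(abs(r), 1 - 1e-12)
  }
  0.5 * (log(1 + r) - log(1 - r))
}

#' @rdname fisher_z
#' @param z Fisher Z value(s).
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' ANOVA on Fisher-Z-transformed predictive abilities
#'
#' Fixed-effects ANOVA (type-II sums of squares) of Z on the design factors
#' present with at least two levels among trait, condition, method and
#' model, with the partition index as a blocking factor (the same
#' partitions are reused across cells, so replicates are paired).
#'
#' @param cv a \code{cv_result} (rows with NA r are dropped).
#' @param factors candidate factor columns.
#' @return A list: \code{anova} (car::Anova table), \code{model} (the lm),
#'   \code{z} (the transformed table).
#' @export
anova_pa <- function(cv, factors = c("trait", "condition", "method", "model")) {
  d <- cv[!is.na(cv$r), , drop = FALSE]
  d$Z <- fisher_z(d$r, clamp = TRUE)
  d$partition <- factor(d$rep)
  used <- character(0)
  for (f in factors) {
    if (f %in% names(d) && length(unique(d[[f]])) >= 2) {
      d[[f]] <- factor(d[[f]])
      used <- c(used, f)
    }
  }
  if (length(used) == 0) stop("no factor with >= 2 levels")
  terms <- c(used, if (length(unique(d$partition)) >= 2) "partition")
  form <- stats::reformulate(terms, response = "Z")
  fit <- stats::lm(form, data = d)
  tab <- if (stats::sd(d$Z) < 1e-12) {
    # degenerate: no variation at all, every sum of squares is zero
    out <- data.frame(`Sum Sq` = rep(0, length(terms) + 1),
                      Df = rep(NA_integer_, length(terms) + 1),
                      `F value` = c(rep(0, length(terms)), NA),
                      `Pr(>F)` = rep(NA_real_, length(terms) + 1),
                      row.names = c(terms, "Residuals"), check.names = FALSE)
    class(out) <- c("anova", "data.frame")
    out
  } else {
    car::Anova(fit, type = 2)
  }
  list(anova = tab, model = fit, z = d)
}

#' Agreement between prediction methods
#'
#' Spearman rank correlation between the predicted performances of two
#' GEBV tables (e.g. RKHS vs GBLUP), per environment.
#'
#' @param g1,g2 GEBV tables from \code{\link{extract_gebv}}.
#' @return data.frame: env, rho, n.
#' @export
method_agreement <- function(g1, g2) {
  mrg <- merge(g1, g2, by = c("genotype", "env"))
  if (nrow(mrg) < 3) stop("fewer than 3 common genotypes")
  out <- do.call(rbind, lapply(split(mrg, mrg$env), function(d)
    data.frame(env = d$env[1],
               rho = stats::cor(d$predicted.x, d$predicted.y,
                                method = "spearman"),
               n = nrow(d))))
  rownames(out) <- NULL
  out
}
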