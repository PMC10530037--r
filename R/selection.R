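#' Specification of the representative validation subset
#'
#' The subset spans the predicted variability of the key salt-tolerance
#' traits: lines ranked in the lowest decile, the top decile, and lines of
#' average performance, in proportions 20\% / 20\% / 60\% of the subset.
#'
#' @param traits traits entering the consensus ranking.
#' @param methods prediction methods whose GEBVs are combined.
#' @param n_sel subset size (41 fits three replicated hydroponic tanks).
#' @param q tail decile defining the bottom/top strata.
#' @param proportions bottom/top/middle composition (sums to 1).
#' @return A list of class \code{selection_spec}.
#' @export
selection_spec <- function(traits = c("Na", "K", "Na_K", "iSHOOT", "iROOT"),
                           methods = c("GBLUP", "RKHS"),
                           n_sel = 41, q = 0.10,
                           proportions = c(bottom = 0.20, top = 0.20,
                                           middle = 0.60)) {
  stopifnot(abs(sum(proportions) - 1) < 1e-8, q > 0, q < 0.5, n_sel >= 1)
  structure(list(traits = traits, methods = methods, n_sel = n_sel, q = q,
                 proportions = proportions),
            class = "selection_spec")
}

#' Train on a reference panel and predict a breeding population
#'
#' Builds the kernel on the union of reference-panel (RP) and
#' breeding-population (BP) genotypes restricted to their common markers,
#' masks the BP phenotypes, fits the requested model and returns GEBVs for
#' the BP lines.
#'
#' @param rp_genotypes,bp_genotypes \code{marker_matrix} objects genotyped
#'   on (largely) the same markers; the intersection is taken and logged.
#' @param rp_phenotypes for \code{model = "single"}: a named phenotype
#'   vector over RP samples; for \code{"multi"}: a named list/matrix of
#'   per-condition vectors.
#' @param method \code{"GBLUP"} (linear kernel) or \code{"RKHS"} (Gaussian
#'   kernel, bandwidth estimated on the RP phenotypes unless \code{h} is
#'   given).
#' @param model \code{"single"} or \code{"multi"}.
#' @param cfg a \code{\link{gibbs_config}}.
#' @param h optional fixed Gaussian bandwidth.
#' @return data.frame of GEBVs (\code{\link{extract_gebv}}) for the BP
#'   lines, with the method recorded.
#' @export
predict_population <- function(rp_genotypes, rp_phenotypes, bp_genotypes,
                               method = c("GBLUP", "RKHS"),
                               model = c("single", "multi"),
                               cfg = gibbs_config(), h = NULL) {
  method <- match.arg(method)
  model <- match.arg(model)
  common <- intersect(rp_genotypes$map$marker, bp_genotypes$map$marker)
  frac_rp <- length(common) / n_markers(rp_genotypes)
  frac_bp <- length(common) / n_markers(bp_genotypes)
  if (frac_rp < 0.5 || frac_bp < 0.5)
    stop(sprintf("marker intersection too small (%.0f%% of RP, %.0f%% of BP)",
                 100 * frac_rp, 100 * frac_bp))
  message(sprintf("using %d markers common to RP and BP", length(common)))
  rp <- subset_markers(rp_genotypes, markers = common)
  bp <- subset_markers(bp_genotypes, markers = common)
  dos <- rbind(rp$dosage, bp$dosage)
  all_ids <- rownames(dos)
  mm <- marker_matrix(dos, rp$map$chrom, rp$map$pos)
  Ymat <- if (is.matrix(rp_phenotypes) || is.data.frame(rp_phenotypes))
    as.matrix(rp_phenotypes)
  else if (is.list(rp_phenotypes)) do.call(cbind, rp_phenotypes)
  else matrix(rp_phenotypes, ncol = 1,
              dimnames = list(names(rp_phenotypes), "env"))
  Y <- matrix(NA_real_, length(all_ids), ncol(Ymat),
              dimnames = list(all_ids, colnames(Ymat)))
  Y[rownames(Ymat), ] <- Ymat
  if (method == "GBLUP") {
    K <- linear_kernel(center_genotypes(mm))
  } else {
    d2 <- squared_distance_matrix(mm)
    if (is.null(h)) {
      rp_idx <- match(rownames(Ymat), all_ids)
      y_for_h <- rowMeans(Ymat, na.rm = TRUE)
      h <- estimate_bandwidth(d2[rp_idx, rp_idx], y_for_h)$h
    }
    K <- gaussian_kernel(d2, h)
  }
  if (model == "multi" && ncol(Y) > 1) {
    fit <- fit_multi_env(Y, K, cfg = cfg)
    gebv <- extract_gebv(fit, genotypes = rownames(bp$dosage))
  } else {
    gebv <- do.call(rbind, lapply(colnames(Y), function(j) {
      fit <- fit_single_env(stats::setNames(Y[, j], all_ids), K, cfg = cfg)
      g <- extract_gebv(fit, genotypes = rownames(bp$dosage))
      g$env <- j
      g
    }))
  }
  gebv$method <- method
  gebv
}

percentile_rank <- function(x) {
  (rank(x, ties.method = "average") - 0.5) / length(x)
}

# evenly spaced picks along a sorted stratum (maximum-spread rule)
spread_pick <- function(ordered_ids, k) {
  ns <- length(ordered_ids)
  if (k >= ns) return(ordered_ids)
  idx <- unique(round(seq(1, ns, length.out = k)))
  i <- 1L
  while (length(idx) < k) {       # fill rounding collisions deterministically
    cand <- setdiff(seq_len(ns), idx)
    idx <- c(idx, cand[1])
    i <- i + 1L
  }
  ordered_ids[sort(idx[seq_len(k)])]
}

#' Select a representative validation subset
#'
#' Per trait x method, lines are percentile-ranked on predicted
#' performance; the consensus score of a line is its mean percentile rank.
#' Lines with consensus below q form the bottom stratum, above 1 - q the
#' top stratum, the rest the middle. Quotas are floor(0.20 n_sel) bottom,
#' floor(0.20 n_sel) top, remainder middle (8/8/25 at n_sel = 41); within
#' each stratum lines are taken at evenly spaced quantiles of the consensus
#' score (maximum spread), ties broken by line identifier.
#'
#' @param gebv data.frame with columns genotype, trait, method, predicted
#'   (e.g. stacked \code{\link{predict_population}} outputs).
#' @param spec a \code{\link{selection_spec}}.
#' @return A list of class \code{selection_result}: \code{selected}
#'   (data.frame: genotype, stratum, consensus), \code{composition} counts,
#'   \code{consensus} for the whole population.
#' @export
select_validation_set <- function(gebv, spec = selection_spec()) {
  need <- expand.grid(trait = spec$traits, method = spec$methods,
                      stringsAsFactors = FALSE)
  have <- unique(gebv[, c("trait", "method")])
  missing_cells <- !apply(need, 1, function(r)
    any(have$trait == r["trait"] & have$method == r["method"]))
  if (any(missing_cells))
    stop("GEBV table lacks trait x method cell(s): ",
         paste(apply(need[missing_cells, ], 1, paste, collapse = "/"),
               collapse = ", "))
  cells <- gebv[gebv$trait %in% spec$traits & gebv$method %in% spec$methods, ]
  ranks <- do.call(rbind, lapply(split(cells, list(cells$trait, cells$method),
                                       drop = TRUE), function(d) {
    data.frame(genotype = d$genotype, pr = percentile_rank(d$predicted))
  }))
  cons <- stats::aggregate(pr ~ genotype, data = ranks, FUN = mean)
  names(cons)[2] <- "consensus"
  cons <- cons[order(cons$consensus, cons$genotype), , drop = FALSE]
  n_pop <- nrow(cons)
  n_sel <- min(spec$n_sel, n_pop)
  cons$stratum <- ifelse(cons$consensus < spec$q, "bottom",
                         ifelse(cons$consensus > 1 - spec$q, "top", "middle"))
  quota <- c(bottom = floor(spec$proportions[["bottom"]] * n_sel),
             top = floor(spec$proportions[["top"]] * n_sel))
  quota <- c(quota, middle = n_sel - sum(quota))
  sizes <- table(factor(cons$stratum, levels = names(quota)))
  for (s in c("bottom", "top")) {
    deficit <- quota[[s]] - sizes[[s]]
    if (deficit > 0) {
      warning(sprintf("stratum '%s' smaller than its quota; %d line(s) reallocated to middle",
                      s, deficit))
      quota[[s]] <- sizes[[s]]
      quota[["middle"]] <- quota[["middle"]] + deficit
    }
  }
  picks <- lapply(names(quota), function(s) {
    ids <- cons$genotype[cons$stratum == s]   # already consensus-ordered
    spread_pick(ids, quota[[s]])
  })
  sel <- cons[cons$genotype %in% unlist(picks), , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(selected = sel[, c("genotype", "stratum", "consensus")],
                 composition = quota,
                 consensus = cons[, c("genotype", "consensus", "stratum")]),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d lines (bottom %d / top %d / middle %d)\n",
              nrow(x$selected), x$composition[["bottom"]],
              x$composition[["top"]], x$composition[["middle"]]))
  invisible(x)
}

#' Write a selection result as CSV
#' @param res a \code{selection_result}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_selection <- function(res, path) {
  utils::write.csv(res$selected, path, row.names = FALSE)
  invisible(path)
}
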