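#' Configuration of the synthetic rice-panel generator
#'
#' The defaults emulate the structure of a temperate japonica panel
#' evaluated under control and mild salinity stress: about 600 individuals
#' over 12 chromosomes, two genetic subgroups (temperate / tropical) plus a
#' 37\% admixed fraction, ~17,000 markers, trait-specific
#' genotype-by-condition correlations and repeatabilities inside the ranges
#' such panels show, and ion-mass-fraction-like traits measured in the salt
#' condition only.
#'
#' @param n_individuals,n_markers,n_chromosomes panel dimensions.
#' @param Fst subpopulation differentiation of the Balding-Nichols model.
#' @param admixture fraction of admixed individuals.
#' @param n_causal causal markers per trait.
#' @param traits data.frame (trait, h2, rho_g, salt_only) defining the
#'   phenotypes: target per-condition heritability, target cross-condition
#'   genetic correlation, and whether the trait exists only under salt.
#' @param mu intercept per condition (named: control, salt).
#' @param rep_frac,tank_frac fractions of the non-genetic variance assigned
#'   to the replicate and tank random effects (the remainder is residual).
#' @param n_replicates replicates of the split-plot design.
#' @param n_tanks tanks per condition within each replicate.
#' @param missing_rate,het_rate fractions of calls set missing /
#'   heterozygous, injected for QC testing.
#' @param chrom_length_bp chromosome length for the uniform marker map.
#' @param seed master seed.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_individuals = 600, n_markers = 17000,
                       n_chromosomes = 12, Fst = 0.1, admixture = 0.37,
                       n_causal = min(200, n_markers),
                       traits = default_sim_traits(),
                       mu = c(control = 50, salt = 40),
                       rep_frac = 0.15, tank_frac = 0.10,
                       n_replicates = 3, n_tanks = 6,
                       missing_rate = 0.05, het_rate = 0.05,
                       chrom_length_bp = 30e6, seed = 1) {
  stopifnot(all(traits$h2 >= 0 & traits$h2 < 1),
            all(traits$rho_g >= 0 & traits$rho_g <= 1),
            n_causal <= n_markers, Fst > 0, Fst < 1,
            admixture >= 0, admixture <= 1,
            rep_frac + tank_frac < 1)
  structure(list(n_individuals = n_individuals, n_markers = n_markers,
                 n_chromosomes = n_chromosomes, Fst = Fst,
                 admixture = admixture, n_causal = n_causal,
                 traits = traits, mu = mu, rep_frac = rep_frac,
                 tank_frac = tank_frac, n_replicates = n_replicates,
                 n_tanks = n_tanks, missing_rate = missing_rate,
                 het_rate = het_rate, chrom_length_bp = chrom_length_bp,
                 seed = seed),
            class = "sim_config")
}

#' Default synthetic trait panel
#'
#' Heritabilities span the repeatability range such panels report
#' (0.44-0.93) and cross-condition genetic correlations the observed
#' genotype-by-condition range (0.25-0.83); Na and K are salt-only.
#'
#' @return data.frame: trait, h2, rho_g, salt_only.
#' @export
default_sim_traits <- function() {
  data.frame(
    trait = c("SHOOT", "RL", "TIL", "SLA", "Na", "K"),
    h2 = c(0.85, 0.70, 0.60, 0.50, 0.80, 0.80),
    rho_g = c(0.80, 0.60, 0.45, 0.30, 1.00, 1.00),
    salt_only = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Simulate structured genotypes (Balding-Nichols model)
#'
#' Ancestral allele frequencies are uniform on [0.1, 0.9]; each of two
#' subpopulations draws its frequency from Beta(p(1-F)/F, (1-p)(1-F)/F).
#' Individuals are fully inbred lines (dosage 0 or 2 at every locus, as in
#' a fixed-line rice panel): pure individuals draw their allele from their
#' subpopulation's frequency, admixed individuals choose, per locus, the
#' source subpopulation with an individual admixture coefficient uniform
#' on (0, 1). Positions are uniform per chromosome. Optional
#' missing/heterozygote injection supports QC testing (heterozygotes in
#' such panels are calling artifacts).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param inject_qc_noise add missing calls and heterozygotes at the
#'   configured rates (default FALSE: a clean matrix).
#' @return A list: \code{genotypes} (\code{marker_matrix}), \code{labels}
#'   (data.frame: sample, subpop in \{1, 2, "admixed"\}, admix_coef).
#' @export
simulate_genotypes <- function(cfg = sim_config(), inject_qc_noise = FALSE) {
  set.seed(cfg$seed)
  n <- cfg$n_individuals; p <- cfg$n_markers; F <- cfg$Fst
  p_anc <- stats::runif(p, 0.1, 0.9)
  shape <- (1 - F) / F
  freq <- cbind(stats::rbeta(p, p_anc * shape, (1 - p_anc) * shape),
                stats::rbeta(p, p_anc * shape, (1 - p_anc) * shape))
  n_adm <- round(cfg$admixture * n)
  n_pure <- n - n_adm
  subpop <- c(rep(1L, ceiling(n_pure / 2)), rep(2L, floor(n_pure / 2)),
              rep(NA_integer_, n_adm))
  admix_coef <- rep(NA_real_, n)
  admix_coef[is.na(subpop)] <- stats::runif(n_adm, 0, 1)
  dos <- matrix(0L, n, p)
  for (i in seq_len(n)) {
    if (is.na(subpop[i])) {
      # per-locus ancestry from subpop 1 with probability admix_coef
      src <- stats::rbinom(p, 1, admix_coef[i])
      f <- ifelse(src == 1, freq[, 1], freq[, 2])
      dos[i, ] <- 2L * stats::rbinom(p, 1, f)
    } else {
      dos[i, ] <- 2L * stats::rbinom(p, 1, freq[, subpop[i]])
    }
  }
  if (inject_qc_noise) {
    n_calls <- length(dos)
    het_idx <- sample.int(n_calls, round(cfg$het_rate * n_calls))
    dos[het_idx] <- 1L
    na_idx <- sample.int(n_calls, round(cfg$missing_rate * n_calls))
    dos[na_idx] <- NA_integer_
  }
  ids <- sprintf("G%04d", seq_len(n))
  rownames(dos) <- ids
  per_chr <- diff(round(seq(0, p, length.out = cfg$n_chromosomes + 1)))
  chrom <- rep(paste0("chr", sprintf("%02d", seq_len(cfg$n_chromosomes))),
               per_chr)
  pos <- unlist(lapply(per_chr, function(k)
    sort(sample.int(cfg$chrom_length_bp, k))))
  colnames(dos) <- sprintf("M%05d", seq_len(p))
  labels <- data.frame(sample = ids,
                       subpop = ifelse(is.na(subpop), "admixed",
                                       as.character(subpop)),
                       admix_coef = admix_coef, stringsAsFactors = FALSE)
  list(genotypes = marker_matrix(dos, chrom, pos), labels = labels)
}

#' Simulate genetic effects and split-plot phenotypes
#'
#' For each configured trait, causal effects are split into a main
#' component beta0 ~ N(0, s2_0) shared across conditions and
#' condition-specific components beta_j ~ N(0, s2_E), with
#' s2_0 / (s2_0 + s2_E) equal to the target genetic correlation rho_g.
#' Genetic values g_j = X(beta0 + beta_j) (centered dosages) are
#' standardized per condition and observations are generated across the
#' split-plot design (replicates, tanks nested in replicates, residual)
#' with var(g)/var(y) equal to the target h2. Salt-only traits are
#' generated in the salt condition only.
#'
#' @param m a complete \code{marker_matrix} from
#'   \code{\link{simulate_genotypes}}.
#' @param cfg a \code{\link{sim_config}}.
#' @return A list: \code{phenotypes} (long-format table), \code{truth}
#'   (per-trait list: beta0, beta_env, genetic values g per condition,
#'   realized h2 and realized cross-condition correlation of g).
#' @export
simulate_effects_and_phenotypes <- function(m, cfg = sim_config()) {
  if (anyNA(m$dosage)) stop("genotypes contain missing data")
  if (cfg$n_causal == 0 && any(cfg$traits$h2 > 0))
    stop("n_causal = 0 is incompatible with h2 > 0")
  set.seed(cfg$seed + 7919)   # distinct stream from the genotype draw
  X <- center_genotypes(m)$values
  n <- nrow(X)
  ids <- rownames(m$dosage)
  conditions <- c("control", "salt")
  rows <- list()
  truth <- list()
  for (t_i in seq_len(nrow(cfg$traits))) {
    tr <- cfg$traits[t_i, ]
    conds <- if (tr$salt_only) "salt" else conditions
    causal <- sample.int(ncol(X), cfg$n_causal)
    s2_0 <- tr$rho_g
    s2_E <- 1 - tr$rho_g
    beta0 <- stats::rnorm(cfg$n_causal, 0, sqrt(s2_0))
    g <- sapply(conds, function(cond) {
      beta_j <- stats::rnorm(cfg$n_causal, 0, sqrt(s2_E))
      gj <- drop(X[, causal, drop = FALSE] %*% (beta0 + beta_j))
      as.numeric(scale(gj)) * sqrt(tr$h2)   # var(g) = h2, var(y) = 1
    })
    g <- matrix(g, nrow = n, dimnames = list(ids, conds))
    v_ng <- 1 - tr$h2
    s_rep <- sqrt(cfg$rep_frac * v_ng)
    s_tank <- sqrt(cfg$tank_frac * v_ng)
    s_res <- sqrt((1 - cfg$rep_frac - cfg$tank_frac) * v_ng)
    for (cond in conds) {
      mu_c <- if (cond %in% names(cfg$mu)) cfg$mu[[cond]] else 0
      for (r in seq_len(cfg$n_replicates)) {
        rep_eff <- stats::rnorm(1, 0, s_rep)
        tank_of <- rep_len(seq_len(cfg$n_tanks), n)   # round-robin tanks
        tank_eff <- stats::rnorm(cfg$n_tanks, 0, s_tank)
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = ids, condition = cond,
          replicate = paste0("R", r),
          tank = paste0(substr(cond, 1, 1), tank_of),
          trait = tr$trait,
          value = mu_c + g[, cond] + rep_eff + tank_eff[tank_of] +
            stats::rnorm(n, 0, s_res),
          stringsAsFactors = FALSE)
      }
    }
    realized_h2 <- apply(g, 2, stats::var) /
      (apply(g, 2, stats::var) + s_rep^2 + s_tank^2 + s_res^2)
    truth[[tr$trait]] <- list(
      causal = causal, beta0 = beta0, g = g,
      realized_h2 = realized_h2,
      realized_rho_g = if (length(conds) == 2 && all(apply(g, 2, stats::sd) > 0))
                         stats::cor(g[, 1], g[, 2])
                       else NA_real_)
  }
  list(phenotypes = do.call(rbind, rows), truth = truth)
}

#' Write a simulation truth object as JSON
#' @param truth the \code{truth} element of
#'   \code{\link{simulate_effects_and_phenotypes}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_truth <- function(truth, path) {
  slim <- lapply(truth, function(t)
    list(realized_h2 = as.list(t$realized_h2),
         realized_rho_g = t$realized_rho_g,
         n_causal = length(t$causal)))
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
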