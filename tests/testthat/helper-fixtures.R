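# Shared fixture builders; everything is generated in code at test time.

# small marker matrix with given dosage columns (markers named m1..mk)
mk_markers <- function(cols, chrom = NULL, pos = NULL, pim = NULL) {
  d <- do.call(cbind, cols)
  colnames(d) <- if (!is.null(names(cols))) names(cols)
                 else paste0("m", seq_along(cols))
  rownames(d) <- paste0("S", seq_len(nrow(d)))
  if (is.null(chrom)) chrom <- "1"
  if (is.null(pos)) pos <- 100 * seq_len(ncol(d))
  marker_matrix(d, chrom, pos, pre_imputation_missing_rate = pim)
}

# random clean inbred marker matrix (dosage 0/2) with moderate MAF
rand_markers <- function(n, p, seed = 1) {
  set.seed(seed)
  f <- runif(p, 0.15, 0.85)
  d <- 2 * matrix(rbinom(n * p, 1, rep(f, each = n)), n, p)
  dimnames(d) <- list(sprintf("S%03d", 1:n), sprintf("m%04d", 1:p))
  marker_matrix(d, chrom = rep("1", p), pos = seq_len(p) * 1000)
}

# the 5-marker QC toy: one low call rate, one high het, one low MAF, two clean
qc_toy <- function() {
  n <- 25
  m_cr <- c(rep(NA, 10), rep(0, 10), rep(2, 5))          # call rate 0.6
  m_het <- c(rep(1, 5), rep(0, 12), rep(2, 8))           # het rate 0.2
  m_maf <- c(1, rep(0, 24))                              # MAF 1/50 = 0.02
  m_ok1 <- c(rep(0, 15), rep(2, 10))                     # MAF 0.4
  m_ok2 <- c(rep(2, 20), rep(0, 5))                      # MAF 0.2
  mk_markers(list(m_cr = m_cr, m_het = m_het, m_maf = m_maf,
                  m_ok1 = m_ok1, m_ok2 = m_ok2))
}

write_vcf_fixture <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "100", "m1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "m2", "C", "T", ".", "PASS", ".", "GT",
          "0/0", "0/0", "1/1", sep = "\t"))
  writeLines(lines, path)
  path
}

write_hapmap_fixture <- function(path, triallelic = TRUE) {
  hd <- paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
                "S1", "S2", "S3"), collapse = "\t")
  rows <- c(
    paste(c("m1", "A/G", "1", "100", "+", rep("NA", 6),
            "AA", "AG", "GG"), collapse = "\t"),
    paste(c("m3", "C/T", "1", "300", "+", rep("NA", 6),
            "CC", "CT", "TT"), collapse = "\t"))
  if (triallelic)
    rows <- c(rows, paste(c("m2", "A/G/T", "1", "200", "+", rep("NA", 6),
                            "AA", "AT", "GG"), collapse = "\t"))
  writeLines(c(hd, rows), path)
  path
}

# phenotype vector with genetic signal drawn from a kernel
kernel_signal <- function(K, h2 = 0.5, mu = 0, seed = 1) {
  Kv <- if (inherits(K, "kernel_matrix")) K$values else K
  n <- nrow(Kv)
  set.seed(seed)
  e <- eigen(Kv, symmetric = TRUE)
  d <- pmax(e$values, 0)
  g <- drop(e$vectors %*% (sqrt(d) * rnorm(n)))
  g <- g / sd(g) * sqrt(h2)
  list(y = mu + g + rnorm(n, 0, sqrt(1 - h2)), g = g)
}

# balanced split-plot phenotype table built from exact effect sizes
balanced_pheno <- function(geno_eff, cond_eff = c(control = 0, salt = -2),
                           inter = NULL, rep_eff = c(R1 = 0, R2 = 0, R3 = 0),
                           sigma = 0, n_tanks = 2, seed = 1, trait = "SHOOT") {
  set.seed(seed)
  g <- names(geno_eff)
  rows <- expand.grid(genotype = g, condition = names(cond_eff),
                      replicate = names(rep_eff), stringsAsFactors = FALSE)
  rows$tank <- paste0(substr(rows$condition, 1, 1),
                      (match(rows$genotype, g) - 1) %% n_tanks + 1)
  rows$trait <- trait
  inter_val <- if (is.null(inter)) 0
               else inter[cbind(rows$genotype, rows$condition)]
  rows$value <- geno_eff[rows$genotype] + cond_eff[rows$condition] +
    rep_eff[rows$replicate] + inter_val + rnorm(nrow(rows), 0, sigma)
  rows
}

# closed-form conditional-mean oracle at fixed variance components, with
# the intercept profiled out by GLS (matching a flat prior on mu):
# E[g | y_obs] = s2u K[, obs] V^-1 (y_obs - mu_gls), V = s2u K[obs] + s2e I
blup_oracle <- function(K, y, s2u, s2e, mu = NULL) {
  obs <- which(!is.na(y))
  V <- s2u * K[obs, obs] + s2e * diag(length(obs))
  Vi <- solve(V)
  if (is.null(mu)) mu <- sum(Vi %*% y[obs]) / sum(Vi)
  drop(s2u * K[, obs] %*% Vi %*% (y[obs] - mu))
}

pooled_g0 <- function(fit) Reduce(rbind, lapply(fit$chains, `[[`, "g0"))

# Monte-Carlo standard error of a posterior mean from autocorrelated draws,
# via batch means
mc_se <- function(draws, n_batch = 20) {
  nb <- floor(nrow(draws) / n_batch)
  bm <- sapply(seq_len(n_batch), function(b)
    colMeans(draws[((b - 1) * nb + 1):(b * nb), , drop = FALSE]))
  apply(t(bm), 2, sd) / sqrt(n_batch)
}

reduced_cfg <- function(seed = 1, n_iter = 1200, burn_in = 200, thin = 5,
                        n_chains = 1) {
  gibbs_config(n_iter = n_iter, burn_in = burn_in, thin = thin,
               n_chains = n_chains, seed = seed)
}
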