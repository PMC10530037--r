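mk_pheno_row <- function(trait, value, genotype = "G1", condition = "control",
                         replicate = "R1", tank = "T1") {
  data.frame(genotype = genotype, condition = condition,
             replicate = replicate, tank = tank, trait = trait,
             value = value, stringsAsFactors = FALSE)
}

test_that("derived traits apply the printed formulas per observation", {
  raw <- rbind(mk_pheno_row("LGTH", 20), mk_pheno_row("WDTH", 2),
               mk_pheno_row("LEAF", 0.5),
               mk_pheno_row("ROOT", 3), mk_pheno_row("SHOOT", 3),
               mk_pheno_row("Na", 1.2), mk_pheno_row("K", 2.4))
  out <- derived_traits(raw)
  val <- function(tr) out$value[out$trait == tr]
  expect_equal(val("LA"), 30)         # 20 x 2 x 0.75
  expect_equal(val("SLA"), 60)        # 30 / 0.5
  expect_equal(val("R_S"), 1)         # ROOT = SHOOT
  expect_equal(val("Na_K"), 0.5)
})

test_that("zero denominators are skipped with a warning", {
  raw <- rbind(mk_pheno_row("ROOT", 3), mk_pheno_row("SHOOT", 0))
  expect_warning(out <- derived_traits(raw), "zero SHOOT")
  expect_false("R_S" %in% out$trait)
})

test_that("noise-free balanced effects are recovered exactly", {
  geno <- c(G1 = 10, G2 = 12, G3 = 15, G4 = 9)
  tab <- balanced_pheno(geno, sigma = 0)
  fit <- fit_split_plot(tab, "SHOOT")
  am <- adjusted_means(fit)
  # constructed cell means: genotype effect + condition effect
  for (g in names(geno)) {
    expect_equal(am$mean[am$genotype == g & am$condition == "control"],
                 geno[[g]], tolerance = 1e-8)
    expect_equal(am$mean[am$genotype == g & am$condition == "salt"],
                 geno[[g]] - 2, tolerance = 1e-8)
  }
})

test_that("adjusted means equal raw cell means on balanced complete data", {
  geno <- c(G1 = 10, G2 = 12, G3 = 15, G4 = 9, G5 = 11)
  tab <- balanced_pheno(geno, sigma = 0.5, seed = 5)
  am <- adjusted_means(fit_split_plot(tab, "SHOOT"))
  raw_cells <- aggregate(value ~ genotype + condition, data = tab, mean)
  mrg <- merge(am, raw_cells, by = c("genotype", "condition"))
  expect_equal(mrg$mean, mrg$value, tolerance = 1e-8)
})

test_that("a replicate-level shift is absorbed by the random effect", {
  geno <- c(G1 = 10, G2 = 12, G3 = 15, G4 = 9, G5 = 11, G6 = 14)
  base <- balanced_pheno(geno, rep_eff = c(R1 = 0, R2 = 0, R3 = 0),
                         sigma = 0.05, seed = 7)
  shifted <- balanced_pheno(geno, rep_eff = c(R1 = 0, R2 = 0, R3 = 10),
                            sigma = 0.05, seed = 7)
  am0 <- adjusted_means(fit_split_plot(base, "SHOOT"))
  am1 <- adjusted_means(fit_split_plot(shifted, "SHOOT"))
  # genotype contrasts are unshifted (the common shift goes to the
  # replicate effect up to the intercept, so compare centered means)
  m0 <- am0$mean[am0$condition == "control"]
  m1 <- am1$mean[am1$condition == "control"]
  expect_lt(max(abs((m1 - mean(m1)) - (m0 - mean(m0)))), 0.1)
})

test_that("dropping degenerate random terms leaves means unchanged", {
  geno <- c(G1 = 10, G2 = 12, G3 = 15, G4 = 9)
  tab <- balanced_pheno(geno, sigma = 0.3, seed = 11)
  am_mixed <- adjusted_means(fit_split_plot(tab, "SHOOT"))
  ols <- lm(value ~ condition * genotype,
            transform(tab, condition = factor(condition, c("control", "salt")),
                      genotype = factor(genotype)))
  cells <- expand.grid(genotype = names(geno),
                       condition = c("control", "salt"),
                       stringsAsFactors = FALSE)
  pred <- predict(ols, cells)
  mrg <- merge(am_mixed, cbind(cells, pred), by = c("genotype", "condition"))
  expect_lt(max(abs(mrg$mean - mrg$pred)), 1e-6)
})

test_that("genotype p-values are uniform under the null", {
  set.seed(123)
  n_perm <- 120
  geno <- setNames(rep(0, 8), paste0("G", 1:8))
  pvals <- replicate(n_perm, {
    tab <- balanced_pheno(geno, rep_eff = c(R1 = 0.3, R2 = -0.2, R3 = 0),
                          sigma = 1, seed = sample.int(1e6, 1))
    fit <- fit_split_plot(tab, "SHOOT")
    aov_tab <- fit$anova
    aov_tab[rownames(aov_tab) == "genotype", "Pr(>Chisq)"]
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a single-genotype table yields its cell averages", {
  tab <- rbind(mk_pheno_row("SHOOT", 10, replicate = "R1"),
               mk_pheno_row("SHOOT", 12, replicate = "R2"),
               mk_pheno_row("SHOOT", 8, condition = "salt", replicate = "R1"),
               mk_pheno_row("SHOOT", 6, condition = "salt", replicate = "R2"))
  am <- adjusted_means(fit_split_plot(tab, "SHOOT"))
  expect_equal(am$mean[am$condition == "control"], 11)
  expect_equal(am$mean[am$condition == "salt"], 7)
})

test_that("stress index matches (salt - control) x 100 / control", {
  am <- data.frame(genotype = rep(c("G1", "G2", "G3"), each = 2),
                   condition = rep(c("control", "salt"), 3),
                   trait = "SHOOT",
                   mean = c(4, 3, 5, 5, 2, 3), se = NA)
  idx <- stress_index(am, "SHOOT")
  expect_equal(idx$index, c(-25, 0, 50))
  expect_equal(unique(idx$trait), "iSHOOT")
  # scale invariance
  am2 <- am; am2$mean <- am2$mean * 7.3
  expect_equal(stress_index(am2, "SHOOT")$index, idx$index)
  # zero control mean is dropped with a warning
  am3 <- am; am3$mean[1] <- 0
  expect_warning(idx3 <- stress_index(am3, "SHOOT"), "zero control")
  expect_equal(nrow(idx3), 2L)
})

test_that("rank correlation between conditions behaves as a rank statistic", {
  am <- data.frame(genotype = rep(paste0("G", 1:5), each = 2),
                   condition = rep(c("control", "salt"), 5),
                   trait = "T",
                   mean = c(1, 10, 2, 20, 3, 30, 4, 40, 5, 50), se = NA)
  expect_equal(gxc_rank_correlation(am, "T"), 1)
  am_rev <- am
  am_rev$mean[am_rev$condition == "salt"] <- rev(c(10, 20, 30, 40, 50))
  expect_equal(gxc_rank_correlation(am_rev, "T"), -1)
  # hand evaluation via the rank formula on a scrambled 5-genotype fixture
  am5 <- am
  salt_vals <- c(30, 10, 50, 20, 40)
  am5$mean[am5$condition == "salt"] <- salt_vals
  rho_hand <- 1 - 6 * sum((rank(c(1, 2, 3, 4, 5)) - rank(salt_vals))^2) /
    (5 * (5^2 - 1))
  expect_equal(gxc_rank_correlation(am5, "T"), rho_hand)
  # invariance to monotone transforms, and the kendall option
  am_exp <- am5
  am_exp$mean[am_exp$condition == "salt"] <-
    exp(am_exp$mean[am_exp$condition == "salt"] / 10)
  expect_equal(gxc_rank_correlation(am_exp, "T"),
               gxc_rank_correlation(am5, "T"))
  expect_equal(gxc_rank_correlation(am, "T", method = "kendall"), 1)
})

test_that("repeatability reflects the genotype-mean variance ratio", {
  set.seed(42)
  # noise-free replicates: H2 = 1
  g <- rnorm(30)
  tab0 <- data.frame(genotype = rep(paste0("G", 1:30), each = 3),
                     condition = "salt", replicate = rep(c("R1", "R2", "R3"), 30),
                     tank = "T1", trait = "Na",
                     value = rep(g, each = 3), stringsAsFactors = FALSE)
  expect_equal(repeatability(tab0, "Na", "salt"), 1, tolerance = 1e-6)
  # pure noise: H2 near zero
  tabn <- tab0
  tabn$value <- rnorm(nrow(tabn))
  expect_lt(repeatability(tabn, "Na", "salt"), 0.1)
  # sigma_g = sigma_e with 3 replicates: H2 = 1 / (1 + 1/3) = 0.75
  set.seed(43)
  g2 <- rnorm(200)
  tab2 <- data.frame(genotype = rep(paste0("G", 1:200), each = 3),
                     condition = "salt", replicate = rep(c("R1", "R2", "R3"), 200),
                     tank = "T1", trait = "Na",
                     value = rep(g2, each = 3) + rnorm(600),
                     stringsAsFactors = FALSE)
  expect_equal(repeatability(tab2, "Na", "salt"), 0.75, tolerance = 0.08)
})
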