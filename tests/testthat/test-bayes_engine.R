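test_that("posterior-mean genetic values match the ridge/BLUP oracle", {
  n <- 50
  sim <- simulate_genotypes(sim_config(n_individuals = n, n_markers = 300,
                                       seed = 11))
  K <- linear_kernel(center_genotypes(sim$genotypes))
  sig <- kernel_signal(K, h2 = 0.5, mu = 2, seed = 12)
  fit <- fit_single_env(sig$y, K,
                        gibbs_config(n_iter = 22000, burn_in = 2000,
                                     thin = 2, seed = 5),
                        fixed_variances = list(s2u0 = 1, s2e = 1))
  g0 <- pooled_g0(fit)
  dev <- abs(colMeans(g0) - blup_oracle(K$values, sig$y, 1, 1))
  expect_lt(max(dev / (3 * mc_se(g0))), 1)
})

test_that("a constant phenotype yields null genetic effects", {
  n <- 40
  K <- linear_kernel(center_genotypes(rand_markers(n, 200, seed = 3)))
  fit <- fit_single_env(rep(5, n), K, reduced_cfg(seed = 4, n_iter = 4000,
                                                  burn_in = 1000))
  g0 <- pooled_g0(fit)
  expect_lt(max(abs(colMeans(g0))), 3 * max(mc_se(g0)) + 0.02)
  s2u <- Reduce(rbind, lapply(fit$chains, `[[`, "s2"))[, "s2u0"]
  expect_lt(median(s2u), 0.5)
})

test_that("chains agree under the Gelman-Rubin diagnostic", {
  n <- 50
  sim <- simulate_genotypes(sim_config(n_individuals = n, n_markers = 250,
                                       seed = 21))
  K <- linear_kernel(center_genotypes(sim$genotypes))
  sig <- kernel_signal(K, h2 = 0.5, seed = 22)
  fit <- fit_single_env(sig$y, K, gibbs_config(n_chains = 2, seed = 30))
  psrf <- gelman_rubin(fit)
  expect_true(all(psrf[c("mu_env", "s2u0", "s2e_env")] < 1.1))
})

test_that("adding a constant shifts the intercept and not the GEBVs", {
  n <- 40
  K <- linear_kernel(center_genotypes(rand_markers(n, 150, seed = 41)))
  sig <- kernel_signal(K, h2 = 0.6, seed = 42)
  cfg <- reduced_cfg(seed = 43, n_iter = 6000, burn_in = 1000)
  f1 <- fit_single_env(sig$y, K, cfg)
  f2 <- fit_single_env(sig$y + 10, K, cfg)
  m1 <- Reduce(rbind, lapply(f1$chains, `[[`, "mu"))
  m2 <- Reduce(rbind, lapply(f2$chains, `[[`, "mu"))
  expect_equal(mean(m2) - mean(m1), 10, tolerance = 0.05)
  expect_equal(colMeans(pooled_g0(f2)), colMeans(pooled_g0(f1)),
               tolerance = 1e-8)
})

test_that("masked lines receive oracle BLUP predictions at fixed variances", {
  n <- 40
  sim <- simulate_genotypes(sim_config(n_individuals = n, n_markers = 250,
                                       seed = 51))
  K <- linear_kernel(center_genotypes(sim$genotypes))
  sig <- kernel_signal(K, h2 = 0.6, seed = 52)
  y <- sig$y
  masked <- c(3, 9, 17, 28, 35)
  y[masked] <- NA
  fit <- fit_single_env(y, K,
                        gibbs_config(n_iter = 22000, burn_in = 2000,
                                     thin = 2, seed = 53),
                        fixed_variances = list(s2u0 = 1, s2e = 0.6))
  g0 <- pooled_g0(fit)
  oracle <- blup_oracle(K$values, y, 1, 0.6)
  dev <- abs(colMeans(g0) - oracle)[masked]
  expect_lt(max(dev / (3 * mc_se(g0))[masked]), 1)
})

test_that("duplicated genotype rows receive equal GEBVs within MC error", {
  n <- 30
  m <- rand_markers(n, 150, seed = 61)
  d <- m$dosage
  d <- rbind(d, dup1 = d[7, ])   # exact genetic copy of sample 7
  K <- linear_kernel(center_genotypes(
    marker_matrix(d, m$map$chrom, m$map$pos)))
  set.seed(62)
  g <- kernel_signal(K, h2 = 0.7, seed = 62)
  y <- g$y
  y[n + 1] <- NA                 # the duplicate is unphenotyped
  fit <- fit_single_env(y, K, gibbs_config(n_iter = 12000, burn_in = 2000,
                                           thin = 2, seed = 63))
  g0 <- pooled_g0(fit)
  se <- mc_se(g0)
  expect_lt(abs(mean(g0[, 7]) - mean(g0[, n + 1])),
            3 * sqrt(se[7]^2 + se[n + 1]^2) + 0.02)
})

test_that("multi-env with one environment is the single-env sampler", {
  n <- 30
  K <- linear_kernel(center_genotypes(rand_markers(n, 100, seed = 71)))
  y <- kernel_signal(K, h2 = 0.5, seed = 72)$y
  cfg <- reduced_cfg(seed = 73, n_iter = 2000, burn_in = 500)
  f1 <- fit_single_env(y, K, cfg)
  Y <- matrix(y, ncol = 1, dimnames = list(NULL, "env"))
  f2 <- fit_multi_env(Y, K, cfg = cfg, include_env_effect = FALSE)
  expect_identical(f1$chains[[1]]$g0, f2$chains[[1]]$g0)
  expect_identical(f1$chains[[1]]$s2, f2$chains[[1]]$s2)
})

test_that("shared-effect simulation puts little mass on specific variances", {
  n <- 200
  sim <- simulate_genotypes(sim_config(n_individuals = n, n_markers = 400,
                                       seed = 81))
  K <- linear_kernel(center_genotypes(sim$genotypes))
  g <- kernel_signal(K, h2 = 0.99, seed = 82)$g   # one shared genetic value
  set.seed(83)
  Y <- cbind(control = g + rnorm(n, 0, 0.3), salt = g + rnorm(n, 0, 0.3))
  fit <- fit_multi_env(Y, K, cfg = reduced_cfg(seed = 84, n_iter = 6000,
                                               burn_in = 1000))
  s2 <- Reduce(rbind, lapply(fit$chains, `[[`, "s2"))
  frac <- (s2[, "s2u_control"] + s2[, "s2u_salt"]) /
    (s2[, "s2u0"] + s2[, "s2u_control"] + s2[, "s2u_salt"])
  expect_lt(mean(frac), 0.25)
})

test_that("environment labels are equivariant", {
  n <- 60
  K <- linear_kernel(center_genotypes(rand_markers(n, 200, seed = 91)))
  set.seed(92)
  g <- kernel_signal(K, h2 = 0.7, seed = 92)$g
  Y <- cbind(A = g + rnorm(n, 0, 0.4), B = 2 + 0.5 * g + rnorm(n, 0, 0.4))
  cfg <- reduced_cfg(seed = 93, n_iter = 6000, burn_in = 1000)
  f_ab <- fit_multi_env(Y, K, cfg = cfg)
  f_ba <- fit_multi_env(Y[, c("B", "A")], K, cfg = cfg)
  g_ab <- extract_gebv(f_ab)
  g_ba <- extract_gebv(f_ba)
  for (e in c("A", "B")) {
    a <- g_ab$predicted[g_ab$env == e]
    b <- g_ba$predicted[g_ba$env == e]
    expect_gt(cor(a, b), 0.98)
    expect_lt(mean(abs(a - b)), 0.1)
  }
})

test_that("split-chain PSRF separates converged from divergent chains", {
  set.seed(101)
  iid <- lapply(1:2, function(i)
    matrix(rnorm(3000), ncol = 1, dimnames = list(NULL, "theta")))
  psrf <- gelman_rubin(iid)
  expect_gt(psrf[["theta"]], 0.99)
  expect_lt(psrf[["theta"]], 1.05)
  shifted <- list(iid[[1]], iid[[2]] + 5)
  expect_gt(gelman_rubin(shifted)[["theta"]], 1.5)
  flat <- lapply(1:2, function(i)
    matrix(1, nrow = 100, ncol = 1, dimnames = list(NULL, "theta")))
  expect_warning(p <- gelman_rubin(flat), "undefined")
  expect_true(is.na(p[["theta"]]))
})

test_that("extract_gebv validates requested genotypes", {
  n <- 20
  K <- linear_kernel(center_genotypes(rand_markers(n, 60, seed = 111)))
  y <- setNames(rnorm(n), rownames(K$values))
  fit <- fit_single_env(y, K, reduced_cfg(seed = 112, n_iter = 600,
                                          burn_in = 100))
  expect_error(extract_gebv(fit, genotypes = "NOPE"), "absent")
  g <- extract_gebv(fit, genotypes = names(y)[1:3])
  expect_equal(nrow(g), 3L)
})
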