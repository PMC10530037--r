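test_that("partitions respect the 80/20 split and are reproducible", {
  p <- make_partitions(241, seed = 17)
  expect_equal(length(p$reps), 100L)
  sizes_tr <- vapply(p$reps, function(r) length(r$train), integer(1))
  sizes_va <- vapply(p$reps, function(r) length(r$validation), integer(1))
  expect_true(all(sizes_tr == 192L))
  expect_true(all(sizes_va == 49L))
  for (r in p$reps) {
    expect_length(intersect(r$train, r$validation), 0)
    expect_setequal(c(r$train, r$validation), 1:241)
  }
  p2 <- make_partitions(241, seed = 17)
  expect_identical(p, p2)
  expect_error(make_partitions(241, fraction = 1.2), "fraction")
  expect_error(make_partitions(5), "at least 10")
})

test_that("partitions round-trip through JSON", {
  p <- make_partitions(30, n_reps = 5, seed = 3)
  ids <- sprintf("G%02d", 1:30)
  path <- withr::local_tempfile(fileext = ".json")
  write_partitions(p, path, ids = ids)
  p2 <- read_partitions(path)
  for (i in 1:5) {
    expect_identical(p2$reps[[i]]$train, p$reps[[i]]$train)
    expect_identical(p2$reps[[i]]$validation, p$reps[[i]]$validation)
  }
})

test_that("Fisher Z matches its closed form and inverse", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.69), 0.5 * log(1.69 / 0.31))
  expect_equal(fisher_z(0.69), 0.8480, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_lt(max(abs(fisher_z_inverse(fisher_z(r)) - r)), 1e-12)
  # odd and strictly increasing
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(1), ">= 1")
  expect_equal(fisher_z(1, clamp = TRUE), fisher_z(1 - 1e-12))
})

test_that("high-signal phenotypes give high predictive ability", {
  n <- 200
  # fewer markers than training lines, so the noiseless genetic value is
  # fully recoverable from the linear kernel
  sim <- simulate_genotypes(sim_config(n_individuals = n, n_markers = 100,
                                       n_causal = 50, seed = 121))
  K <- linear_kernel(center_genotypes(sim$genotypes))
  g <- kernel_signal(K, h2 = 0.999, seed = 122)$g   # essentially noiseless
  parts <- make_partitions(n, n_reps = 5, seed = 123)
  cv <- run_cv(K, list(env = g), parts, model = "single",
               cfg = reduced_cfg(seed = 124), trait = "g")
  expect_true(all(cv$r >= -1 & cv$r <= 1))
  expect_equal(nrow(cv), 5L)
  expect_gt(mean(cv$r), 0.9)
})

test_that("pure-noise phenotypes give predictive ability near zero", {
  n <- 120
  sim <- simulate_genotypes(sim_config(n_individuals = n, n_markers = 300,
                                       seed = 131))
  K <- linear_kernel(center_genotypes(sim$genotypes))
  # a fresh noise vector per replicate: conditioning on a single draw
  # leaves a phenotype-specific alignment with the kernel's structure axes
  # that does not average out across overlapping partitions
  set.seed(132)
  rs <- sapply(1:25, function(i) {
    y <- rnorm(n)
    parts <- make_partitions(n, n_reps = 2, seed = 133 + i)
    cv <- run_cv(K, list(env = y), parts, model = "single",
                 cfg = reduced_cfg(seed = 134 + i, n_iter = 800,
                                   burn_in = 200),
                 trait = "noise")
    mean(cv$r, na.rm = TRUE)
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("predictive ability rises with simulated heritability", {
  n <- 150
  sim <- simulate_genotypes(sim_config(n_individuals = n, n_markers = 400,
                                       seed = 141))
  K <- linear_kernel(center_genotypes(sim$genotypes))
  parts <- make_partitions(n, n_reps = 8, seed = 142)
  pa <- sapply(c(0.2, 0.5, 0.8), function(h2) {
    y <- kernel_signal(K, h2 = h2, seed = 143)$y
    mean(run_cv(K, list(env = y), parts, model = "single",
                cfg = reduced_cfg(seed = 144), trait = "t")$r, na.rm = TRUE)
  })
  expect_true(all(diff(pa) > 0))
})

test_that("multi-environment CV reports per-condition abilities", {
  n <- 80
  sim <- simulate_genotypes(sim_config(n_individuals = n, n_markers = 250,
                                       seed = 151))
  K <- linear_kernel(center_genotypes(sim$genotypes))
  set.seed(152)
  g <- kernel_signal(K, h2 = 0.8, seed = 152)$g
  Y <- cbind(control = g + rnorm(n, 0, 0.4), salt = 0.8 * g + rnorm(n, 0, 0.4))
  parts <- make_partitions(n, n_reps = 3, seed = 153)
  cv <- run_cv(K, Y, parts, model = "multi",
               cfg = reduced_cfg(seed = 154), trait = "SHOOT",
               method = "GBLUP")
  expect_equal(nrow(cv), 6L)   # 3 reps x 2 conditions
  expect_setequal(unique(cv$condition), c("control", "salt"))
  smry <- summarize_cv(cv)
  expect_equal(nrow(smry), 2L)
  expect_equal(smry$n_reps, c(3L, 3L))
})

test_that("ANOVA on Z detects a pure trait effect", {
  set.seed(161)
  grid <- expand.grid(rep = 1:30, trait = c("A", "B", "C"),
                      condition = c("control", "salt"),
                      method = "GBLUP", model = "single",
                      stringsAsFactors = FALSE)
  trait_eff <- c(A = 0.1, B = 0.35, C = 0.6)
  grid$r <- tanh(trait_eff[grid$trait] + rnorm(nrow(grid), 0, 0.08))
  class(grid) <- c("cv_result", "data.frame")
  res <- anova_pa(grid)
  tab <- res$anova
  expect_lt(tab["trait", "Pr(>F)"], 0.01)
  expect_gt(tab["condition", "Pr(>F)"], 0.01)
})

test_that("all-equal Z values produce zero factor sums of squares", {
  grid <- expand.grid(rep = 1:10, trait = c("A", "B"),
                      condition = c("control", "salt"),
                      method = "GBLUP", model = "single",
                      stringsAsFactors = FALSE)
  grid$r <- 0.5
  class(grid) <- c("cv_result", "data.frame")
  tab <- anova_pa(grid)$anova
  expect_equal(tab["trait", "Sum Sq"], 0)
  expect_equal(tab["condition", "Sum Sq"], 0)
})

# independent type-II oracle: residual-sum-of-squares differences computed
# with raw normal equations, no anova machinery
rss <- function(X, y) {
  b <- qr.solve(qr(X), y)
  sum((y - X %*% b)^2)
}

test_that("type-II sums of squares match a projection-matrix oracle", {
  set.seed(171)
  d <- expand.grid(rep = 1:5, trait = c("A", "B"),
                   condition = c("control", "salt"),
                   method = c("GBLUP", "RKHS"), model = "single",
                   stringsAsFactors = FALSE)
  d <- d[1:40, ]
  d$r <- tanh(0.3 + 0.2 * (d$trait == "B") - 0.1 * (d$condition == "salt") +
                rnorm(40, 0, 0.1))
  class(d) <- c("cv_result", "data.frame")
  res <- anova_pa(d, factors = c("trait", "condition", "method"))
  z <- res$z
  full_terms <- c("trait", "condition", "method", "partition")
  Xof <- function(terms) model.matrix(reformulate(terms), data = z)
  for (term in c("trait", "condition", "method")) {
    ss_oracle <- rss(Xof(setdiff(full_terms, term)), z$Z) -
      rss(Xof(full_terms), z$Z)
    expect_equal(res$anova[term, "Sum Sq"], ss_oracle, tolerance = 1e-8)
  }
})

test_that("method agreement is a rank statistic on predictions", {
  set.seed(181)
  g1 <- data.frame(genotype = sprintf("G%03d", 1:500), env = "salt",
                   gebv = rnorm(500), predicted = rnorm(500))
  expect_equal(method_agreement(g1, g1)$rho, 1)
  mono <- g1
  mono$predicted <- exp(g1$predicted)     # strictly monotone transform
  expect_equal(method_agreement(g1, mono)$rho, 1)
  indep <- g1
  indep$predicted <- rnorm(500)
  expect_lt(abs(method_agreement(g1, indep)$rho), 0.15)
  expect_error(method_agreement(g1[1:2, ], g1[3:4, ]), "common genotypes")
})
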