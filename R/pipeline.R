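#' Read and validate a pipeline run configuration
#'
#' YAML with a strict key check: unknown top-level keys are rejected. The
#' configuration is serialized into every output directory for provenance.
#'
#' @param path YAML file.
#' @return A list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("output_dir", "seed", "simulate", "genotypes", "genotype_map",
             "phenotypes", "bp_genotypes", "filters", "impute_method",
             "kernel", "gibbs", "cv", "selection", "structure", "traits",
             "map_gap_threshold_kb")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$output_dir)) stop("output_dir is required")
  if (is.null(cfg$seed)) cfg$seed <- 1
  structure(cfg, class = "run_config")
}

log_stage <- function(cfg, stage, t0, extra = list()) {
  entry <- c(list(stage = stage,
                  time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  seed = cfg$seed,
                  elapsed_s = round(as.numeric(Sys.time()) - t0, 2),
                  r_version = as.character(getRversion())),
             extra)
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = file.path(cfg$output_dir, "run_log.jsonl"),
      append = TRUE)
  invisible(entry)
}

need_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop(sprintf("missing input artifact for this stage: %s (%s)",
                 what, if (is.null(path)) "not configured" else path))
  path
}

cfg_gibbs <- function(cfg) {
  g <- cfg$gibbs
  do.call(gibbs_config,
          c(g[names(g) %in% c("n_iter", "burn_in", "thin", "n_chains",
                              "df0", "R2")],
            list(seed = cfg$seed)))
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (synthetic genotypes + phenotypes),
#' \code{qc} (filter + impute + prune + map summary),
#' \code{adjust} (split-plot adjusted means per trait),
#' \code{kernel} (centered kernel of the configured method),
#' \code{fit} (full-data model fit and GEBVs),
#' \code{cv} (CV1 predictive ability), \code{predict} (train on the panel,
#' predict a breeding population), \code{select} (validation subset),
#' \code{structure} (simple-matching distances, NJ tree, group assignment).
#' Each stage writes its outputs into \code{output_dir} plus a JSON-lines
#' log entry, and fails before any computation when an input artifact is
#' missing.
#'
#' @param stage stage name.
#' @param cfg a \code{run_config} (or path to one).
#' @return Invisibly, a list of the paths written.
#' @export
run_stage <- function(stage, cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stages <- c("simulate", "qc", "adjust", "kernel", "fit", "cv", "predict",
              "select", "structure")
  stage <- match.arg(stage, stages)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$output_dir, "run_config.yaml"))
  t0 <- as.numeric(Sys.time())
  out <- switch(stage,
                simulate = stage_simulate(cfg),
                qc = stage_qc(cfg),
                adjust = stage_adjust(cfg),
                kernel = stage_kernel(cfg),
                fit = stage_fit(cfg),
                cv = stage_cv(cfg),
                predict = stage_predict(cfg),
                select = stage_select(cfg),
                structure = stage_structure(cfg))
  log_stage(cfg, stage, t0, extra = list(outputs = unname(unlist(out))))
  invisible(out)
}

sim_cfg_from <- function(cfg) {
  args <- cfg$simulate
  args$traits <- if (!is.null(args$traits))
    do.call(rbind, lapply(args$traits, as.data.frame)) else NULL
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(sim_config, c(args, list(seed = cfg$seed)))
}

stage_simulate <- function(cfg) {
  sc <- sim_cfg_from(cfg)
  sim <- simulate_genotypes(sc, inject_qc_noise = FALSE)
  phe <- simulate_effects_and_phenotypes(sim$genotypes, sc)
  # QC-style noise goes into the written genotypes only; phenotypes are
  # generated from the clean matrix.
  dos <- sim$genotypes$dosage
  set.seed(sc$seed + 104729)
  dos[sample.int(length(dos), round(sc$het_rate * length(dos)))] <- 1
  dos[sample.int(length(dos), round(sc$missing_rate * length(dos)))] <- NA
  noisy <- marker_matrix(dos, sim$genotypes$map$chrom, sim$genotypes$map$pos)
  paths <- list(
    genotypes = file.path(cfg$output_dir, "genotypes.csv"),
    phenotypes = file.path(cfg$output_dir, "phenotypes.csv"),
    labels = file.path(cfg$output_dir, "subpop_labels.csv"),
    truth = file.path(cfg$output_dir, "truth.json"))
  write_genotypes(noisy, paths$genotypes)
  utils::write.csv(phe$phenotypes, paths$phenotypes, row.names = FALSE)
  utils::write.csv(sim$labels, paths$labels, row.names = FALSE)
  write_truth(phe$truth, paths$truth)
  paths
}

resolve_genotypes <- function(cfg, what = "genotypes") {
  path <- cfg[[what]]
  if (is.null(path)) path <- file.path(cfg$output_dir, paste0(what, ".csv"))
  need_file(path, what)
  read_genotypes(path, format = "csv_dosage", map_path = cfg$genotype_map)
}

stage_qc <- function(cfg) {
  m <- resolve_genotypes(cfg)
  thr <- do.call(filter_thresholds, as.list(cfg$filters))
  f <- filter_markers(m, thr)
  imp <- impute_naive(f$matrix,
                      method = if (is.null(cfg$impute_method)) "mode"
                               else cfg$impute_method)
  pr <- prune_redundant(imp)
  gap_kb <- if (is.null(cfg$map_gap_threshold_kb)) 500 else cfg$map_gap_threshold_kb
  ms <- map_summary(pr$matrix, gap_kb)
  paths <- list(genotypes_qc = file.path(cfg$output_dir, "genotypes_qc.csv"),
                report = file.path(cfg$output_dir, "filter_report.tsv"),
                map_summary = file.path(cfg$output_dir, "map_summary.json"))
  write_genotypes(pr$matrix, paths$genotypes_qc)
  write_filter_report(f$report, paths$report)
  jsonlite::write_json(
    list(n_in = f$report$n_in, n_filtered = f$report$n_out,
         n_pruned = n_markers(pr$matrix),
         n_fail_call_rate = f$report$n_fail_call_rate,
         n_fail_het = f$report$n_fail_het,
         n_fail_maf = f$report$n_fail_maf,
         mean_adjacent_kb = ms$mean_adjacent_kb,
         max_gap_kb = ms$max_gap_kb, max_gap_chrom = ms$max_gap_chrom,
         n_gaps_over = ms$n_gaps_over),
    paths$map_summary, auto_unbox = TRUE, digits = NA)
  paths
}

stage_adjust <- function(cfg) {
  path <- need_file(if (is.null(cfg$phenotypes))
    file.path(cfg$output_dir, "phenotypes.csv") else cfg$phenotypes,
    "phenotypes")
  tab <- derived_traits(utils::read.csv(path, stringsAsFactors = FALSE))
  traits <- if (!is.null(cfg$traits)) cfg$traits else unique(tab$trait)
  am <- list()
  for (tr in traits) {
    d <- tab[tab$trait == tr, ]
    if (length(unique(d$condition)) == 2) {
      am[[tr]] <- adjusted_means(fit_split_plot(tab, tr))
    } else {
      # single-condition (ion) traits: genotype cell means
      agg <- stats::aggregate(value ~ genotype + condition, data = d, mean)
      am[[tr]] <- data.frame(genotype = agg$genotype,
                             condition = agg$condition, trait = tr,
                             mean = agg$value, se = NA_real_)
    }
  }
  am <- do.call(rbind, am)
  out <- file.path(cfg$output_dir, "adjusted_means.csv")
  utils::write.csv(am, out, row.names = FALSE)
  list(adjusted_means = out)
}

qc_kernel_inputs <- function(cfg) {
  m <- resolve_genotypes(cfg, "genotypes_qc")
  am_path <- need_file(file.path(cfg$output_dir, "adjusted_means.csv"),
                       "adjusted_means")
  list(m = m, am = utils::read.csv(am_path, stringsAsFactors = FALSE))
}

kernel_for <- function(cfg, m, am = NULL) {
  method <- if (is.null(cfg$kernel$method)) "GBLUP" else cfg$kernel$method
  if (method == "GBLUP") return(linear_kernel(center_genotypes(m)))
  d2 <- squared_distance_matrix(m)
  h <- cfg$kernel$bandwidth
  if (is.null(h)) {
    tr <- if (!is.null(cfg$kernel$bandwidth_trait)) cfg$kernel$bandwidth_trait
          else am$trait[1]
    a <- am[am$trait == tr, ]
    y <- stats::setNames(a$mean, a$genotype)[rownames(m$dosage)]
    h <- estimate_bandwidth(d2, y)$h
  }
  gaussian_kernel(d2, h)
}

stage_kernel <- function(cfg) {
  inp <- qc_kernel_inputs(cfg)
  K <- kernel_for(cfg, inp$m, inp$am)
  out <- file.path(cfg$output_dir, "kernel.tsv")
  write_kernel(K, out)
  list(kernel = out)
}

am_matrix <- function(am, trait, ids) {
  a <- am[am$trait == trait, ]
  conds <- sort(unique(a$condition))
  Y <- sapply(conds, function(cc) {
    v <- a[a$condition == cc, ]
    stats::setNames(v$mean, v$genotype)[ids]
  })
  matrix(Y, nrow = length(ids), dimnames = list(ids, conds))
}

stage_fit <- function(cfg) {
  inp <- qc_kernel_inputs(cfg)
  K <- read_kernel(need_file(file.path(cfg$output_dir, "kernel.tsv"), "kernel"))
  gc_ <- cfg_gibbs(cfg)
  model <- if (is.null(cfg$cv$model)) "single" else cfg$cv$model
  traits <- if (!is.null(cfg$traits)) cfg$traits else unique(inp$am$trait)
  gebv <- list()
  for (tr in traits) {
    Y <- am_matrix(inp$am, tr, rownames(inp$m$dosage))
    fit <- if (model == "multi" && ncol(Y) > 1) fit_multi_env(Y, K, cfg = gc_)
           else if (ncol(Y) == 1) fit_single_env(Y[, 1], K, cfg = gc_)
           else fit_multi_env(Y, K, cfg = gc_, include_env_effect = FALSE)
    g <- extract_gebv(fit)
    g$trait <- tr
    gebv[[tr]] <- g
  }
  out <- file.path(cfg$output_dir, "gebv.csv")
  utils::write.csv(do.call(rbind, gebv), out, row.names = FALSE)
  list(gebv = out)
}

stage_cv <- function(cfg) {
  inp <- qc_kernel_inputs(cfg)
  K <- read_kernel(need_file(file.path(cfg$output_dir, "kernel.tsv"), "kernel"))
  ids <- rownames(inp$m$dosage)
  n_reps <- if (is.null(cfg$cv$n_reps)) 100 else cfg$cv$n_reps
  fraction <- if (is.null(cfg$cv$fraction)) 0.8 else cfg$cv$fraction
  model <- if (is.null(cfg$cv$model)) "single" else cfg$cv$model
  parts <- make_partitions(length(ids), fraction, n_reps, seed = cfg$seed)
  write_partitions(parts, file.path(cfg$output_dir, "partitions.json"),
                   ids = ids)
  gc_ <- cfg_gibbs(cfg)
  method <- if (is.null(cfg$kernel$method)) "GBLUP" else cfg$kernel$method
  traits <- if (!is.null(cfg$traits)) cfg$traits else unique(inp$am$trait)
  res <- list()
  for (tr in traits) {
    Y <- am_matrix(inp$am, tr, ids)
    mdl <- if (ncol(Y) > 1) model else "single"
    res[[tr]] <- run_cv(K, Y, parts, model = mdl, cfg = gc_,
                        method = method, trait = tr)
  }
  res <- do.call(rbind, res)
  paths <- list(cv = file.path(cfg$output_dir, "cv_results.csv"),
                cv_summary = file.path(cfg$output_dir, "cv_summary.csv"))
  utils::write.csv(res, paths$cv, row.names = FALSE)
  utils::write.csv(summarize_cv(res), paths$cv_summary, row.names = FALSE)
  paths
}

stage_predict <- function(cfg) {
  inp <- qc_kernel_inputs(cfg)
  bp <- read_genotypes(need_file(cfg$bp_genotypes, "bp_genotypes"),
                       format = "csv_dosage")
  if (anyNA(bp$dosage)) bp <- impute_naive(bp)
  gc_ <- cfg_gibbs(cfg)
  method <- if (is.null(cfg$kernel$method)) "GBLUP" else cfg$kernel$method
  model <- if (is.null(cfg$cv$model)) "single" else cfg$cv$model
  traits <- if (!is.null(cfg$selection$traits)) cfg$selection$traits
            else unique(inp$am$trait)
  gebv <- list()
  for (tr in traits) {
    Y <- am_matrix(inp$am, tr, rownames(inp$m$dosage))
    g <- predict_population(inp$m, Y, bp, method = method,
                            model = if (ncol(Y) > 1) model else "single",
                            cfg = gc_, h = cfg$kernel$bandwidth)
    g$trait <- tr
    gebv[[tr]] <- g
  }
  out <- file.path(cfg$output_dir, "bp_gebv.csv")
  utils::write.csv(do.call(rbind, gebv), out, row.names = FALSE)
  list(bp_gebv = out)
}

stage_select <- function(cfg) {
  path <- need_file(file.path(cfg$output_dir, "bp_gebv.csv"), "bp_gebv")
  gebv <- utils::read.csv(path, stringsAsFactors = FALSE)
  args <- cfg$selection
  args <- args[names(args) %in% c("traits", "methods", "n_sel", "q")]
  spec <- do.call(selection_spec, args)
  res <- select_validation_set(gebv, spec)
  out <- file.path(cfg$output_dir, "validation_subset.csv")
  write_selection(res, out)
  list(validation_subset = out)
}

stage_structure <- function(cfg) {
  m <- resolve_genotypes(cfg, "genotypes_qc")
  d <- simple_matching(m)
  k <- if (is.null(cfg$structure$k)) 3 else cfg$structure$k
  ve <- if (is.null(cfg$structure$var_explained)) 0.90
        else cfg$structure$var_explained
  ga <- assign_groups(m, k = k, var_explained = ve, seed = cfg$seed)
  paths <- list(distances = file.path(cfg$output_dir, "distances.tsv"),
                tree = file.path(cfg$output_dir, "nj_tree.nwk"),
                groups = file.path(cfg$output_dir, "groups.csv"))
  write_distance_matrix(d, paths$distances)
  nj_tree(d, paths$tree)
  utils::write.csv(data.frame(sample = names(ga$groups), group = ga$groups),
                   paths$groups, row.names = FALSE)
  paths
}
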