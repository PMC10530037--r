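#' Validate a long-format phenotype table
#'
#' Expected columns: genotype, condition (\code{"control"}/\code{"salt"}),
#' replicate, tank, trait, value. Used by the split-plot model, adjusted
#' means, indices and repeatability.
#'
#' @param tab data.frame in the long format above.
#' @return The table, with factors normalized, invisibly validated.
#' @export
validate_phenotypes <- function(tab) {
  need <- c("genotype", "condition", "replicate", "tank", "trait", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(tab$condition %in% c("control", "salt")))
    stop("condition must be 'control' or 'salt'")
  if (any(!is.finite(tab$value)))
    stop("non-finite phenotype values present")
  for (col in c("genotype", "condition", "replicate", "tank", "trait"))
    tab[[col]] <- as.character(tab[[col]])
  tab
}

#' Add derived traits to a phenotype table
#'
#' Per observation (genotype x condition x replicate x tank), computes leaf
#' area LA = LGTH x WDTH x 0.75, specific leaf area SLA = LA / LEAF, the
#' root-to-shoot ratio R_S = ROOT / SHOOT, and the Na/K ratio Na_K = Na / K.
#' Observations with a zero denominator are skipped with a warning.
#'
#' @param raw phenotype table containing the component traits (any subset of
#'   LGTH, WDTH, LEAF, ROOT, SHOOT, Na, K).
#' @return The table with the derived-trait rows appended.
#' @export
derived_traits <- function(raw) {
  raw <- validate_phenotypes(raw)
  wide <- stats::reshape(raw, idvar = c("genotype", "condition", "replicate", "tank"),
                         timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  derive <- function(num, den = NULL, scale = 1, name) {
    if (!all(c(num, den) %in% names(wide))) return(NULL)
    v <- wide[[num[1]]]
    if (length(num) == 2) v <- v * wide[[num[2]]]
    v <- v * scale
    if (!is.null(den)) {
      zero <- !is.na(wide[[den]]) & wide[[den]] == 0
      if (any(zero)) {
        warning(sprintf("%s: skipped %d observation(s) with zero %s",
                        name, sum(zero), den))
        v[zero] <- NA_real_
      }
      v <- v / wide[[den]]
    }
    ok <- !is.na(v)
    if (!any(ok)) return(NULL)
    data.frame(genotype = wide$genotype, condition = wide$condition,
               replicate = wide$replicate, tank = wide$tank,
               trait = name, value = v, stringsAsFactors = FALSE)[ok, ]
  }
  if (all(c("LGTH", "WDTH") %in% names(wide)))
    wide$LA_tmp <- wide$LGTH * wide$WDTH * 0.75
  extra <- rbind(
    derive(c("LGTH", "WDTH"), scale = 0.75, name = "LA"),
    derive("LA_tmp", den = "LEAF", name = "SLA"),
    derive("ROOT", den = "SHOOT", name = "R_S"),
    derive("Na", den = "K", name = "Na_K"))
  rbind(raw, extra)
}

#' Fit the split-plot mixed model for one trait
#'
#' REML fit of value ~ condition * genotype (fixed) with random replicate
#' and tank-within-replicate intercepts. For small designs the two random
#' terms can be combined into a single tank term
#' (\code{random = "combined"}). Falls back to ordinary least squares when
#' the mixed fit fails or is singular in both random terms.
#'
#' @param tab phenotype table.
#' @param trait trait name to fit.
#' @param random \code{"nested"} (default) or \code{"combined"}.
#' @return A list of class \code{lmm_fit}: \code{model}, \code{trait},
#'   \code{converged}, \code{varcomp}, \code{anova} (Wald type-II tests of
#'   condition, genotype and their interaction), \code{logLik}.
#' @export
fit_split_plot <- function(tab, trait, random = c("nested", "combined")) {
  random <- match.arg(random)
  tab <- validate_phenotypes(tab)
  d <- tab[tab$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop("no observations for trait ", trait)
  if (length(unique(d$condition)) < 2)
    stop("both conditions required for the split-plot model")
  if (length(unique(d$replicate)) < 2)
    stop("at least two replicates required")
  d$genotype <- factor(d$genotype)
  d$condition <- factor(d$condition, levels = c("control", "salt"))
  d$replicate <- factor(d$replicate)
  d$tank_unit <- factor(paste(d$replicate, d$tank, sep = ":"))
  fixed_rhs <- if (nlevels(d$genotype) > 1) "condition * genotype"
               else "condition"   # degenerate single-genotype table
  rand_rhs <- if (random == "nested") "(1 | replicate) + (1 | tank_unit)"
              else "(1 | tank_unit)"
  form <- stats::as.formula(paste("value ~", fixed_rhs, "+", rand_rhs))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(form, data = d, REML = TRUE,
                                control = lme4::lmerControl(calc.derivs = FALSE))),
    error = function(e) NULL)
  converged <- !is.null(fit)
  if (converged) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- stats::setNames(vc$vcov, vc$grp)
    aov_tab <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
    model <- fit
  } else {
    # fallback: ordinary least squares on the fixed part
    model <- stats::lm(stats::as.formula(paste("value ~", fixed_rhs)), data = d)
    varcomp <- c(Residual = summary(model)$sigma^2)
    aov_tab <- tryCatch(car::Anova(model, type = 2), error = function(e) NULL)
  }
  structure(list(model = model, trait = trait, data = d, fixed_rhs = fixed_rhs,
                 converged = converged, varcomp = varcomp,
                 anova = aov_tab, logLik = as.numeric(stats::logLik(model))),
            class = "lmm_fit")
}

#' Adjusted (least-squares) genotype means per condition
#'
#' Predicted cell means per genotype x condition from the fixed effects of a
#' split-plot fit, averaging over the random effects (set to zero). On
#' balanced complete data these equal the raw cell means.
#'
#' @param fit an \code{lmm_fit} from \code{\link{fit_split_plot}}.
#' @return data.frame of class \code{adjusted_means}: genotype, condition,
#'   trait, mean, se.
#' @export
adjusted_means <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  d <- fit$data
  cells <- unique(d[, c("genotype", "condition")])
  cells <- cells[order(cells$genotype, cells$condition), , drop = FALSE]
  mm_data <- cells
  mm_data$value <- 0
  xlev <- list(condition = levels(d$condition))
  if (grepl("genotype", fit$fixed_rhs)) xlev$genotype <- levels(d$genotype)
  X <- stats::model.matrix(stats::as.formula(paste("~", fit$fixed_rhs)),
                           data = mm_data, xlev = xlev)
  beta <- if (inherits(fit$model, "merMod")) lme4::fixef(fit$model)
          else stats::coef(fit$model)
  usable <- !is.na(beta)
  V <- as.matrix(stats::vcov(fit$model))
  Xu <- X[, names(beta)[usable], drop = FALSE]
  mu <- drop(Xu %*% beta[usable])
  se <- sqrt(rowSums((Xu %*% V) * Xu))
  out <- data.frame(genotype = as.character(cells$genotype),
                    condition = as.character(cells$condition),
                    trait = fit$trait, mean = mu, se = se,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("adjusted_means", "data.frame")
  out
}

#' Stress-response index iTRAIT = (salt - control) x 100 / control
#'
#' @param am an \code{adjusted_means} table (single trait or filtered by
#'   \code{trait}).
#' @param trait trait to index.
#' @return data.frame: genotype, trait (\code{"i<trait>"}), index (percent).
#'   Genotypes with a zero control mean are dropped with a warning.
#' @export
stress_index <- function(am, trait) {
  a <- am[am$trait == trait, , drop = FALSE]
  ctrl <- a[a$condition == "control", c("genotype", "mean")]
  salt <- a[a$condition == "salt", c("genotype", "mean")]
  mrg <- merge(ctrl, salt, by = "genotype", suffixes = c("_control", "_salt"))
  if (nrow(mrg) == 0) stop("no genotype has both condition means for ", trait)
  zero <- mrg$mean_control == 0
  if (any(zero)) {
    warning(sprintf("i%s undefined for %d genotype(s) with zero control mean",
                    trait, sum(zero)))
    mrg <- mrg[!zero, , drop = FALSE]
  }
  data.frame(genotype = mrg$genotype,
             trait = paste0("i", trait),
             index = (mrg$mean_salt - mrg$mean_control) * 100 / mrg$mean_control,
             stringsAsFactors = FALSE)
}

#' Genotype-by-condition rank correlation
#'
#' Rank correlation between per-genotype adjusted means in the control and
#' salt conditions; low values indicate strong genotype-by-condition
#' interaction.
#'
#' @param am an \code{adjusted_means} table.
#' @param trait trait name.
#' @param method \code{"spearman"} (default, midrank ties) or
#'   \code{"kendall"}.
#' @return The rank correlation (single numeric).
#' @export
gxc_rank_correlation <- function(am, trait, method = c("spearman", "kendall")) {
  method <- match.arg(method)
  a <- am[am$trait == trait, , drop = FALSE]
  ctrl <- a[a$condition == "control", c("genotype", "mean")]
  salt <- a[a$condition == "salt", c("genotype", "mean")]
  mrg <- merge(ctrl, salt, by = "genotype")
  if (nrow(mrg) < 3) stop("need >= 3 genotypes with both conditions")
  stats::cor(mrg$mean.x, mrg$mean.y, method = method)
}

#' Repeatability of genotype means within one condition
#'
#' H^2 = s2_g / (s2_g + s2_e / r_bar) from a one-condition fit with genotype
#' random, where r_bar is the harmonic mean of the per-genotype observation
#' counts.
#'
#' @param tab phenotype table.
#' @param trait trait name.
#' @param condition \code{"control"} or \code{"salt"}.
#' @return H^2 in [0, 1].
#' @export
repeatability <- function(tab, trait, condition) {
  tab <- validate_phenotypes(tab)
  d <- tab[tab$trait == trait & tab$condition == condition, , drop = FALSE]
  if (nrow(d) == 0) stop("no observations for ", trait, " in ", condition)
  counts <- table(d$genotype)
  if (all(counts < 2)) stop("need >= 2 observations per genotype")
  r_bar <- length(counts) / sum(1 / as.numeric(counts))
  # boundary fits (zero residual variance) trigger spurious convergence
  # warnings while the estimates are exact
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(value ~ (1 | genotype), data = d, REML = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2g <- vc$vcov[vc$grp == "genotype"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  if (s2g <= 0) return(0)
  s2g / (s2g + s2e / r_bar)
}
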