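# Per-entry BLUEs, ANOVA variance components, Knapp broad-sense
# heritability, testcross gain, and correlations with significance stars.
#
# BLUEs and variance components are computed by fixed-effect least squares /
# method-of-moments from expected mean squares, not with a mixed-model
# solver; for balanced data these coincide with the mixed-model results.

#' Per-entry best linear unbiased estimates (adjusted means)
#'
#' Least-squares entry means from the two-way model
#' `value = mu + entry + block + residual`, where a block is a
#' rep-within-(location x year) cell (so block effects absorb both the
#' environment main effects and rep-within-environment effects).  Estimates
#' are reported on the grand-mean scale: each entry's effect plus the average
#' block contribution, so for balanced data the BLUE equals the arithmetic
#' entry mean.
#'
#' @param pheno Long-format phenotype table (see [read_pheno_csv()]).
#' @param trait Trait to analyse.
#' @param population Optional population tag filter (e.g. `"RIL"`).
#' @return Named numeric vector of BLUEs (one per entry with data).  Entries
#'   whose observations are all missing are excluded with a warning.
#' @export
compute_blue <- function(pheno, trait, population = NULL) {
  d <- pheno[pheno$trait == trait, , drop = FALSE]
  if (!is.null(population)) d <- d[d$population %in% population, , drop = FALSE]
  if (!nrow(d)) stop_bad("no records for trait %s", trait)
  all_missing <- tapply(d$value, d$entry, function(v) all(is.na(v)))
  if (any(all_missing)) {
    warning(sprintf("excluding %d entries with all-missing values for %s",
                    sum(all_missing), trait), call. = FALSE)
    d <- d[!(d$entry %in% names(all_missing)[all_missing]), , drop = FALSE]
  }
  d <- d[!is.na(d$value), , drop = FALSE]
  entry <- factor(d$entry)
  block <- factor(paste(d$location, d$year, d$rep, sep = ":"))
  entry_means <- function() {
    m <- tapply(d$value, entry, mean)[levels(entry)]
    stats::setNames(as.numeric(m), names(m))
  }
  if (nlevels(block) == 1L) return(entry_means())
  # balanced fast path: every entry observed once in every block
  tab <- table(entry, block)
  if (all(tab == 1L)) return(entry_means())
  fit <- stats::lm(d$value ~ entry + block)
  cf <- stats::coef(fit)
  be <- cf[grepl("^block", names(cf))]
  be[is.na(be)] <- 0
  base <- cf[1L] + mean(c(0, be))  # average over all block levels
  eff <- c(0, cf[grepl("^entry", names(cf))])
  names(eff) <- levels(entry)
  if (anyNA(eff)) warning("some entry effects were inestimable", call. = FALSE)
  base + eff
}

# Moebius sum-of-squares helper for balanced factorials:
# q_U = sum over cells of the factor subset U of (cell sum)^2 / (cell count);
# the ANOVA SS of the interaction of a subset S is sum_{U subseteq S}
# (-1)^{|S|-|U|} q_U, with q_{empty} the correction factor.
q_stat <- function(value, factors, subset) {
  if (!length(subset)) return(sum(value)^2 / length(value))
  key <- interaction(factors[subset], drop = TRUE, lex.order = TRUE)
  sums <- tapply(value, key, sum)
  cnts <- tapply(value, key, length)
  sum(sums^2 / cnts)
}

ss_subset <- function(value, factors, S) {
  subsets <- list(character(0))
  for (f in S) subsets <- c(subsets, lapply(subsets, c, f))
  sum(vapply(subsets, function(U)
    (-1)^(length(S) - length(U)) * q_stat(value, factors, U), numeric(1)))
}

#' ANOVA variance components for a multi-environment RIL trial
#'
#' Sequential balanced ANOVA of the genotype x location x year model with
#' rep-within-environment blocks, followed by method-of-moments estimation
#' from expected mean squares.  Negative solutions are truncated to zero.
#' Components requiring a stratum with fewer than two levels (e.g. GxY with a
#' single year) are reported as `NA` (not estimable).
#'
#' @param pheno Long-format phenotype table.
#' @param trait Trait to analyse.
#' @param population Population tag (default `"RIL"`).
#' @return Object of class `"varcomp"`: list with components `sigma_G`,
#'   `sigma_GL`, `sigma_GY`, `sigma_GLY`, `sigma_E` (variances), design
#'   constants `L`, `Y`, `R`, and a `table` of sources, df and mean squares.
#' @export
anova_variance_components <- function(pheno, trait, population = "RIL") {
  d <- pheno[pheno$trait == trait & pheno$population %in% population, , drop = FALSE]
  d <- d[!is.na(d$value), , drop = FALSE]
  if (!nrow(d)) stop_bad("no records for trait %s", trait)
  fac <- list(G = factor(d$entry), L = factor(d$location), Y = factor(d$year),
              rep = factor(d$rep))
  K <- nlevels(fac$G); L <- nlevels(fac$L); Y <- nlevels(fac$Y)
  env <- interaction(fac$L, fac$Y, drop = TRUE)
  R <- round(nrow(d) / (K * L * Y))
  cell <- interaction(fac$G, env, fac$rep, drop = TRUE)
  if (any(table(cell) != 1L) || nrow(d) != K * L * Y * R)
    warning("design is not balanced; method-of-moments estimates are approximate",
            call. = FALSE)

  y <- d$value
  tot <- sum(y^2) - q_stat(y, fac, character(0))
  use_L <- L > 1L; use_Y <- Y > 1L
  sets <- list(G = "G")
  if (use_L) sets <- c(sets, list(L = "L", GL = c("G", "L")))
  if (use_Y) sets <- c(sets, list(Y = "Y", GY = c("G", "Y")))
  if (use_L && use_Y) sets <- c(sets, list(LY = c("L", "Y"), GLY = c("G", "L", "Y")))
  ss <- vapply(sets, function(S) ss_subset(y, fac, S), numeric(1))
  dfs <- vapply(sets, function(S)
    prod(vapply(S, function(f) nlevels(fac[[f]]) - 1L, numeric(1))), numeric(1))
  # blocks: reps within environment
  ss_blk <- if (R > 1L) {
    facb <- list(env = env, rep = fac$rep)
    ss_subset(y, facb, c("env", "rep")) + ss_subset(y, facb, "rep")
  } else 0
  df_blk <- L * Y * (R - 1L)
  ss_err <- tot - sum(ss) - ss_blk
  df_err <- nrow(d) - 1L - sum(dfs) - df_blk
  if (df_err <= 0) stop_bad("no residual degrees of freedom for trait %s", trait)
  ms <- ss / dfs
  ms_err <- ss_err / df_err

  sGL <- sGY <- sGLY <- NA_real_
  sE <- ms_err
  ms_gly <- if (use_L && use_Y) ms[["GLY"]] else ms_err
  if (use_L && use_Y) sGLY <- (ms[["GLY"]] - ms_err) / R
  if (use_L) sGL <- (ms[["GL"]] - ms_gly) / (R * Y)
  if (use_Y) sGY <- (ms[["GY"]] - ms_gly) / (R * L)
  sG <- if (use_L && use_Y)
    (ms[["G"]] - ms[["GL"]] - ms[["GY"]] + ms[["GLY"]]) / (R * L * Y)
  else if (use_L) (ms[["G"]] - ms[["GL"]]) / (R * L * Y)
  else if (use_Y) (ms[["G"]] - ms[["GY"]]) / (R * L * Y)
  else (ms[["G"]] - ms_err) / R
  trunc0 <- function(x) if (is.na(x)) x else max(x, 0)
  out <- list(sigma_G = trunc0(sG), sigma_GL = trunc0(sGL),
              sigma_GY = trunc0(sGY), sigma_GLY = trunc0(sGLY),
              sigma_E = trunc0(sE), L = L, Y = Y, R = R,
              table = data.frame(
                source = c(names(sets), "Block", "Error"),
                df = c(dfs, df_blk, df_err),
                mean_sq = c(ms, if (df_blk > 0) ss_blk / df_blk else NA, ms_err),
                stringsAsFactors = FALSE))
  class(out) <- "varcomp"
  out
}

#' @export
print.varcomp <- function(x, ...) {
  cat("ANOVA variance components (method of moments):\n")
  cat(sprintf("  sigma2_G = %.4g, sigma2_GL = %.4g, sigma2_GY = %.4g, sigma2_GLY = %.4g, sigma2_E = %.4g\n",
              x$sigma_G, x$sigma_GL, x$sigma_GY, x$sigma_GLY, x$sigma_E))
  cat(sprintf("  design: L = %d, Y = %d, R = %d; H2 = %.3f\n",
              x$L, x$Y, x$R, broad_sense_heritability(x)))
  invisible(x)
}

#' Broad-sense heritability (Knapp)
#'
#' `H2 = sigma2_G / (sigma2_G + sigma2_GL/L + sigma2_GY/Y +
#' sigma2_GLY/(L*Y) + sigma2_E/(L*Y*R))` on the entry-mean basis.
#' Not-estimable (`NA`) interaction components are treated as zero.
#'
#' @param vc A `"varcomp"` object or a list with the same fields.
#' @return Heritability in `[0, 1]`, or `NA` if all components are zero.
#' @export
broad_sense_heritability <- function(vc) {
  z <- function(x) if (is.null(x) || is.na(x)) 0 else x
  num <- z(vc$sigma_G)
  den <- num + z(vc$sigma_GL) / vc$L + z(vc$sigma_GY) / vc$Y +
    z(vc$sigma_GLY) / (vc$L * vc$Y) + z(vc$sigma_E) / (vc$L * vc$Y * vc$R)
  if (den <= 0) {
    warning("all variance components are zero; heritability undefined", call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Testcross gain: percent difference between two population means
#'
#' `100 * (mean(pop a) - mean(pop b)) / mean(pop b)` over all records of the
#' trait, e.g. testcross progenies versus their parent RILs.
#'
#' @param pheno Long-format phenotype table.
#' @param trait Trait.
#' @param population_pair Character vector `c(a, b)`: numerator and baseline
#'   population tags.
#' @return Percent difference.
#' @export
testcross_gain <- function(pheno, trait, population_pair = c("TC", "RIL")) {
  stopifnot(length(population_pair) == 2L)
  d <- pheno[pheno$trait == trait, , drop = FALSE]
  m <- vapply(population_pair, function(p)
    mean(d$value[d$population == p], na.rm = TRUE), numeric(1))
  if (anyNA(m)) stop_bad("missing population in phenotype table")
  unname(100 * (m[1L] - m[2L]) / m[2L])
}

#' Pearson correlation with a t-test and significance stars
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p` (two-sided, t distribution with n-2 df) and
#'   `stars` (`"**"` if p < 0.01, `"*"` if p < 0.05, else `""`).  `r` is `NA`
#'   when n < 3 or either vector has zero variance.
#' @export
correlation_with_significance <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, stars = "", n = n))
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(r = r, p = p, stars = stars, n = n)
}

#' Trait correlation matrix with significance stars
#'
#' Builds the standard combined layout for per se and GCA values: the lower
#' triangle holds correlations among per se trait BLUEs, the upper triangle
#' correlations among GCA effects, and the diagonal the per se versus GCA
#' correlation of each trait.
#'
#' @param perse Numeric matrix/data.frame, lines x traits, of per se values.
#' @param gca Matching matrix of GCA effects (same lines and traits).
#' @return List with numeric matrix `r`, p-value matrix `p`, and character
#'   matrix `annotated` (`"r**"` style).
#' @export
correlation_star_matrix <- function(perse, gca) {
  perse <- as.matrix(perse); gca <- as.matrix(gca)
  stopifnot(identical(dim(perse), dim(gca)))
  tr <- colnames(perse)
  k <- length(tr)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(tr, tr))
  ann <- matrix("", k, k, dimnames = list(tr, tr))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cs <- if (i == j) correlation_with_significance(perse[, i], gca[, i])
    else if (i > j) correlation_with_significance(perse[, i], perse[, j])
    else correlation_with_significance(gca[, i], gca[, j])
    r[i, j] <- cs$r; p[i, j] <- cs$p
    ann[i, j] <- if (is.na(cs$r)) "" else paste0(sprintf("%.2f", cs$r), cs$stars)
  }
  list(r = r, p = p, annotated = ann)
}
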