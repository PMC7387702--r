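# GCA/SCA estimation from the NCII testcross table, the joint ANOVA with the
# sigma2GCA/sigma2SCA ratio, and per-line GCA phenotype vectors for QTL
# scans.

# least-squares line x tester cell means, averaging over environments/reps;
# balanced cells reduce to arithmetic means, unbalanced entries are
# BLUE-adjusted across environments first
hybrid_cell_means <- function(hybrid_pheno, design, trait) {
  d <- hybrid_pheno[hybrid_pheno$trait == trait &
                      hybrid_pheno$entry %in% design$hybrid_table$hybrid, , drop = FALSE]
  if (!nrow(d)) stop_bad("no hybrid records for trait %s", trait)
  blue <- compute_blue(d, trait)
  ht <- design$hybrid_table
  cells <- matrix(NA_real_, length(design$line_ids), length(design$tester_ids),
                  dimnames = list(design$line_ids, design$tester_ids))
  idx <- match(ht$hybrid, names(blue))
  cells[cbind(ht$line, ht$tester)] <- blue[idx]
  cells
}

#' Estimate general and specific combining ability
#'
#' On balanced data, `gca_line[k] = xbar_k.. - xbar...`, `gca_tester[l] =
#' xbar_.l. - xbar...` and `sca[k,l] = xbar_kl. - xbar_k.. - xbar_.l. +
#' xbar...`, where cell means average over environments and replicates
#' (unbalanced cells are BLUE-adjusted first).  Lines without any hybrid data
#' get `NA` GCA and are excluded from the zero-sum basis.
#'
#' @param hybrid_pheno Long-format phenotype table of hybrid records.
#' @param design The [build_ncii_design()].
#' @param trait Trait to analyse.
#' @return Object of class `"gca_est"`: list with `mu`, `gca_line`,
#'   `gca_tester`, `sca` (line x tester matrix) and `cell_means`.
#' @export
estimate_combining_ability <- function(hybrid_pheno, design, trait) {
  cells <- hybrid_cell_means(hybrid_pheno, design, trait)
  if (nrow(cells) < 2L || ncol(cells) < 2L)
    stop_bad("need >= 2 lines and >= 2 testers to separate GCA and SCA")
  mu <- mean(cells, na.rm = TRUE)
  gca_line <- rowMeans(cells, na.rm = TRUE) - mu
  gca_line[rowSums(is.finite(cells)) == 0L] <- NA_real_
  gca_tester <- colMeans(cells, na.rm = TRUE) - mu
  sca <- cells - mu - outer(gca_line, rep(1, ncol(cells))) -
    outer(rep(1, nrow(cells)), gca_tester)
  structure(list(mu = mu, gca_line = gca_line, gca_tester = gca_tester,
                 sca = sca, cell_means = cells, trait = trait),
            class = "gca_est")
}

#' @export
print.gca_est <- function(x, ...) {
  cat(sprintf("combining-ability estimates for %s: mu = %.4g\n", x$trait, x$mu))
  cat(sprintf("  %d lines (GCA sd %.4g), %d testers; SCA sd %.4g\n",
              length(x$gca_line), stats::sd(x$gca_line, na.rm = TRUE),
              length(x$gca_tester), stats::sd(x$sca, na.rm = TRUE)))
  invisible(x)
}

#' NCII joint analysis of variance for the testcross population
#'
#' Sequential balanced ANOVA of the joint model with sources L, Y, blocks
#' within environment, line GCA, tester GCA, SCA, and all location/year
#' interactions with the genetic terms.  Variance components are solved by
#' method of moments from the expected mean squares of the balanced factorial
#' (lines, testers and environments random), truncated at zero.  Reports the
#' ratio `sigma2_GCA(line) / sigma2_SCA` (NA with an `undefined` flag when
#' the SCA component truncates to zero) and a testcross heritability on the
#' line-mean basis (the Knapp formula applied to the line-side components,
#' with SCA-by-environment terms and error averaged over testers as well).
#'
#' @param hybrid_pheno Long-format phenotype table of hybrid records.
#' @param design The [build_ncii_design()].
#' @param trait Trait to analyse.
#' @return Object of class `"ncii_anova"`: list with `components` (named
#'   variances), `ratio_gca_sca`, `ratio_undefined`, `h2_testcross`, `table`
#'   (source, df, mean square), design constants.
#' @export
ncii_anova <- function(hybrid_pheno, design, trait) {
  ht <- design$hybrid_table
  d <- hybrid_pheno[hybrid_pheno$trait == trait &
                      hybrid_pheno$entry %in% ht$hybrid, , drop = FALSE]
  d <- d[!is.na(d$value), , drop = FALSE]
  if (!nrow(d)) stop_bad("no hybrid records for trait %s", trait)
  i <- match(d$entry, ht$hybrid)
  fac <- list(K = factor(ht$line[i], levels = design$line_ids),
              T = factor(ht$tester[i], levels = design$tester_ids),
              L = factor(d$location), Y = factor(d$year))
  fac <- lapply(fac, droplevels)
  lev <- vapply(fac, nlevels, integer(1))
  if (lev[["T"]] < 2L)
    stop_bad("single tester: SCA is not estimable in an NCII analysis")
  env <- interaction(fac$L, fac$Y, drop = TRUE)
  R <- round(nrow(d) / prod(lev))
  if (nrow(d) != prod(lev) * R || any(table(interaction(fac$K, fac$T, env, factor(d$rep), drop = TRUE)) != 1L))
    warning("unbalanced testcross table; estimates are approximate", call. = FALSE)

  y <- d$value
  use <- c(K = TRUE, T = TRUE, L = lev[["L"]] > 1L, Y = lev[["Y"]] > 1L)
  gen <- list("K", "T", c("K", "T"))
  envf <- list(character(0))
  if (use[["L"]]) envf <- c(envf, list("L"))
  if (use[["Y"]]) envf <- c(envf, list("Y"))
  if (use[["L"]] && use[["Y"]]) envf <- c(envf, list(c("L", "Y")))
  sets <- list()
  for (e in envf) for (g in gen) sets[[paste(c(g, e), collapse = "")]] <- c(g, e)
  for (e in envf[-1L]) sets[[paste(e, collapse = "")]] <- e

  ss <- vapply(sets, function(S) ss_subset(y, fac, S), numeric(1))
  dfs <- vapply(sets, function(S)
    prod(vapply(S, function(f) lev[[f]] - 1L, numeric(1))), numeric(1))
  tot <- sum(y^2) - q_stat(y, fac, character(0))
  ss_blk <- if (R > 1L) {
    facb <- list(env = env, rep = factor(d$rep))
    ss_subset(y, facb, c("env", "rep")) + ss_subset(y, facb, "rep")
  } else 0
  df_blk <- lev[["L"]] * lev[["Y"]] * (R - 1L)
  ss_err <- tot - sum(ss) - ss_blk
  df_err <- nrow(d) - 1L - sum(dfs) - df_blk
  if (df_err <= 0) stop_bad("no residual degrees of freedom for trait %s", trait)
  ms <- ss / dfs
  ms_err <- ss_err / df_err

  # method of moments: EMS coefficient of sigma2_Z in MS_X is
  # R * prod(levels not in Z) when X's factors are a subset of Z's
  rnd <- names(sets)[vapply(sets, function(S) any(S %in% c("K", "T")), logical(1))]
  M <- matrix(0, length(rnd) + 1L, length(rnd) + 1L,
              dimnames = list(c(rnd, "E"), c(rnd, "E")))
  for (xn in rnd) for (zn in rnd) {
    if (all(sets[[xn]] %in% sets[[zn]]))
      M[xn, zn] <- R * prod(lev[setdiff(names(lev)[use], sets[[zn]])])
  }
  M[, "E"] <- 1
  M["E", ] <- c(rep(0, length(rnd)), 1)
  comp <- solve(M, c(ms[rnd], E = ms_err))
  comp <- pmax(comp, 0)

  g <- function(nm) if (nm %in% names(comp)) comp[[nm]] else 0
  Lv <- lev[["L"]]; Yv <- lev[["Y"]]; Tv <- lev[["T"]]
  ratio_undef <- g("KT") <= 0
  ratio <- if (ratio_undef) NA_real_ else g("K") / g("KT")
  denom <- g("K") +
    (g("KL") + g("KTL") / Tv) / Lv + (g("KY") + g("KTY") / Tv) / Yv +
    (g("KLY") + g("KTLY") / Tv) / (Lv * Yv) +
    g("KT") / Tv + comp[["E"]] / (Tv * Lv * Yv * R)
  h2_tc <- if (denom > 0) g("K") / denom else NA_real_

  structure(list(
    components = comp, ratio_gca_sca = ratio, ratio_undefined = ratio_undef,
    h2_testcross = h2_tc, L = Lv, Y = Yv, R = R, n_testers = Tv,
    table = data.frame(source = c(names(sets), "Block", "Error"),
                       df = c(dfs, df_blk, df_err),
                       mean_sq = c(ms, if (df_blk > 0) ss_blk / df_blk else NA,
                                   ms_err),
                       stringsAsFactors = FALSE)),
    class = "ncii_anova")
}

#' @export
print.ncii_anova <- function(x, ...) {
  cat(sprintf("NCII testcross ANOVA: sigma2_GCA = %.4g, sigma2_SCA = %.4g\n",
              x$components[["K"]], x$components[["KT"]]))
  if (x$ratio_undefined) cat("  GCA/SCA ratio undefined (SCA component is zero)\n")
  else cat(sprintf("  GCA/SCA ratio = %.3g\n", x$ratio_gca_sca))
  cat(sprintf("  testcross H2 = %.3f\n", x$h2_testcross))
  invisible(x)
}

#' Per-line GCA phenotype vectors for QTL scans
#'
#' For each environment (location-year) the line's GCA phenotype is its
#' hybrid line margin (mean over testers and reps) centered over lines; the
#' joint value uses BLUE-corrected hybrid means across all environments.
#' These vectors are the responses for GCA QTL scans.
#'
#' @param hybrid_pheno Long-format phenotype table of hybrid records.
#' @param design The [build_ncii_design()].
#' @param trait Trait.
#' @return data.frame, lines x datasets; environment columns labelled
#'   `<year><location>` plus a final `joint` column.
#' @export
gca_phenotype_vector <- function(hybrid_pheno, design, trait) {
  ht <- design$hybrid_table
  d <- hybrid_pheno[hybrid_pheno$trait == trait &
                      hybrid_pheno$entry %in% ht$hybrid, , drop = FALSE]
  d <- d[!is.na(d$value), , drop = FALSE]
  if (!nrow(d)) stop_bad("no hybrid records for trait %s", trait)
  envs <- unique(d[, c("location", "year")])
  envs <- envs[order(envs$year, envs$location), , drop = FALSE]
  out <- data.frame(row.names = design$line_ids)
  line_of <- stats::setNames(ht$line, ht$hybrid)
  for (e in seq_len(nrow(envs))) {
    de <- d[d$location == envs$location[e] & d$year == envs$year[e], , drop = FALSE]
    m <- tapply(de$value, line_of[de$entry], mean)
    v <- m[design$line_ids]
    out[[paste0(envs$year[e], envs$location[e])]] <-
      as.numeric(v - mean(v, na.rm = TRUE))
  }
  blue <- compute_blue(d, trait)
  mj <- tapply(blue, line_of[names(blue)], mean)
  vj <- mj[design$line_ids]
  out$joint <- as.numeric(vj - mean(vj, na.rm = TRUE))
  out
}
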