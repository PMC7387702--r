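# Synthetic-data module: NCII crossing designs, RIL genome simulation, trait
# architectures and multi-environment phenotype simulation.

#' Build an NCII (North Carolina Design II) crossing design
#'
#' Every line is crossed as male to every tester; crosses that failed (e.g.
#' insufficient seed) can be excluded.  Hybrids are enumerated
#' deterministically, lines major and testers minor.
#'
#' @param line_ids Character vector of unique line identifiers.
#' @param tester_ids Character vector of unique tester identifiers.
#' @param failed_crosses Optional data.frame with columns `line`, `tester`
#'   listing crosses that produced no hybrid.
#' @return An object of class `"ncii_design"`: list with `line_ids`,
#'   `tester_ids` and `hybrid_table` (data.frame `hybrid`, `line`, `tester`).
#' @export
#' @examples
#' d <- build_ncii_design(sprintf("L%03d", 1:328), c("TC", "TM"))
#' nrow(d$hybrid_table)  # 656
build_ncii_design <- function(line_ids, tester_ids, failed_crosses = NULL) {
  line_ids <- as.character(line_ids)
  tester_ids <- as.character(tester_ids)
  if (length(line_ids) < 1L || length(tester_ids) < 1L)
    stop_bad("need at least one line and one tester")
  if (anyDuplicated(line_ids)) stop_bad("duplicate line ids")
  if (anyDuplicated(tester_ids)) stop_bad("duplicate tester ids")
  if (length(intersect(line_ids, tester_ids)))
    stop_bad("line and tester ids overlap")
  tab <- data.frame(
    line = rep(line_ids, each = length(tester_ids)),
    tester = rep(tester_ids, times = length(line_ids)),
    stringsAsFactors = FALSE)
  if (!is.null(failed_crosses)) {
    failed_crosses <- as.data.frame(failed_crosses)
    if (!all(c("line", "tester") %in% names(failed_crosses)))
      stop_bad("failed_crosses needs columns line, tester")
    if (!all(failed_crosses$line %in% line_ids) ||
        !all(failed_crosses$tester %in% tester_ids))
      stop_bad("failed_crosses must be a subset of lines x testers")
    drop <- paste(tab$line, tab$tester) %in%
      paste(failed_crosses$line, failed_crosses$tester)
    tab <- tab[!drop, , drop = FALSE]
  }
  tab <- data.frame(hybrid = paste(tab$line, tab$tester, sep = "x"), tab,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(line_ids = line_ids, tester_ids = tester_ids,
                 hybrid_table = tab),
            class = "ncii_design")
}

#' @export
print.ncii_design <- function(x, ...) {
  cat(sprintf("NCII design: %d lines x %d testers = %d hybrids (%d failed)\n",
              length(x$line_ids), length(x$tester_ids), nrow(x$hybrid_table),
              length(x$line_ids) * length(x$tester_ids) - nrow(x$hybrid_table)))
  invisible(x)
}

#' Simulate a genetic map with smooth cM-to-Mb distortion
#'
#' Markers are equally spaced in cM on each chromosome.  Physical positions
#' follow a strictly increasing smooth distortion of the genetic positions
#' (default scale 1 cM ~ 1 Mb, locally compressed/expanded by a sinusoidal
#' modulation with random phase) so that physical-interval rules such as the
#' 20-Mb co-localization window are exercised on a non-trivial coordinate
#' system.
#'
#' @param n_chrom Number of chromosomes.
#' @param markers_per_chrom Markers on each chromosome (recycled).
#' @param chrom_length_cM Length of each chromosome in cM (recycled).
#' @param mb_per_cM Mean physical-to-genetic scale.
#' @param distortion Relative amplitude of the local rate modulation in
#'   `[0, 1)`; 0 gives exactly linear Mb positions.
#' @param seed RNG seed (controls the distortion phases only).
#' @return A [genetic_map()].
#' @export
simulate_map <- function(n_chrom = 10, markers_per_chrom = 150,
                         chrom_length_cM = 153.37, mb_per_cM = 1,
                         distortion = 0.6, seed = 1) {
  n_chrom <- check_count(n_chrom, "n_chrom")
  markers_per_chrom <- rep_len(as.integer(markers_per_chrom), n_chrom)
  chrom_length_cM <- rep_len(as.numeric(chrom_length_cM), n_chrom)
  if (any(markers_per_chrom < 2L)) stop_bad("need >= 2 markers per chromosome")
  if (distortion < 0 || distortion >= 1) stop_bad("distortion must be in [0, 1)")
  set.seed(derive_seed(seed, 11))
  pieces <- lapply(seq_len(n_chrom), function(cc) {
    m <- markers_per_chrom[cc]
    len <- chrom_length_cM[cc]
    cm <- seq(0, len, length.out = m)
    phase <- stats::runif(1, 0, 2 * pi)
    rate <- mb_per_cM * (1 + distortion * sin(2 * pi * cm / len + phase))
    mb <- 1 + cumsum(c(0, (diff(cm)) * (rate[-m] + rate[-1L]) / 2))
    data.frame(marker = sprintf("MK%d_%03d", cc, seq_len(m)),
               chrom = as.character(cc), pos_cM = cm, pos_Mb = mb,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, pieces)
  genetic_map(d$marker, d$chrom, d$pos_cM, d$pos_Mb)
}

#' Simulate RIL genomes by single-seed descent
#'
#' Starting from the F1 of a biparental cross, each line is advanced by
#' selfing to the requested filial generation.  Meiosis follows the Haldane
#' model: crossovers on each chromosome are a Poisson process on the cM scale
#' with mean `length/100` Morgans and no interference.  Residual
#' heterozygotes are retained and coded `Het` (expected frequency
#' `(1/2)^(generations-1)` per locus at F_generations).
#'
#' @param map A [genetic_map()].
#' @param n_lines Number of lines (>= 1).
#' @param generations Filial generation number (F_g, >= 2); default 11 (F11),
#'   i.e. 10 rounds of selfing from the F1.
#' @param seed RNG seed; a fixed seed reproduces the matrix exactly.
#' @return A [geno_matrix()] of codes `P1`/`P2`/`Het`.
#' @export
simulate_ril_genomes <- function(map, n_lines, generations = 11, seed = 1) {
  stopifnot(inherits(map, "genmap"))
  n_lines <- check_count(n_lines, "n_lines")
  generations <- check_count(generations, "generations", min = 2L)
  set.seed(derive_seed(seed, 23))
  chroms <- chrom_levels(map)
  out <- matrix(0L, n_lines, nrow(map))
  for (cc in chroms) {
    mi <- which(map$chrom == cc)
    pos <- map$pos_cM[mi] - min(map$pos_cM[mi])
    len <- max(pos)
    m <- length(mi)
    for (i in seq_len(n_lines)) {
      h1 <- rep(0L, m); h2 <- rep(1L, m)  # F1 haplotypes
      for (g in seq_len(generations - 1L)) {
        g1 <- sim_gamete(h1, h2, pos, len)
        g2 <- sim_gamete(h1, h2, pos, len)
        h1 <- g1; h2 <- g2
      }
      out[i, mi] <- h1 + h2
    }
  }
  codes <- matrix("Het", n_lines, nrow(map))
  codes[out == 0L] <- "P1"
  codes[out == 2L] <- "P2"
  dimnames(codes) <- list(sprintf("L%03d", seq_len(n_lines)), map$marker)
  geno_matrix(codes, map)
}

# one gamete from a haplotype pair; positions relative to chromosome start
sim_gamete <- function(h1, h2, pos, len) {
  nxo <- stats::rpois(1L, len / 100)
  start <- sample.int(2L, 1L)
  if (nxo == 0L) return(if (start == 1L) h1 else h2)
  xo <- sort(stats::runif(nxo, 0, len))
  seg <- findInterval(pos, xo, left.open = TRUE) + start
  ifelse(seg %% 2L == 1L, h1, h2)
}

#' Environment structure for a multi-environment trial
#'
#' @param locations Character vector of location codes (>= 1).
#' @param years Character vector of year codes (>= 1).
#' @param reps Replicates per location-year environment (>= 1).
#' @return A list of class `"env_spec"`.
#' @export
env_spec <- function(locations = c("S", "X"), years = c("15", "16"), reps = 2) {
  locations <- as.character(locations); years <- as.character(years)
  if (!length(locations) || !length(years)) stop_bad("need >= 1 location and year")
  reps <- check_count(reps, "reps")
  structure(list(locations = locations, years = years, reps = reps),
            class = "env_spec")
}

#' Trait architecture for the phenotype simulator
#'
#' Houses the generative truth for one trait: QTL positions and effects for
#' the line per se model and tester-specific effects for the testcross model,
#' plus all variance components (trait-variance units).  Additive effects use
#' the half-difference convention: an effect `a` means P2/P2 lines exceed
#' P1/P1 lines by `2a`; a positive sign means the male-parent (P2) allele
#' increases the trait.
#'
#' Residual SDs may be given directly (`sd_e`, `sd_e_h`) or left `NULL` with
#' target heritabilities supplied instead, in which case
#' [simulate_phenotypes()] solves for the residual SD that yields the target
#' Knapp heritability given the realized genetic variance.
#'
#' @param trait Trait name.
#' @param qtl data.frame with columns `chrom`, `pos_cM`, `add` (per se
#'   effect) and one `add_<tester>` column per tester (testcross effects).
#' @param mu,mu_hybrid Trait intercepts for lines and hybrids.
#' @param tester_effects Named numeric vector of tester main effects.
#' @param sd_env,sd_block SDs of the environment (location-year) main effect
#'   and the rep-within-environment block effect.
#' @param sd_gl,sd_gy,sd_gly Per se genotype-by-environment interaction SDs.
#' @param sd_e Per se residual SD, or `NULL` to solve from `h2`.
#' @param sd_gl_h,sd_gy_h,sd_gly_h,sd_e_h Hybrid-side counterparts.
#' @param h2 Target per se broad-sense heritability (used when `sd_e` is NULL).
#' @param h2_tc Target testcross heritability (used when `sd_e_h` is NULL).
#' @param h2_tc_basis Scale on which `h2_tc` is interpreted: the Knapp
#'   `"entry_mean"` heritability or the `"plot"`-level heritability (see
#'   [resid_sd_for_h2()]).
#' @return A list of class `"trait_arch"`.
#' @export
trait_arch <- function(trait, qtl, mu = 0, mu_hybrid = mu,
                       tester_effects = NULL,
                       sd_env = 0, sd_block = 0,
                       sd_gl = 0, sd_gy = 0, sd_gly = 0, sd_e = NULL,
                       sd_gl_h = 0, sd_gy_h = 0, sd_gly_h = 0, sd_e_h = NULL,
                       h2 = 0.8, h2_tc = 0.6,
                       h2_tc_basis = c("entry_mean", "plot")) {
  qtl <- as.data.frame(qtl)
  if (!all(c("chrom", "pos_cM", "add") %in% names(qtl)))
    stop_bad("qtl table needs columns chrom, pos_cM, add")
  qtl$chrom <- as.character(qtl$chrom)
  sds <- c(sd_env, sd_block, sd_gl, sd_gy, sd_gly, sd_gl_h, sd_gy_h, sd_gly_h,
           sd_e %||% 0, sd_e_h %||% 0)
  if (any(sds < 0)) stop_bad("all SDs must be >= 0")
  structure(list(trait = as.character(trait), qtl = qtl, mu = mu,
                 mu_hybrid = mu_hybrid, tester_effects = tester_effects,
                 sd_env = sd_env, sd_block = sd_block,
                 sd_gl = sd_gl, sd_gy = sd_gy, sd_gly = sd_gly, sd_e = sd_e,
                 sd_gl_h = sd_gl_h, sd_gy_h = sd_gy_h, sd_gly_h = sd_gly_h,
                 sd_e_h = sd_e_h, h2 = h2, h2_tc = h2_tc,
                 h2_tc_basis = match.arg(h2_tc_basis)),
            class = "trait_arch")
}

#' A three-locus contrast architecture (shared / per-se-only / GCA-only)
#'
#' Builds the canonical test architecture: one QTL affecting both the line
#' per se trait and its GCA (same sign), one affecting the per se trait only,
#' and one injected only into the tester-interaction effects so it is visible
#' to the GCA scan but invisible per se.  Small-effect background loci on the
#' remaining chromosomes bring total genetic variance to a realistic level
#' without being individually detectable.
#'
#' @param map A [genetic_map()] with at least 4 chromosomes.
#' @param trait Trait name.
#' @param testers Tester ids (>= 2).
#' @param pve Approximate phenotypic variance explained by each focal locus
#'   on its own scale (fraction of line-mean variance).
#' @param pve_background Total variance fraction carried by background loci.
#' @param n_background Number of background loci.
#' @param h2,h2_tc Target per se and testcross heritabilities (`h2_tc` on
#'   the basis given by `h2_tc_basis`; the plot basis is the default here
#'   because the testcross world is stated in single-plot terms).
#' @return A [trait_arch()]; focal positions are recorded in attribute
#'   `"focal"`.
#' @export
contrast_architecture <- function(map, trait = "T1", testers = c("TC", "TM"),
                                  pve = 0.18, pve_background = 0.30,
                                  n_background = 14, h2 = 0.7, h2_tc = 0.6,
                                  h2_tc_basis = "plot") {
  stopifnot(inherits(map, "genmap"))
  chroms <- chrom_levels(map)
  if (length(chroms) < 4L) stop_bad("contrast architecture needs >= 4 chromosomes")
  mid <- function(cc) {
    p <- map$pos_cM[map$chrom == cc]
    p[which.min(abs(p - stats::median(p)))]
  }
  a_focal <- sqrt(pve)
  a_bg <- sqrt(pve_background / n_background)
  bg_chroms <- rep_len(chroms[-(1:3)], n_background)
  bg_pos <- numeric(n_background)
  for (cc in unique(bg_chroms)) {
    ii <- which(bg_chroms == cc)
    p <- map$pos_cM[map$chrom == cc]
    bg_pos[ii] <- stats::quantile(p, probs = seq(0.25, 0.75, length.out = length(ii)),
                                  names = FALSE)
  }
  qtl <- data.frame(
    chrom = c(chroms[1:3], bg_chroms),
    pos_cM = c(mid(chroms[1L]), mid(chroms[2L]), mid(chroms[3L]), bg_pos),
    add = c(a_focal, a_focal, 0, rep(a_bg, n_background)),
    stringsAsFactors = FALSE)
  for (t in testers)
    qtl[[paste0("add_", t)]] <- c(a_focal, 0, a_focal, rep(a_bg, n_background))
  arch <- trait_arch(trait, qtl, mu = 10, mu_hybrid = 12,
                     tester_effects = stats::setNames(
                       seq_along(testers) - (length(testers) + 1) / 2, testers),
                     sd_env = 0.5, sd_block = 0.1,
                     sd_gl = sqrt(0.08), sd_gy = sqrt(0.08), sd_gly = sqrt(0.08),
                     sd_gl_h = sqrt(0.05), sd_gy_h = sqrt(0.05),
                     sd_gly_h = sqrt(0.05),
                     h2 = h2, h2_tc = h2_tc, h2_tc_basis = h2_tc_basis)
  attr(arch, "focal") <- data.frame(
    role = c("shared", "perse_only", "gca_only"),
    chrom = chroms[1:3],
    pos_cM = qtl$pos_cM[1:3], stringsAsFactors = FALSE)
  arch
}

check_qtl_on_map <- function(qtl, map, trait) {
  for (k in seq_len(nrow(qtl))) {
    cc <- qtl$chrom[k]
    if (!(cc %in% map$chrom))
      stop_bad("trait %s: QTL chromosome %s is not on the map", trait, cc)
    p <- map$pos_cM[map$chrom == cc]
    if (qtl$pos_cM[k] < min(p) || qtl$pos_cM[k] > max(p))
      stop_bad("trait %s: QTL position %g cM is off chromosome %s (range %g-%g)",
               trait, qtl$pos_cM[k], cc, min(p), max(p))
  }
  invisible(TRUE)
}

# expected genotype dosage (signed scale) at arbitrary cM positions: nearest
# marker's signed score (architecture positions default to marker positions)
signed_at_positions <- function(geno, map, chrom, pos_cM) {
  s <- geno_signed(geno)
  idx <- vapply(seq_along(chrom), function(k) {
    mi <- which(map$chrom == chrom[k])
    mi[which.min(abs(map$pos_cM[mi] - pos_cM[k]))]
  }, integer(1))
  s[, idx, drop = FALSE]
}

#' Residual SD achieving a target Knapp heritability
#'
#' Solves `h2 = g_var / (g_var + gl2/L + gy2/Y + gly2/(L Y) + e2/(L Y R))`
#' for the residual SD `sqrt(e2)` given the other components.
#'
#' @param g_var Genetic variance among entry means.
#' @param h2 Target heritability in (0, 1].
#' @param L,Y,R Numbers of locations, years, reps.
#' @param sd_gl,sd_gy,sd_gly Interaction SDs.
#' @param n_obs_scale Extra divisor on interaction/error terms (used for
#'   testcross line means, where each line mean additionally averages over
#'   testers).
#' @param basis `"entry_mean"` targets the Knapp entry-mean heritability
#'   (noise averaged over environments and reps); `"plot"` targets the
#'   plot-level heritability (genetic variance over total single-plot
#'   variance).
#' @return Residual SD (single number).
#' @export
resid_sd_for_h2 <- function(g_var, h2, L, Y, R, sd_gl = 0, sd_gy = 0,
                            sd_gly = 0, n_obs_scale = 1,
                            basis = c("entry_mean", "plot")) {
  basis <- match.arg(basis)
  h2 <- check_number(h2, "h2", min = 1e-6, max = 1)
  noise <- g_var * (1 - h2) / h2
  e2 <- if (basis == "plot")
    noise - sd_gl^2 - sd_gy^2 - sd_gly^2
  else
    (noise - sd_gl^2 / (L * n_obs_scale) - sd_gy^2 / (Y * n_obs_scale) -
       sd_gly^2 / (L * Y * n_obs_scale)) * (L * Y * R * n_obs_scale)
  if (e2 < 0)
    stop_bad("target h2 = %g is unattainable with the given interaction SDs", h2)
  sqrt(e2)
}

#' Simulate multi-environment phenotypes for RILs and their testcross hybrids
#'
#' Generates plot-level records under the additive generative model.  Line
#' per se records follow `mu + sum_q a_q s_q + env + block + GxL + GxY +
#' GxLxY + error`, with `s_q` the signed genotype score at QTL `q`.  Hybrid
#' records follow `mu_H + tester + sum_q a_q^(t) s_q + env + block +
#' (hybrid x env interactions) + error`.  The line's true GCA is the mean
#' over testers of its testcross genetic value, centered over lines, and is
#' returned as ground truth.
#'
#' @param geno RIL genotype matrix.
#' @param map The matching [genetic_map()].
#' @param archs A [trait_arch()] or list of them.
#' @param design A [build_ncii_design()] whose lines are rows of `geno`.
#' @param env A [env_spec()].
#' @param seed RNG seed.
#' @return List of class `"sim_phenotypes"`: `pheno` (long-format table) and
#'   `truth` (per trait: genetic values, true GCA, variance components used,
#'   true per se and testcross heritabilities, QTL table).
#' @export
simulate_phenotypes <- function(geno, map, archs, design, env, seed = 1) {
  stopifnot(inherits(design, "ncii_design"), inherits(env, "env_spec"))
  if (inherits(archs, "trait_arch")) archs <- list(archs)
  lines <- rownames(geno)
  if (!all(design$line_ids %in% lines))
    stop_bad("design lines are missing from the genotype matrix")
  L <- length(env$locations); Y <- length(env$years); R <- env$reps
  testers <- design$tester_ids
  Tn <- length(testers)
  set.seed(derive_seed(seed, 37))

  envs <- expand.grid(location = env$locations, year = env$years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nE <- nrow(envs)

  pheno_list <- list()
  truth <- list()
  for (arch in archs) {
    check_qtl_on_map(arch$qtl, map, arch$trait)
    s <- signed_at_positions(geno, map, arch$qtl$chrom, arch$qtl$pos_cM)
    g_perse <- arch$mu + as.vector(s %*% arch$qtl$add)
    names(g_perse) <- lines
    tcols <- paste0("add_", testers)
    missing_t <- setdiff(tcols, names(arch$qtl))
    if (length(missing_t) && Tn > 0)
      stop_bad("trait %s: qtl table lacks columns %s", arch$trait,
               paste(missing_t, collapse = ", "))
    a_tc <- as.matrix(arch$qtl[, tcols, drop = FALSE])
    tau <- arch$tester_effects %||% stats::setNames(rep(0, Tn), testers)
    # hybrid genetic values, lines x testers
    g_hyb <- matrix(arch$mu_hybrid, length(lines), Tn,
                    dimnames = list(lines, testers))
    for (t in seq_len(Tn))
      g_hyb[, t] <- g_hyb[, t] + tau[testers[t]] + as.vector(s %*% a_tc[, t])
    gca_true <- rowMeans(g_hyb) - mean(rowMeans(g_hyb))

    # residual SDs: honor explicit values, else solve for target h2
    keep <- design$line_ids
    var_g <- stats::var(g_perse[keep])
    sd_e <- arch$sd_e %||% resid_sd_for_h2(var_g, arch$h2, L, Y, R,
                                           arch$sd_gl, arch$sd_gy, arch$sd_gly)
    var_gca <- stats::var(gca_true[keep])
    sd_e_h <- arch$sd_e_h %||% resid_sd_for_h2(var_gca, arch$h2_tc, L, Y, R,
                                               arch$sd_gl_h, arch$sd_gy_h,
                                               arch$sd_gly_h,
                                               n_obs_scale = Tn,
                                               basis = arch$h2_tc_basis %||% "entry_mean")
    h2_true <- var_g / (var_g + arch$sd_gl^2 / L + arch$sd_gy^2 / Y +
                          arch$sd_gly^2 / (L * Y) + sd_e^2 / (L * Y * R))
    h2_tc_true <- var_gca /
      (var_gca + arch$sd_gl_h^2 / (L * Tn) + arch$sd_gy_h^2 / (Y * Tn) +
         arch$sd_gly_h^2 / (L * Y * Tn) + sd_e_h^2 / (L * Y * R * Tn))

    env_eff <- stats::rnorm(nE, 0, arch$sd_env)
    block_eff <- matrix(stats::rnorm(nE * R, 0, arch$sd_block), nE, R)

    # per se records for all design lines
    nl <- length(keep)
    gl <- matrix(stats::rnorm(nl * L, 0, arch$sd_gl), nl, L,
                 dimnames = list(keep, env$locations))
    gy <- matrix(stats::rnorm(nl * Y, 0, arch$sd_gy), nl, Y,
                 dimnames = list(keep, env$years))
    gly <- matrix(stats::rnorm(nl * nE, 0, arch$sd_gly), nl, nE,
                  dimnames = list(keep, NULL))
    perse <- do.call(rbind, lapply(seq_len(nE), function(e) {
      do.call(rbind, lapply(seq_len(R), function(r) {
        data.frame(entry = keep, population = "RIL",
                   location = envs$location[e], year = envs$year[e],
                   rep = as.character(r), trait = arch$trait,
                   value = g_perse[keep] + env_eff[e] + block_eff[e, r] +
                     gl[, envs$location[e]] + gy[, envs$year[e]] + gly[, e] +
                     stats::rnorm(nl, 0, sd_e),
                   stringsAsFactors = FALSE)
      }))
    }))

    # hybrid records
    ht <- design$hybrid_table
    nh <- nrow(ht)
    env_eff_h <- stats::rnorm(nE, 0, arch$sd_env)
    block_eff_h <- matrix(stats::rnorm(nE * R, 0, arch$sd_block), nE, R)
    hgl <- matrix(stats::rnorm(nh * L, 0, arch$sd_gl_h), nh, L,
                  dimnames = list(ht$hybrid, env$locations))
    hgy <- matrix(stats::rnorm(nh * Y, 0, arch$sd_gy_h), nh, Y,
                  dimnames = list(ht$hybrid, env$years))
    hgly <- matrix(stats::rnorm(nh * nE, 0, arch$sd_gly_h), nh, nE,
                   dimnames = list(ht$hybrid, NULL))
    gh <- g_hyb[cbind(ht$line, ht$tester)]
    hyb <- do.call(rbind, lapply(seq_len(nE), function(e) {
      do.call(rbind, lapply(seq_len(R), function(r) {
        data.frame(entry = ht$hybrid, population = ht$tester,
                   location = envs$location[e], year = envs$year[e],
                   rep = as.character(r), trait = arch$trait,
                   value = gh + env_eff_h[e] + block_eff_h[e, r] +
                     hgl[, envs$location[e]] + hgy[, envs$year[e]] + hgly[, e] +
                     stats::rnorm(nh, 0, sd_e_h),
                   stringsAsFactors = FALSE)
      }))
    }))
    pheno_list[[arch$trait]] <- rbind(perse, hyb)
    truth[[arch$trait]] <- list(
      qtl = arch$qtl, g_perse = g_perse, g_hybrid = g_hyb,
      gca_true = gca_true - mean(gca_true[keep]),
      sd_e = sd_e, sd_e_h = sd_e_h,
      h2_true = h2_true, h2_tc_true = h2_tc_true,
      var_g = var_g, var_gca = var_gca,
      focal = attr(arch, "focal"))
  }
  pheno <- do.call(rbind, pheno_list)
  rownames(pheno) <- NULL
  structure(list(pheno = pheno, truth = truth, design = design, env = env),
            class = "sim_phenotypes")
}
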