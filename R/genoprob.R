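#' Genotype probabilities at markers and pseudomarkers
#'
#' Computes, for every line and every evaluation position (the observed
#' markers plus a pseudomarker grid at `step_cM`), the probability of P1 and
#' P2 parental ancestry, conditional on all observed markers on the
#' chromosome.  The ancestry process along a RIL chromosome is modelled as a
#' two-state Markov chain whose stepwise transition probabilities are
#' RIL-scale recombination fractions (`ril_recomb(haldane_to_r(d))` for an
#' interval of `d` cM); probabilities are obtained by a forward-backward
#' pass.  Informative markers (`P1`/`P2`) fix the state; `Het` and `Missing`
#' observations are uninformative, so positions between informative markers
#' are conditioned on the nearest informative flanking markers, and a line
#' missing a whole chromosome gets 0.5/0.5 everywhere on it.  At a marker
#' observed `Het` the reported P2 probability is 0.5 (half ancestry from each
#' parent), matching the additive dosage convention.
#'
#' @param geno Genotype matrix (lines x markers) of codes.
#' @param map The [genetic_map()] for the markers.
#' @param step_cM Pseudomarker step in cM (> 0); pseudomarkers are inserted on
#'   a regular grid between the first and last marker of each chromosome.
#' @return An object of class `"genoprob"`: a list with `prob` (lines x
#'   positions matrix of P(P2 ancestry)) and `grid` (data.frame with `id`,
#'   `chrom`, `pos_cM`, `pos_Mb`, `is_marker`).
#' @export
genotype_probabilities <- function(geno, map, step_cM = 1) {
  stopifnot(inherits(map, "genmap"))
  step_cM <- check_number(step_cM, "step_cM")
  if (step_cM <= 0) stop_bad("step_cM must be > 0")
  if (ncol(geno) != nrow(map)) stop_bad("genotypes do not match the map")
  n <- nrow(geno)
  if (n < 1L) stop_bad("no lines in the genotype matrix")

  grids <- lapply(chrom_levels(map), function(cc) {
    mi <- which(map$chrom == cc)
    mcm <- map$pos_cM[mi]
    gcm <- seq(min(mcm), max(mcm), by = step_cM)
    gcm <- gcm[!(gcm %in% mcm)]
    gr <- data.frame(
      id = c(map$marker[mi], sprintf("c%s.loc%g", cc, gcm)),
      chrom = cc,
      pos_cM = c(mcm, gcm),
      pos_Mb = c(map$pos_Mb[mi], interp_mb(mcm, map$pos_Mb[mi], gcm)),
      is_marker = c(rep(TRUE, length(mi)), rep(FALSE, length(gcm))),
      marker_col = c(mi, rep(NA_integer_, length(gcm))),
      stringsAsFactors = FALSE)
    # stable order: by position, markers keep their map order at ties
    gr[order(gr$pos_cM, !gr$is_marker), , drop = FALSE]
  })
  grid <- do.call(rbind, grids)
  rownames(grid) <- NULL

  prob <- matrix(NA_real_, n, nrow(grid),
                 dimnames = list(rownames(geno), grid$id))
  offset <- 0L
  for (gr in grids) {
    m <- nrow(gr)
    cols <- offset + seq_len(m)
    # stepwise RIL-scale transition probabilities
    rstep <- ril_recomb(haldane_to_r(pmax(diff(gr$pos_cM), 0)))
    rstep <- pmax(rstep, 1e-12)  # guard: discordant markers at 0 cM
    # emissions: n x m each for states (P1, P2)
    e1 <- matrix(1, n, m); e2 <- matrix(1, n, m)
    mk <- which(gr$is_marker)
    obs <- geno[, gr$marker_col[mk], drop = FALSE]
    e1[, mk][obs == "P2"] <- 0
    e2[, mk][obs == "P1"] <- 0
    # forward
    f1 <- matrix(0, n, m); f2 <- matrix(0, n, m)
    f1[, 1L] <- 0.5 * e1[, 1L]; f2[, 1L] <- 0.5 * e2[, 1L]
    for (j in seq_len(m - 1L)) {
      r <- rstep[j]
      a1 <- f1[, j] * (1 - r) + f2[, j] * r
      a2 <- f1[, j] * r + f2[, j] * (1 - r)
      f1[, j + 1L] <- a1 * e1[, j + 1L]
      f2[, j + 1L] <- a2 * e2[, j + 1L]
      s <- f1[, j + 1L] + f2[, j + 1L]
      s[s == 0] <- 1
      f1[, j + 1L] <- f1[, j + 1L] / s
      f2[, j + 1L] <- f2[, j + 1L] / s
    }
    # backward
    b1 <- matrix(0, n, m); b2 <- matrix(0, n, m)
    b1[, m] <- 1; b2[, m] <- 1
    for (j in seq(m - 1L, length.out = m - 1L, by = -1L)) {
      r <- rstep[j]
      u1 <- b1[, j + 1L] * e1[, j + 1L]
      u2 <- b2[, j + 1L] * e2[, j + 1L]
      b1[, j] <- u1 * (1 - r) + u2 * r
      b2[, j] <- u1 * r + u2 * (1 - r)
      s <- b1[, j] + b2[, j]
      s[s == 0] <- 1
      b1[, j] <- b1[, j] / s
      b2[, j] <- b2[, j] / s
    }
    p2 <- (f2 * b2) / (f1 * b1 + f2 * b2)
    p2[!is.finite(p2)] <- 0.5
    # observed heterozygotes: half ancestry from each parent
    if (length(mk)) {
      het <- obs == "Het"
      sub <- p2[, mk, drop = FALSE]
      sub[het] <- 0.5
      p2[, mk] <- sub
    }
    prob[, cols] <- p2
    offset <- offset + m
  }
  structure(list(prob = prob, grid = grid, step_cM = step_cM),
            class = "genoprob")
}

# monotone interpolation of Mb at pseudomarker cM positions
interp_mb <- function(mcm, mmb, gcm) {
  if (length(gcm) == 0L) return(numeric(0))
  if (any(!is.finite(mmb))) return(rep(NA_real_, length(gcm)))
  if (length(unique(mcm)) < 2L) return(rep(mmb[1L], length(gcm)))
  stats::approx(mcm, mmb, xout = gcm, ties = "ordered", rule = 2)$y
}

#' @export
print.genoprob <- function(x, ...) {
  cat(sprintf("genotype probabilities: %d lines x %d positions (%d markers, step %g cM)\n",
              nrow(x$prob), nrow(x$grid), sum(x$grid$is_marker), x$step_cM))
  invisible(x)
}
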