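# Haley-Knott interval mapping and composite interval mapping on expected
# genotype dosages, permutation thresholds, support intervals, PVE and
# signed additive effects.
#
# LOD convention: LOD = (n/2) * log10(RSS0 / RSS1), RSS0 from the
# covariate-only fit.  Degenerate zero-residual fits are capped at LOD_CAP
# to avoid infinities while preserving peak ordering.

LOD_CAP <- 50

# core engine: partial correlations of columns of X with columns of Y after
# residualizing both on [1 | Z]; returns LOD and additive-effect matrices
scan_core <- function(X, Y, Z = NULL, lod_cap = LOD_CAP) {
  n <- nrow(X)
  B <- cbind(rep(1, n), Z)
  Q <- qr.Q(qr(B))
  Xr <- X - Q %*% crossprod(Q, X)
  Yr <- Y - Q %*% crossprod(Q, Y)
  sx2 <- colSums(Xr^2)
  sy2 <- colSums(Yr^2)
  num <- crossprod(Xr, Yr)                    # p x m
  den <- outer(sx2, sy2)
  r2 <- num^2 / den
  r2[den <= 0] <- 0
  r2 <- pmin(r2, 1)
  lod <- -(n / 2) * log10(1 - r2)
  lod[!is.finite(lod) | lod > lod_cap] <- lod_cap
  slope <- num / sx2
  slope[sx2 <= 0, ] <- 0
  list(lod = lod, add = slope / 2)
}

align_response <- function(probs, y, covariates = NULL) {
  y <- stats::setNames(as.numeric(y), names(y))  # tolerate 1-d arrays
  lines <- rownames(probs$prob)
  if (!is.null(names(y))) {
    if (!all(names(y) %in% lines))
      stop_bad("response has lines absent from the genotype probabilities")
    idx <- match(names(y), lines)
  } else {
    if (length(y) != length(lines))
      stop_bad("unnamed response must have one value per line (%d)", length(lines))
    idx <- seq_along(lines)
  }
  keep <- is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(y))
      stop_bad("covariates must have one row per response value")
    keep <- keep & apply(is.finite(covariates), 1L, all)
    covariates <- covariates[keep, , drop = FALSE]
  }
  list(X = probs$prob[idx[keep], , drop = FALSE], y = y[keep], Z = covariates)
}

new_scanresult <- function(grid, lod, add, n, meta = list()) {
  out <- data.frame(id = grid$id, chrom = grid$chrom, pos_cM = grid$pos_cM,
                    pos_Mb = grid$pos_Mb, lod = as.numeric(lod),
                    add = as.numeric(add), stringsAsFactors = FALSE)
  attr(out, "n") <- n
  attr(out, "meta") <- meta
  class(out) <- c("scanresult", "data.frame")
  out
}

#' Genome scan by Haley-Knott regression
#'
#' At each evaluation position the response is regressed on the expected
#' genotype dosage (plus optional covariates);
#' `LOD = (n/2) log10(RSS0/RSS1)` with `RSS0` the covariate-only fit.  The
#' reported additive effect is the regression slope on the dosage scale
#' divided by two (half the difference between parental homozygotes;
#' positive = P2 allele increases the trait).
#'
#' @param probs A [genotype_probabilities()] object.
#' @param y Named (by line) or position-aligned numeric response.
#' @param covariates Optional numeric matrix of covariates (rows = entries of
#'   `y`).
#' @return A `"scanresult"` data.frame: `id`, `chrom`, `pos_cM`, `pos_Mb`,
#'   `lod`, `add`.
#' @export
scan_hk <- function(probs, y, covariates = NULL) {
  al <- align_response(probs, y, covariates)
  if (length(al$y) < 3L) stop_bad("need at least 3 lines with data")
  if (stats::sd(al$y) == 0) {
    warning("response has zero variance; returning all-zero LOD", call. = FALSE)
    return(new_scanresult(probs$grid, 0, 0, length(al$y)))
  }
  sc <- scan_core(al$X, matrix(al$y), al$Z)
  new_scanresult(probs$grid, sc$lod, sc$add, length(al$y))
}

#' Forward stepwise cofactor selection
#'
#' Selects up to `n_cofactors` markers by greedy forward selection minimizing
#' the residual sum of squares of the multiple regression of `y` on the
#' chosen marker dosages.  Ties are broken deterministically in favour of the
#' lowest marker index.  Missing dosages are mean-imputed per marker.
#'
#' @param geno Genotype matrix.
#' @param y Named or aligned numeric response.
#' @param n_cofactors Number of markers to select (0 gives an empty set;
#'   values above the marker count are capped with a warning).
#' @return Character vector of selected marker names, in selection order.
#' @export
select_cofactors <- function(geno, y, n_cofactors) {
  n_cofactors <- check_count(n_cofactors, "n_cofactors", min = 0L)
  if (n_cofactors == 0L) return(character(0))
  y <- stats::setNames(as.numeric(y), names(y))
  X <- geno_dosage(geno)
  if (!is.null(names(y))) {
    X <- X[match(names(y), rownames(X)), , drop = FALSE]
  } else if (length(y) != nrow(X)) stop_bad("response does not match genotypes")
  keep <- is.finite(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
  }
  if (n_cofactors > ncol(X)) {
    warning("n_cofactors exceeds the number of markers; capping", call. = FALSE)
    n_cofactors <- ncol(X)
  }
  n <- length(y)
  Q <- qr.Q(qr(matrix(1, n, 1)))
  Xr <- X - Q %*% crossprod(Q, X)
  yr <- y - Q %*% crossprod(Q, y)
  chosen <- integer(0)
  for (k in seq_len(n_cofactors)) {
    sx2 <- colSums(Xr^2)
    score <- as.vector(crossprod(Xr, yr))^2 / sx2
    score[sx2 <= 1e-12] <- -Inf
    score[chosen] <- -Inf
    if (!any(is.finite(score)) || max(score) <= 0) break
    j <- which.max(score)   # ties resolve to the lowest index
    chosen <- c(chosen, j)
    u <- Xr[, j] / sqrt(sum(Xr[, j]^2))
    Xr <- Xr - u %*% crossprod(u, Xr)
    yr <- yr - u * sum(u * yr)
  }
  colnames(X)[chosen]
}

#' Composite interval mapping
#'
#' A Haley-Knott scan with background cofactor markers as covariates.  At
#' each test position, cofactors lying within `window_cM` of the position on
#' the same chromosome are excluded from the covariate set.  With an empty
#' cofactor set the scan is identical to [scan_hk()].
#'
#' @param probs [genotype_probabilities()] object (cofactor dosages are taken
#'   from its marker columns).
#' @param y Named or aligned response.
#' @param cofactors Character vector of cofactor marker names (as from
#'   [select_cofactors()]).
#' @param window_cM Exclusion window around the test position, in cM.
#' @return A `"scanresult"` data.frame.
#' @export
cim_scan <- function(probs, y, cofactors = character(0), window_cM = 10) {
  if (!length(cofactors)) return(scan_hk(probs, y))
  grid <- probs$grid
  ci <- match(cofactors, grid$id)
  if (anyNA(ci)) stop_bad("cofactors not found in the evaluation grid: %s",
                          paste(cofactors[is.na(ci)], collapse = ", "))
  al <- align_response(probs, y, probs$prob[, ci, drop = FALSE][
    match(names(y) %||% rownames(probs$prob), rownames(probs$prob)), , drop = FALSE])
  if (stats::sd(al$y) == 0) {
    warning("response has zero variance; returning all-zero LOD", call. = FALSE)
    return(new_scanresult(grid, 0, 0, length(al$y)))
  }
  X <- al$X; Zfull <- al$Z
  n <- length(al$y)
  # active cofactor set per position (drop cofactors within the window)
  excl <- matrix(FALSE, nrow(grid), length(ci))
  for (k in seq_along(ci)) {
    excl[, k] <- grid$chrom == grid$chrom[ci[k]] &
      abs(grid$pos_cM - grid$pos_cM[ci[k]]) <= window_cM
  }
  key <- apply(excl, 1L, function(z) paste(which(z), collapse = ","))
  lod <- numeric(nrow(grid)); add <- numeric(nrow(grid))
  for (kk in unique(key)) {
    rows <- which(key == kk)
    drop <- if (nzchar(kk)) as.integer(strsplit(kk, ",")[[1L]]) else integer(0)
    Z <- if (length(drop) < ncol(Zfull)) Zfull[, setdiff(seq_len(ncol(Zfull)), drop), drop = FALSE] else NULL
    sc <- scan_core(X[, rows, drop = FALSE], matrix(al$y), Z)
    lod[rows] <- sc$lod
    add[rows] <- sc$add
  }
  new_scanresult(grid, lod, add, n, meta = list(cofactors = cofactors,
                                                window_cM = window_cM))
}

#' Genome-wide permutation LOD threshold
#'
#' Shuffles the response over lines `n_perm` times (fixed seed), records the
#' genome-wide maximum LOD of each shuffled scan, and returns the empirical
#' `1 - alpha` quantile (type-7 interpolation).
#'
#' @param probs [genotype_probabilities()] object.
#' @param y Named or aligned response.
#' @param covariates Optional covariates (kept fixed to lines while `y` is
#'   shuffled).
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Genome-wide type-I error rate in (0, 1).
#' @param seed RNG seed.
#' @return Single LOD threshold; the vector of permutation maxima is attached
#'   as attribute `"max_lod"`.
#' @export
permutation_threshold <- function(probs, y, covariates = NULL, n_perm = 1000,
                                  alpha = 0.05, seed = 1) {
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_bad("alpha must lie strictly between 0 and 1")
  al <- align_response(probs, y, covariates)
  set.seed(derive_seed(seed, 41))
  n <- length(al$y)
  Y <- vapply(seq_len(n_perm), function(i) al$y[sample.int(n)], numeric(n))
  sc <- scan_core(al$X, Y, al$Z)
  maxlod <- apply(sc$lod, 2L, max)
  structure(stats::quantile(maxlod, 1 - alpha, names = FALSE, type = 7),
            max_lod = maxlod)
}

#' 1.5-LOD support interval around a peak
#'
#' The widest contiguous region on the peak's chromosome where the LOD stays
#' within `drop` of the peak LOD, expanded outward to the nearest evaluated
#' position on each side (`drop = 0` gives the degenerate interval at the
#' peak itself).
#'
#' @param scan A `"scanresult"` data.frame.
#' @param peak Row index of the peak in `scan`.
#' @param drop LOD drop defining the interval (default 1.5).
#' @return List with `lo_cM`, `hi_cM`, `lo_Mb`, `hi_Mb`, `lo_idx`, `hi_idx`.
#' @export
support_interval <- function(scan, peak, drop = 1.5) {
  peak <- check_count(peak, "peak")
  if (peak > nrow(scan)) stop_bad("peak index out of range")
  drop <- check_number(drop, "drop", min = 0)
  rows <- which(scan$chrom == scan$chrom[peak])
  j <- match(peak, rows)
  if (drop == 0) {
    lo <- hi <- j
  } else {
    thr <- scan$lod[peak] - drop
    ok <- scan$lod[rows] >= thr
    lo <- j; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
    hi <- j; while (hi < length(rows) && ok[hi + 1L]) hi <- hi + 1L
    lo <- max(1L, lo - 1L)                 # expand to nearest evaluated position
    hi <- min(length(rows), hi + 1L)
  }
  list(lo_cM = scan$pos_cM[rows[lo]], hi_cM = scan$pos_cM[rows[hi]],
       lo_Mb = scan$pos_Mb[rows[lo]], hi_Mb = scan$pos_Mb[rows[hi]],
       lo_idx = rows[lo], hi_idx = rows[hi])
}

#' Joint multi-QTL fit: model PVE and per-QTL contributions
#'
#' Fits one linear model of the response on the expected dosages at all peak
#' positions.  Model PVE is `100 (1 - RSS_full / RSS_null)`; each QTL's PVE
#' is the drop-one decrease in explained sum of squares (as a percentage of
#' the total).  Peaks whose dosages are nearly collinear (|r| > 0.99) are
#' merged with a warning.
#'
#' @param probs [genotype_probabilities()] object.
#' @param y Named or aligned response.
#' @param positions Row indices into `probs$grid` (or position ids).
#' @return List with `model_pve` and `per_qtl` (data.frame `id`, `pve`,
#'   `add`), plus `kept` (indices actually fitted after merging).
#' @export
fit_qtl_model <- function(probs, y, positions) {
  if (is.character(positions)) positions <- match(positions, probs$grid$id)
  if (anyNA(positions) || !length(positions)) stop_bad("unknown QTL positions")
  al <- align_response(probs, y)
  X <- al$X[, positions, drop = FALSE]
  keep <- seq_along(positions)
  if (length(positions) > 1L) {
    cm <- suppressWarnings(stats::cor(X))
    cm[!is.finite(cm)] <- 0
    drop <- logical(length(positions))
    for (a in seq_along(positions)) for (b in seq_len(a - 1L)) {
      if (!drop[b] && !drop[a] && abs(cm[a, b]) > 0.99) drop[a] <- TRUE
    }
    if (any(drop)) {
      warning(sprintf("merged %d collinear QTL position(s)", sum(drop)), call. = FALSE)
      keep <- which(!drop)
      X <- X[, keep, drop = FALSE]
    }
  }
  yc <- al$y - mean(al$y)
  tss <- sum(yc^2)
  fit_rss <- function(M) {
    if (is.null(M) || ncol(M) == 0L) return(tss)
    sum(stats::lm.fit(cbind(1, M), al$y)$residuals^2)
  }
  rss_full <- fit_rss(X)
  model_pve <- 100 * (1 - rss_full / tss)
  cf <- stats::lm.fit(cbind(1, X), al$y)$coefficients[-1L]
  per <- vapply(seq_len(ncol(X)), function(j) {
    100 * (fit_rss(X[, -j, drop = FALSE]) - rss_full) / tss
  }, numeric(1))
  list(model_pve = model_pve,
       per_qtl = data.frame(id = probs$grid$id[positions[keep]],
                            index = positions[keep], pve = per,
                            add = as.numeric(cf) / 2, stringsAsFactors = FALSE),
       kept = positions[keep])
}

#' Signed additive effect at a position
#'
#' Half the regression slope of the response on the expected dosage at the
#' position: the estimated half-difference between P2 and P1 homozygote
#' means.  Positive values mean the male-parent (P2) allele increases the
#' trait.
#'
#' @param probs [genotype_probabilities()] object.
#' @param y Named or aligned response.
#' @param position Row index into `probs$grid` (or a position id).
#' @return Single signed effect in trait units.
#' @export
additive_effect <- function(probs, y, position) {
  if (is.character(position)) position <- match(position, probs$grid$id)
  position <- check_count(position, "position")
  al <- align_response(probs, y)
  x <- al$X[, position]
  sx2 <- sum((x - mean(x))^2)
  if (sx2 <= 0) return(0)
  sum((x - mean(x)) * al$y) / sx2 / 2
}

#' Call QTL from a scan
#'
#' Declares QTL at local LOD maxima above `threshold`, merging maxima closer
#' than `merge_cM` on the same chromosome (keeping the higher LOD).  Each QTL
#' gets a 1.5-LOD support interval, a drop-one PVE from the joint multi-QTL
#' fit, and the marginal additive effect at its peak.  Names are
#' auto-generated as `q<TRAIT><chrom>-<ordinal>` (ordinal by position within
#' chromosome).
#'
#' @param scan A `"scanresult"`.
#' @param probs The [genotype_probabilities()] used for the scan.
#' @param y The response used for the scan.
#' @param threshold Declaration LOD threshold.
#' @param trait,dataset Labels stored with each record (dataset: an
#'   environment tag or `"joint"`).
#' @param drop LOD drop for support intervals.
#' @param merge_cM Peak-merging distance.
#' @return A `"qtl_records"` data.frame (possibly 0 rows): trait, name,
#'   chrom, dataset, peak/interval coordinates in cM and Mb, lod, pve, add, n.
#' @export
call_qtl <- function(scan, probs, y, threshold, trait = "trait",
                     dataset = "joint", drop = 1.5, merge_cM = 20) {
  peaks <- integer(0)
  for (cc in unique(scan$chrom)) {
    rows <- which(scan$chrom == cc)
    l <- scan$lod[rows]
    cand <- which(l >= threshold &
                    l >= c(-Inf, l[-length(l)]) & l >= c(l[-1L], -Inf))
    if (!length(cand)) next
    cand <- cand[order(-l[cand])]
    kept <- integer(0)
    for (j in cand) {
      if (!length(kept) ||
          all(abs(scan$pos_cM[rows[j]] - scan$pos_cM[rows[kept]]) >= merge_cM))
        kept <- c(kept, j)
    }
    peaks <- c(peaks, rows[kept])
  }
  if (!length(peaks)) return(empty_qtl_records())
  peaks <- sort(peaks)
  fq <- fit_qtl_model(probs, y, peaks)
  peaks <- fq$kept
  recs <- do.call(rbind, lapply(seq_along(peaks), function(k) {
    p <- peaks[k]
    si <- support_interval(scan, p, drop)
    data.frame(trait = trait, name = NA_character_, chrom = scan$chrom[p],
               dataset = dataset, peak_cM = scan$pos_cM[p],
               peak_Mb = scan$pos_Mb[p], lo_cM = si$lo_cM, hi_cM = si$hi_cM,
               lo_Mb = si$lo_Mb, hi_Mb = si$hi_Mb, lod = scan$lod[p],
               pve = fq$per_qtl$pve[k], add = fq$per_qtl$add[k],
               n = attr(scan, "n"), stringsAsFactors = FALSE)
  }))
  for (cc in unique(recs$chrom)) {
    i <- which(recs$chrom == cc)
    recs$name[i] <- sprintf("q%s%s-%d", trait, cc,
                            as.integer(rank(recs$peak_cM[i], ties.method = "first")))
  }
  recs$id <- paste(recs$dataset, recs$name, sep = ":")
  class(recs) <- c("qtl_records", "data.frame")
  recs
}

empty_qtl_records <- function() {
  recs <- data.frame(trait = character(0), name = character(0),
                     chrom = character(0), dataset = character(0),
                     peak_cM = numeric(0), peak_Mb = numeric(0),
                     lo_cM = numeric(0), hi_cM = numeric(0),
                     lo_Mb = numeric(0), hi_Mb = numeric(0),
                     lod = numeric(0), pve = numeric(0), add = numeric(0),
                     n = integer(0), id = character(0),
                     stringsAsFactors = FALSE)
  class(recs) <- c("qtl_records", "data.frame")
  recs
}
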