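# Haley-Knott scans, CIM, permutation thresholds, support intervals, PVE

scan_fixture <- function(n_lines = 200, n_chrom = 2, markers = 15,
                         len = 100, seed = 1) {
  map <- simulate_map(n_chrom, markers, len, seed = seed)
  geno <- simulate_ril_genomes(map, n_lines, 11, seed = seed + 1)
  probs <- genotype_probabilities(geno, map, step_cM = 5)
  list(map = map, geno = geno, probs = probs)
}

# brute-force oracle: per-marker OLS LOD with optional covariates
ols_lod <- function(x, y, Z = NULL) {
  n <- length(y)
  one <- rep(1, n)
  f0 <- stats::lm.fit(cbind(one, Z), y)
  f1 <- stats::lm.fit(cbind(one, Z, x), y)
  (n / 2) * log10(sum(f0$residuals^2) / sum(f1$residuals^2))
}

test_that("a noiseless marker signal peaks at that marker with capped LOD", {
  fx <- scan_fixture(seed = 3)
  y <- geno_dosage(fx$geno)[, 8]
  y[is.na(y)] <- 0.5
  names(y) <- rownames(fx$geno)
  sc <- scan_hk(fx$probs, y)
  # the causal marker reaches the cap; nearby positions may tie at the cap
  expect_true(fx$map$marker[8] %in% sc$id[sc$lod == max(sc$lod)])
  expect_equal(max(sc$lod), 50)
  expect_true(all(sc$lod >= 0))
  capped <- sc[sc$lod == max(sc$lod), ]
  expect_true(all(capped$chrom == fx$map$chrom[8]))
})

test_that("scan_hk equals the exhaustive per-marker OLS oracle", {
  for (seed in 1:5) {
    fx <- scan_fixture(n_lines = 120, markers = 10, seed = 10 + seed)
    set.seed(seed)
    d <- geno_dosage(fx$geno)
    y <- 0.8 * d[, 4] + rnorm(120)
    names(y) <- rownames(fx$geno)
    sc <- scan_hk(fx$probs, y)
    at_marker <- match(fx$map$marker, sc$id)
    oracle <- vapply(seq_len(ncol(d)), function(j) ols_lod(d[, j], y), numeric(1))
    expect_equal(sc$lod[at_marker], oracle, tolerance = 1e-8)
  }
})

test_that("scan_hk LOD is invariant to affine transforms of y", {
  fx <- scan_fixture(n_lines = 100, markers = 8, seed = 21)
  set.seed(2)
  y <- rnorm(100); names(y) <- rownames(fx$geno)
  a <- scan_hk(fx$probs, y)
  b <- scan_hk(fx$probs, -3.2 * y + 17)
  expect_equal(a$lod, b$lod, tolerance = 1e-10)
  expect_equal(b$add, -3.2 * a$add, tolerance = 1e-10)
})

test_that("zero-variance response warns and returns all-zero LOD", {
  fx <- scan_fixture(n_lines = 50, markers = 6, seed = 31)
  y <- rep(2, 50); names(y) <- rownames(fx$geno)
  expect_warning(sc <- scan_hk(fx$probs, y), "zero variance")
  expect_true(all(sc$lod == 0))
})

test_that("cofactor selection: empty set, cap, tie-break, and signal recovery", {
  fx <- scan_fixture(n_lines = 150, markers = 12, seed = 41)
  set.seed(5)
  y <- rnorm(150); names(y) <- rownames(fx$geno)
  expect_identical(select_cofactors(fx$geno, y, 0), character(0))
  expect_warning(cf <- select_cofactors(fx$geno, y, 1000), "capping")
  expect_lte(length(cf), ncol(fx$geno))

  # duplicate marker columns: the lower index wins
  map <- genetic_map(c("a", "b", "c"), c(1, 1, 1), c(0, 5, 5))
  g <- simulate_ril_genomes(map, 100, 11, seed = 6)   # b and c identical
  stopifnot(identical(g[, "b"], g[, "c"]))
  yy <- geno_dosage(g)[, "b"] + rnorm(100, 0, 0.5)
  names(yy) <- rownames(g)
  expect_identical(select_cofactors(g, yy, 1), "b")

  # single QTL with ~20% PVE: first pick lands within 10 cM in >= 8/10 seeds
  hits <- 0L
  for (k in 1:10) {
    fxk <- scan_fixture(n_lines = 150, n_chrom = 2, markers = 21, len = 100,
                        seed = 600 + k)
    dk <- geno_dosage(fxk$geno)
    truth <- which(fxk$map$marker == "MK1_011")
    set.seed(k)
    s <- 2 * dk[, truth] - 1
    yk <- 0.5 * s + rnorm(150, 0, 1)
    names(yk) <- rownames(fxk$geno)
    pick <- select_cofactors(fxk$geno, yk, 1)
    dpos <- abs(fxk$map$pos_cM[match(pick, fxk$map$marker)] -
                  fxk$map$pos_cM[truth])
    same <- fxk$map$chrom[match(pick, fxk$map$marker)] == fxk$map$chrom[truth]
    if (same && dpos <= 10) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("cim_scan reduces to scan_hk without cofactors and obeys the window", {
  fx <- scan_fixture(n_lines = 120, markers = 10, seed = 51)
  set.seed(7)
  y <- rnorm(120); names(y) <- rownames(fx$geno)
  expect_equal(cim_scan(fx$probs, y, character(0)), scan_hk(fx$probs, y))

  # at the cofactor's own position the cofactor is excluded: LOD there equals
  # a scan with the remaining covariates only
  cof <- c("MK1_003", "MK2_007")
  sc <- cim_scan(fx$probs, y, cof, window_cM = 10)
  at <- match("MK1_003", sc$id)
  d <- fx$probs$prob
  z_other <- d[, match("MK2_007", colnames(d))]
  oracle <- ols_lod(d[, match("MK1_003", colnames(d))], y[rownames(d)], z_other)
  expect_equal(sc$lod[at], oracle, tolerance = 1e-8)
  # far from any cofactor both covariates are active
  far <- match("MK2_001", sc$id)
  z_both <- d[, match(cof, colnames(d))]
  expect_equal(sc$lod[far],
               ols_lod(d[, match("MK2_001", colnames(d))], y[rownames(d)], z_both),
               tolerance = 1e-8)
})

test_that("CIM localizes two linked QTL better than plain HK", {
  hits_cim <- 0L; hits_hk <- 0L
  for (k in 1:10) {
    map <- simulate_map(1, 41, 120, seed = 700 + k)   # markers every 3 cM
    g <- simulate_ril_genomes(map, 250, 11, seed = 800 + k)
    d <- geno_dosage(g)
    q1 <- which.min(abs(map$pos_cM - 40)); q2 <- which.min(abs(map$pos_cM - 80))
    set.seed(k)
    y <- (2 * d[, q1] - 1) * 0.5 + (2 * d[, q2] - 1) * 0.5 + rnorm(250, 0, 1)
    names(y) <- rownames(g)
    probs <- genotype_probabilities(g, map, step_cM = 3)
    cof <- select_cofactors(g, y, 3)
    sc <- cim_scan(probs, y, cof, window_cM = 10)
    sh <- scan_hk(probs, y)
    near <- function(scan) {
      pk <- call_qtl(scan, probs, y, threshold = 3, merge_cM = 20)
      if (nrow(pk) < 1) return(FALSE)
      d1 <- min(abs(pk$peak_cM - map$pos_cM[q1]))
      d2 <- min(abs(pk$peak_cM - map$pos_cM[q2]))
      d1 <= 10 && d2 <= 10
    }
    if (near(sc)) hits_cim <- hits_cim + 1L
    if (near(sh)) hits_hk <- hits_hk + 1L
  }
  expect_gte(hits_cim, 8L)
  expect_gte(hits_cim, hits_hk)
})

test_that("permutation thresholds are deterministic and monotone in alpha", {
  fx <- scan_fixture(n_lines = 100, markers = 10, seed = 61)
  set.seed(3)
  y <- rnorm(100); names(y) <- rownames(fx$geno)
  t1 <- permutation_threshold(fx$probs, y, n_perm = 120, alpha = 0.05, seed = 4)
  t2 <- permutation_threshold(fx$probs, y, n_perm = 120, alpha = 0.05, seed = 4)
  expect_identical(as.numeric(t1), as.numeric(t2))
  t10 <- permutation_threshold(fx$probs, y, n_perm = 120, alpha = 0.10, seed = 4)
  t01 <- permutation_threshold(fx$probs, y, n_perm = 120, alpha = 0.01, seed = 4)
  expect_lte(t10, t1)
  expect_lte(t1, t01)
  expect_error(permutation_threshold(fx$probs, y, n_perm = 50), "100")
  expect_error(permutation_threshold(fx$probs, y, n_perm = 120, alpha = 1.2),
               "alpha")
})

test_that("null scans rarely exceed the permutation threshold", {
  fx <- scan_fixture(n_lines = 150, n_chrom = 3, markers = 15, seed = 71)
  set.seed(9)
  y0 <- rnorm(150); names(y0) <- rownames(fx$geno)
  thr <- permutation_threshold(fx$probs, y0, n_perm = 200, alpha = 0.05, seed = 5)
  exceed <- 0L
  for (k in 1:30) {
    y <- rnorm(150); names(y) <- rownames(fx$geno)
    if (max(scan_hk(fx$probs, y)$lod) > thr) exceed <- exceed + 1L
  }
  expect_lte(exceed, 4L)   # ~5% expected; allow Monte-Carlo slack
})

test_that("support intervals implement the 1.5-LOD drop rule", {
  mk_scan <- function(lod, pos = seq(0, by = 10, length.out = length(lod))) {
    s <- data.frame(id = sprintf("p%d", seq_along(lod)), chrom = "1",
                    pos_cM = pos, pos_Mb = pos, lod = lod, add = 0,
                    stringsAsFactors = FALSE)
    class(s) <- c("scanresult", "data.frame")
    attr(s, "n") <- 100
    s
  }
  sc <- mk_scan(c(1, 2, 5, 2, 1))
  si <- support_interval(sc, 3, drop = 1.5)
  expect_equal(c(si$lo_cM, si$hi_cM), c(10, 30))

  # drop = 0: degenerate interval at the peak
  si0 <- support_interval(sc, 3, drop = 0)
  expect_equal(c(si0$lo_cM, si0$hi_cM), c(20, 20))

  # flat curve: whole chromosome
  sif <- support_interval(mk_scan(rep(2, 5)), 3, drop = 1.5)
  expect_equal(c(sif$lo_cM, sif$hi_cM), c(0, 40))

  # interval clamped at chromosome ends
  sce <- mk_scan(c(5, 4.2, 1, 1, 1))
  sie <- support_interval(sce, 1, drop = 1.5)
  expect_equal(sie$lo_cM, 0)
  expect_equal(sie$hi_cM, 20)
})

test_that("fit_qtl_model: exact fit, random-regressor PVE, additivity", {
  fx <- scan_fixture(n_lines = 200, markers = 15, seed = 81)
  d <- geno_dosage(fx$geno)
  # noiseless single QTL explains 100%
  y <- d[, 5]; y[is.na(y)] <- 0.5; names(y) <- rownames(fx$geno)
  f <- fit_qtl_model(fx$probs, y, fx$map$marker[5])
  expect_equal(f$model_pve, 100, tolerance = 1e-8)

  # pure noise, one random position: E[R2] = 1/(n-1) ~ 100/n
  set.seed(12)
  pves <- replicate(60, {
    yy <- rnorm(200); names(yy) <- rownames(fx$geno)
    fit_qtl_model(fx$probs, yy, sample(nrow(fx$probs$grid), 1))$model_pve
  })
  expect_lt(abs(mean(pves) - 100 / 200), 0.35)

  # two orthogonal QTL with ~10% and ~20% PVE sum to ~30%
  pves2 <- replicate(12, {
    fx2 <- scan_fixture(n_lines = 300, n_chrom = 2, markers = 11,
                        seed = sample.int(1e4, 1))
    d2 <- geno_dosage(fx2$geno)
    s1 <- 2 * d2[, 3] - 1; s2 <- 2 * d2[, 14] - 1   # different chromosomes
    yy <- sqrt(0.10) * s1 + sqrt(0.20) * s2 +
      rnorm(300, 0, sqrt(1 - 0.30))
    names(yy) <- rownames(fx2$geno)
    fit_qtl_model(fx2$probs, yy,
                  c(fx2$map$marker[3], fx2$map$marker[14]))$model_pve
  })
  expect_lt(abs(mean(pves2) - 30), 5)

  # collinear peaks are merged with a warning
  expect_warning(fc <- fit_qtl_model(fx$probs, y, fx$map$marker[c(5, 5)]),
                 "collinear")
  expect_equal(nrow(fc$per_qtl), 1L)
})

test_that("additive effects are signed half-differences", {
  map <- genetic_map(c("a", "b"), c(1, 1), c(0, 50))
  g <- simulate_ril_genomes(map, 300, 11, seed = 91)
  probs <- genotype_probabilities(g, map, step_cM = 50)
  d <- geno_dosage(g)[, 1]
  hom <- d %in% c(0, 1)
  y <- ifelse(d == 1, 2, 0); y[!hom] <- 1
  names(y) <- rownames(g)
  expect_equal(additive_effect(probs, y, "a"), 1, tolerance = 1e-9)
  expect_equal(additive_effect(probs, -y + 2, "a"), -1, tolerance = 1e-9)

  # recovery of a = 0.5 at n = 328 with h2 ~ 0.8
  hits <- 0L
  for (k in 1:10) {
    gk <- simulate_ril_genomes(map, 328, 11, seed = 1000 + k)
    pk <- genotype_probabilities(gk, map, step_cM = 50)
    set.seed(k)
    s <- 2 * geno_dosage(gk)[, 1] - 1
    yk <- 0.5 * s + rnorm(328, 0, 0.25)
    names(yk) <- rownames(gk)
    if (abs(additive_effect(pk, yk, "a") - 0.5) <= 0.15) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("call_qtl merges nearby maxima and labels records", {
  fx <- scan_fixture(n_lines = 250, n_chrom = 2, markers = 21, len = 100,
                     seed = 95)
  d <- geno_dosage(fx$geno)
  set.seed(14)
  s <- 2 * d[, 11] - 1
  y <- 0.7 * s + rnorm(250, 0, 1)
  names(y) <- rownames(fx$geno)
  sc <- scan_hk(fx$probs, y)
  rec <- call_qtl(sc, fx$probs, y, threshold = 3, trait = "KW", dataset = "15S")
  expect_gte(nrow(rec), 1L)
  expect_match(rec$name[1], "^qKW")
  expect_true(all(rec$lo_cM <= rec$peak_cM & rec$peak_cM <= rec$hi_cM))
  expect_true(all(rec$pve >= 0 & rec$pve <= 100))
  # no two called peaks within the merge distance on one chromosome
  for (cc in unique(rec$chrom)) {
    p <- sort(rec$peak_cM[rec$chrom == cc])
    if (length(p) > 1) expect_true(all(diff(p) >= 20))
  }
})
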