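# BLUEs, variance components, heritability, testcross gain, correlations

test_that("BLUE equals the replicate mean in a single environment", {
  ph <- data.frame(entry = c("a", "a"), population = "RIL", location = "A",
                   year = "y", rep = c("1", "2"), trait = "tr",
                   value = c(3, 5), stringsAsFactors = FALSE)
  expect_equal(compute_blue(ph, "tr"), c(a = 4))
})

test_that("BLUE equals the raw entry mean for balanced tables", {
  eff <- c(a = 1, b = 5, c = -2)
  env_eff <- c("A y1" = 3, "B y1" = -1, "A y2" = 0.5, "B y2" = 2)
  ph <- balanced_pheno(eff, env_eff = env_eff, noise_sd = 0.3, seed = 2)
  blue <- compute_blue(ph, "tr")
  raw <- tapply(ph$value, ph$entry, mean)
  expect_equal(blue, setNames(as.numeric(raw[names(blue)]), names(blue)))
})

test_that("unbalanced BLUE matches explicit normal-equations least squares", {
  eff <- c(a = 1, b = 5, c = -2)
  env_eff <- c("A y1" = 3, "B y1" = -1, "A y2" = 0.5, "B y2" = 2)
  ph <- balanced_pheno(eff, env_eff = env_eff, noise_sd = 0.5, seed = 3)
  drop <- ph$entry == "c" & ph$location == "B" & ph$year == "y2"
  ph <- ph[!drop, ]
  blue <- compute_blue(ph, "tr")

  # oracle: explicit design matrix with sum-to-zero block contrasts, then
  # adjusted means = entry effect + average block contribution
  entry <- factor(ph$entry)
  block <- factor(paste(ph$location, ph$year, ph$rep))
  Xe <- model.matrix(~ 0 + entry)
  Cb <- stats::contr.sum(nlevels(block))
  Xb <- model.matrix(~ block, contrasts.arg = list(block = "contr.sum"))[, -1]
  X <- cbind(Xe, Xb)
  beta <- solve(crossprod(X), crossprod(X, ph$value))
  oracle <- as.numeric(beta[seq_len(nlevels(entry))])  # block effects average 0
  expect_equal(unname(blue), oracle, tolerance = 1e-10)
})

test_that("BLUEs are translation-equivariant and warn on all-missing entries", {
  eff <- c(a = 1, b = 2, c = 3)
  ph <- balanced_pheno(eff, noise_sd = 0.4, seed = 5)
  b0 <- compute_blue(ph, "tr")
  ph2 <- ph; ph2$value <- ph2$value + 7.5
  expect_equal(compute_blue(ph2, "tr"), b0 + 7.5)

  ph3 <- ph; ph3$value[ph3$entry == "b"] <- NA
  expect_warning(b3 <- compute_blue(ph3, "tr"), "all-missing")
  expect_identical(names(b3), c("a", "c"))
})

test_that("hand-built 2x2x2 table matches hand-computed mean squares", {
  # genotypes a,b x locations A,B x reps 1,2 (single year)
  vals <- c(10, 12, 14, 16, 20, 22, 30, 32)
  ph <- data.frame(entry = rep(c("a", "b"), each = 4),
                   population = "RIL",
                   location = rep(rep(c("A", "B"), each = 2), 2),
                   year = "y", rep = rep(c("1", "2"), 4), trait = "tr",
                   value = vals, stringsAsFactors = FALSE)
  vc <- anova_variance_components(ph, "tr")
  # hand algebra: cell means a:A=11, a:B=15, b:A=21, b:B=31
  # MS_G = 4*(mean_a - mean_b)^2 / 2 ... computed classically:
  gm <- mean(vals)
  ssG <- 4 * sum((c(13, 26) - gm)^2)
  ssL <- 4 * sum((c(16, 23) - gm)^2)
  ssGL <- 2 * sum((c(11, 15, 21, 31) - rep(c(13, 26), each = 2) -
                     rep(c(16, 23), 2) + gm)^2)
  tab <- vc$table
  expect_equal(tab$mean_sq[tab$source == "G"], ssG / 1)
  expect_equal(tab$mean_sq[tab$source == "L"], ssL / 1)
  expect_equal(tab$mean_sq[tab$source == "GL"], ssGL / 1)
  # within-cell reps differ by 2 -> SS_E = 8 * 1^2 = 8 over 8 obs; blocks
  # within env absorb 2 df, error keeps 2 df with MS 2 here
  expect_equal(vc$sigma_E, tab$mean_sq[tab$source == "Error"])
  expect_true(is.na(vc$sigma_GY))   # single year: not estimable
  # method of moments: sigma_GL = (MS_GL - MS_E)/(R*Y), sigma_G = (MS_G - MS_GL)/(R*L)
  expect_equal(vc$sigma_GL, max(0, (ssGL - vc$sigma_E) / 2))
  expect_equal(vc$sigma_G, (ssG - ssGL) / 4)
})

test_that("noiseless genotype differences give sigma_E = 0, interactions 0", {
  eff <- c(a = 1, b = 5, c = 9)
  ph <- balanced_pheno(eff, noise_sd = 0)
  vc <- anova_variance_components(ph, "tr")
  expect_equal(vc$sigma_E, 0, tolerance = 1e-20)
  expect_gt(vc$sigma_G, 0)
  expect_equal(vc$sigma_GL, 0, tolerance = 1e-20)
  expect_equal(vc$sigma_GLY, 0, tolerance = 1e-20)
  expect_equal(broad_sense_heritability(vc), 1)
})

test_that("variance components are recovered within 15% at scale", {
  truth <- c(G = 4, GL = 1, GY = 0.5, GLY = 1.5, E = 3)
  est <- matrix(NA_real_, 12, 5, dimnames = list(NULL, names(truth)))
  for (k in seq_len(12)) {
    set.seed(4000 + k)
    nl <- 200
    g <- rnorm(nl, 0, sqrt(truth["G"]))
    names(g) <- sprintf("e%03d", seq_len(nl))
    gl <- matrix(rnorm(nl * 2, 0, sqrt(truth["GL"])), nl, 2,
                 dimnames = list(names(g), c("A", "B")))
    gy <- matrix(rnorm(nl * 2, 0, sqrt(truth["GY"])), nl, 2,
                 dimnames = list(names(g), c("y1", "y2")))
    grid <- expand.grid(entry = names(g), location = c("A", "B"),
                        year = c("y1", "y2"), rep = c("1", "2"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    glykey <- interaction(grid$entry, grid$location, grid$year)
    gly <- rnorm(nlevels(glykey), 0, sqrt(truth["GLY"]))[as.integer(glykey)]
    grid$trait <- "tr"; grid$population <- "RIL"
    grid$value <- g[grid$entry] + gl[cbind(grid$entry, grid$location)] +
      gy[cbind(grid$entry, grid$year)] + gly + rnorm(nrow(grid), 0, sqrt(truth["E"]))
    vc <- anova_variance_components(grid, "tr")
    est[k, ] <- c(vc$sigma_G, vc$sigma_GL, vc$sigma_GY, vc$sigma_GLY, vc$sigma_E)
  }
  avg <- colMeans(est)
  expect_true(all(abs(avg - truth) / truth < 0.15))
})

test_that("Knapp heritability evaluates the formula and is monotone", {
  vc <- list(sigma_G = 4, sigma_GL = 0, sigma_GY = 0, sigma_GLY = 0,
             sigma_E = 4, L = 2, Y = 2, R = 2)
  expect_equal(broad_sense_heritability(vc), 4 / 4.5)
  vc0 <- vc; vc0$sigma_G <- 0
  expect_equal(broad_sense_heritability(vc0), 0)
  vc1 <- vc; vc1$sigma_E <- 0
  expect_equal(broad_sense_heritability(vc1), 1)
  expect_warning(h <- broad_sense_heritability(
    list(sigma_G = 0, sigma_GL = 0, sigma_GY = 0, sigma_GLY = 0, sigma_E = 0,
         L = 2, Y = 2, R = 2)), "undefined")
  expect_true(is.na(h))
  # monotone: increasing sigma_G raises H2; increasing any noise lowers it
  base <- broad_sense_heritability(vc)
  up <- vc; up$sigma_G <- 6
  expect_gt(broad_sense_heritability(up), base)
  for (comp in c("sigma_GL", "sigma_GY", "sigma_GLY", "sigma_E")) {
    worse <- vc; worse[[comp]] <- worse[[comp]] + 2
    expect_lt(broad_sense_heritability(worse), base)
  }
})

test_that("testcross gain reproduces the percent arithmetic", {
  mk <- function(pop, vals) data.frame(entry = sprintf("%s%d", pop, seq_along(vals)),
                                       population = pop, location = "A", year = "y",
                                       rep = "1", trait = "tr", value = vals,
                                       stringsAsFactors = FALSE)
  ph <- rbind(mk("RIL", c(8, 10, 12)), mk("TC", c(8, 10, 12)))
  expect_equal(testcross_gain(ph, "tr"), 0)
  ph2 <- rbind(mk("RIL", c(5, 15)), mk("TC", c(10, 30)))
  expect_equal(testcross_gain(ph2, "tr"), 100)
  ph3 <- rbind(mk("RIL", c(9, 10, 11)), mk("TC", c(24, 24.15, 24.3)))
  expect_equal(testcross_gain(ph3, "tr"), 141.5)
})

test_that("correlation matches the brute-force formula with correct stars", {
  expect_equal(correlation_with_significance(1:10, 1:10)$r, 1)
  x <- c(1, -1, 2, -2, 3, -3)
  y <- c(1, 1, -2, -2, 1, 1)   # orthogonal to x by construction
  expect_equal(correlation_with_significance(x, y)$r, 0)

  set.seed(8)
  a <- rnorm(10); b <- 0.6 * a + rnorm(10)
  cs <- correlation_with_significance(a, b)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cs$r, r_oracle, tolerance = 1e-12)
  p_oracle <- stats::cor.test(a, b)$p.value
  expect_equal(cs$p, p_oracle, tolerance = 1e-12)
  expect_identical(cs$stars, if (p_oracle < 0.01) "**"
                   else if (p_oracle < 0.05) "*" else "")

  expect_true(is.na(correlation_with_significance(c(1, 2), c(3, 4))$r))
  expect_true(is.na(correlation_with_significance(rep(1, 5), rnorm(5))$r))
})

test_that("correlation star matrix lays out per se / GCA blocks", {
  set.seed(9)
  perse <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("A", "B", "C")))
  gca <- perse * 0.7 + matrix(rnorm(60, 0, 0.6), 20, 3)
  colnames(gca) <- colnames(perse)
  cm <- correlation_star_matrix(perse, gca)
  expect_equal(cm$r["B", "A"], cor(perse[, "B"], perse[, "A"]))
  expect_equal(cm$r["A", "B"], cor(gca[, "A"], gca[, "B"]))
  expect_equal(cm$r["A", "A"], cor(perse[, "A"], gca[, "A"]))
  expect_match(cm$annotated["A", "A"], "^-?[01]\\.\\d\\d")
})
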