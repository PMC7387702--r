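# Configuration-driven end-to-end runner: simulation -> BLUE/GCA -> scans ->
# per se vs GCA comparison, with deterministic sub-seeding and a checksum
# manifest.

#' Build a run configuration
#'
#' All counts must be >= 1, `alpha` in (0, 1).  A single root seed
#' deterministically derives per-stage sub-seeds, so stage outputs are
#' reproducible.  With `n_perm = 0` the scans use the fixed `lod_threshold`
#' (the conventional declaration threshold 3.0); with `n_perm >= 100` a
#' permutation threshold is computed per response.
#'
#' @param seed Root RNG seed.
#' @param n_lines,testers Design constants.
#' @param locations,years,reps Environment structure.
#' @param n_chrom,markers_per_chrom,chrom_length_cM Map constants.
#' @param generations RIL filial generation.
#' @param traits List of [trait_arch()] objects, or NULL for the default
#'   contrast architecture.
#' @param step_cM,n_cofactors,window_cM,n_perm,alpha,lod_threshold Scan
#'   settings.
#' @param max_peak_dist_Mb Co-localization threshold.
#' @param out_dir Output directory.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 1, n_lines = 328, testers = c("TC", "TM"),
                       locations = c("S", "X"), years = c("15", "16"),
                       reps = 2, n_chrom = 10, markers_per_chrom = 31,
                       chrom_length_cM = 150, generations = 11,
                       traits = NULL, step_cM = 2.5, n_cofactors = 3,
                       window_cM = 10, n_perm = 0, alpha = 0.05,
                       lod_threshold = 3.0, max_peak_dist_Mb = 20,
                       out_dir = tempfile("gcamap_run_")) {
  cfg <- list(seed = check_number(seed, "seed"),
              n_lines = check_count(n_lines, "n_lines"),
              testers = as.character(testers),
              locations = as.character(locations),
              years = as.character(years),
              reps = check_count(reps, "reps"),
              n_chrom = check_count(n_chrom, "n_chrom"),
              markers_per_chrom = check_count(markers_per_chrom, "markers_per_chrom", 2L),
              chrom_length_cM = check_number(chrom_length_cM, "chrom_length_cM", min = 1),
              generations = check_count(generations, "generations", 2L),
              traits = traits,
              step_cM = check_number(step_cM, "step_cM", min = 1e-6),
              n_cofactors = check_count(n_cofactors, "n_cofactors", 0L),
              window_cM = check_number(window_cM, "window_cM", min = 0),
              n_perm = check_count(n_perm, "n_perm", 0L),
              alpha = check_number(alpha, "alpha"),
              lod_threshold = check_number(lod_threshold, "lod_threshold"),
              max_peak_dist_Mb = check_number(max_peak_dist_Mb, "max_peak_dist_Mb", min = 0),
              out_dir = out_dir)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_bad("alpha must be in (0, 1)")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from JSON
#'
#' @param path JSON file whose fields override [run_config()] defaults.
#' @return A `"run_config"` object.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop_bad("unknown config fields: %s", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

write_table_with_header <- function(df, path, cfg_hash, seed, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gcamap %s | %s | seed=%s | config=%s",
                     as.character(utils::packageVersion("gcamap")),
                     what, format(seed), cfg_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  # out_dir is excluded: the hash identifies the analysis, not its location
  writeLines(jsonlite::toJSON(cfg[setdiff(names(cfg), c("traits", "out_dir"))],
                              auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Simulation -> per se BLUEs, heritability and GCA estimation -> per se and
#' GCA QTL scans (per environment and joint) -> consolidation,
#' classification and pleiotropy report.  Deterministic given the config
#' seed; every output file is listed with its MD5 checksum in
#' `manifest.tsv`.  On simulated input, recovery metrics (true vs estimated
#' H2 and GCA, true vs detected QTL) are written alongside.
#'
#' @param cfg A [run_config()].
#' @param stages Subset of `c("simulate", "estimate", "scan", "compare")`;
#'   later stages require earlier ones.
#' @return Invisibly, a list with all intermediate objects and the manifest.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "estimate", "scan", "compare")) {
  stopifnot(inherits(cfg, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  files <- character(0)
  emit <- function(df, name, what) {
    p <- file.path(cfg$out_dir, name)
    write_table_with_header(df, p, hash, cfg$seed, what)
    files <<- c(files, p)
    p
  }
  res <- list(config = cfg)

  # --- simulate ---------------------------------------------------------
  map <- simulate_map(cfg$n_chrom, cfg$markers_per_chrom,
                      cfg$chrom_length_cM, seed = derive_seed(cfg$seed, 1))
  geno <- simulate_ril_genomes(map, cfg$n_lines, cfg$generations,
                               seed = derive_seed(cfg$seed, 2))
  design <- build_ncii_design(rownames(geno), cfg$testers)
  env <- env_spec(cfg$locations, cfg$years, cfg$reps)
  archs <- cfg$traits %||% list(contrast_architecture(map, trait = "T1",
                                                      testers = cfg$testers))
  sim <- simulate_phenotypes(geno, map, archs, design, env,
                             seed = derive_seed(cfg$seed, 3))
  res$map <- map; res$geno <- geno; res$design <- design; res$sim <- sim
  if ("simulate" %in% stages) {
    write_map_tsv(map, file.path(cfg$out_dir, "map.tsv"))
    files <- c(files, file.path(cfg$out_dir, "map.tsv"))
    write_cross_csv(file.path(cfg$out_dir, "cross.csv"), geno, map)
    files <- c(files, file.path(cfg$out_dir, "cross.csv"))
    write_pheno_csv(sim$pheno, file.path(cfg$out_dir, "pheno.csv"))
    files <- c(files, file.path(cfg$out_dir, "pheno.csv"))
    truth_path <- file.path(cfg$out_dir, "truth.json")
    jsonlite::write_json(lapply(sim$truth, function(tt)
      list(qtl = tt$qtl, gca_true = as.list(tt$gca_true),
           h2_true = tt$h2_true, h2_tc_true = tt$h2_tc_true,
           sd_e = tt$sd_e, sd_e_h = tt$sd_e_h)),
      truth_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, truth_path)
  }
  if (!any(c("estimate", "scan", "compare") %in% stages))
    return(finish_run(res, files, cfg, hash))

  # --- estimate ---------------------------------------------------------
  traits <- vapply(archs, function(a) a$trait, character(1))
  est <- list()
  for (tr in traits) {
    perse <- sim$pheno[sim$pheno$population == "RIL", , drop = FALSE]
    hyb <- sim$pheno[sim$pheno$population != "RIL", , drop = FALSE]
    blue_joint <- compute_blue(perse, tr)
    vc <- anova_variance_components(perse, tr)
    gca <- gca_phenotype_vector(hyb, design, tr)
    ca <- estimate_combining_ability(hyb, design, tr)
    nc <- ncii_anova(hyb, design, tr)
    envs <- unique(perse[, c("location", "year")])
    blue_env <- lapply(seq_len(nrow(envs)), function(e) {
      compute_blue(perse[perse$location == envs$location[e] &
                           perse$year == envs$year[e], , drop = FALSE], tr)
    })
    names(blue_env) <- paste0(envs$year, envs$location)
    est[[tr]] <- list(blue_joint = blue_joint, blue_env = blue_env, vc = vc,
                      h2 = broad_sense_heritability(vc), gca = gca, ca = ca,
                      ncii = nc)
    emit(data.frame(entry = names(blue_joint), blue = blue_joint),
         sprintf("blue_%s.tsv", tr), sprintf("per se BLUEs (%s)", tr))
    emit(vc$table, sprintf("anova_perse_%s.tsv", tr),
         sprintf("per se ANOVA (%s)", tr))
    emit(nc$table, sprintf("anova_testcross_%s.tsv", tr),
         sprintf("testcross ANOVA (%s)", tr))
    emit(data.frame(line = rownames(gca), gca, check.names = FALSE),
         sprintf("gca_%s.tsv", tr), sprintf("GCA phenotypes (%s)", tr))
  }
  res$estimates <- est
  if (!any(c("scan", "compare") %in% stages))
    return(finish_run(res, files, cfg, hash))

  # --- scan -------------------------------------------------------------
  probs <- genotype_probabilities(geno, map, cfg$step_cM)
  res$probs <- probs
  scans <- list(); records <- list()
  kk <- 0L
  for (tr in traits) {
    responses <- c(
      stats::setNames(lapply(names(est[[tr]]$blue_env), function(e)
        est[[tr]]$blue_env[[e]]), paste0("perse:", names(est[[tr]]$blue_env))),
      list("perse:joint" = est[[tr]]$blue_joint),
      stats::setNames(lapply(colnames(est[[tr]]$gca), function(e) {
        v <- est[[tr]]$gca[[e]]; names(v) <- rownames(est[[tr]]$gca); v
      }), paste0("gca:", colnames(est[[tr]]$gca))))
    for (nm in names(responses)) {
      kk <- kk + 1L
      y <- responses[[nm]]
      y <- y[is.finite(y)]
      cof <- select_cofactors(geno[names(y), , drop = FALSE], y, cfg$n_cofactors)
      sc <- cim_scan(probs, y, cof, cfg$window_cM)
      thr <- if (cfg$n_perm >= 100L)
        permutation_threshold(probs, y, n_perm = cfg$n_perm, alpha = cfg$alpha,
                              seed = derive_seed(cfg$seed, 100 + kk))
      else cfg$lod_threshold
      ds <- sub("^[^:]*:", "", nm)
      type <- sub(":.*$", "", nm)
      rec <- call_qtl(sc, probs, y, thr, trait = tr, dataset = ds,
                      merge_cM = cfg$window_cM * 2)
      if (nrow(rec)) rec$id <- paste(type, rec$id, sep = ":")
      scans[[paste(tr, nm)]] <- sc
      records[[paste(tr, nm)]] <- list(type = type, rec = rec, threshold = thr)
    }
    curves <- do.call(rbind, lapply(names(scans)[grepl(paste0("^", tr, " "), names(scans))],
                                    function(nm) cbind(dataset = sub("^\\S+ ", "", nm),
                                                       scans[[nm]])))
    emit(curves, sprintf("scan_%s.tsv", tr), sprintf("LOD curves (%s)", tr))
  }
  res$scans <- scans
  res$records <- records
  if (!("compare" %in% stages)) return(finish_run(res, files, cfg, hash))

  # --- compare ----------------------------------------------------------
  all_perse <- do.call(rbind, lapply(records, function(r)
    if (r$type == "perse") r$rec))
  all_gca <- do.call(rbind, lapply(records, function(r)
    if (r$type == "gca") r$rec))
  cons_perse <- consolidate_environments(all_perse %||% empty_qtl_records(),
                                         max_peak_dist_Mb = cfg$max_peak_dist_Mb)
  cons_gca <- consolidate_environments(all_gca %||% empty_qtl_records(),
                                       max_peak_dist_Mb = cfg$max_peak_dist_Mb)
  cls <- classify_perse_vs_gca(cons_perse, cons_gca, cfg$max_peak_dist_Mb)
  pleio <- pleiotropy_report(rbind(cons_perse, cons_gca), cfg$max_peak_dist_Mb)
  res$consolidated <- list(perse = cons_perse, gca = cons_gca)
  res$classification <- cls
  res$pleiotropy <- pleio
  emit(as.data.frame(cons_perse), "qtl_perse.tsv", "consolidated per se QTL")
  emit(as.data.frame(cons_gca), "qtl_gca.tsv", "consolidated GCA QTL")
  emit(cls$table, "classification.tsv", "per se vs GCA classification")
  emit(pleio$components, "pleiotropy.tsv", "pleiotropy components")

  # recovery metrics against the generative truth
  recov <- do.call(rbind, lapply(traits, function(tr) {
    tt <- sim$truth[[tr]]
    truth_vec <- tt$gca_true[rownames(est[[tr]]$gca)]
    gca_cor <- if (stats::sd(truth_vec, na.rm = TRUE) > 0 &&
                   stats::sd(est[[tr]]$gca$joint, na.rm = TRUE) > 0)
      stats::cor(truth_vec, est[[tr]]$gca$joint, use = "complete.obs")
    else NA_real_
    data.frame(trait = tr, h2_true = tt$h2_true, h2_est = est[[tr]]$h2,
               h2_tc_true = tt$h2_tc_true,
               h2_tc_est = est[[tr]]$ncii$h2_testcross,
               gca_cor = gca_cor,
               n_qtl_true = nrow(tt$qtl),
               n_qtl_perse = sum(cons_perse$trait == tr),
               n_qtl_gca = sum(cons_gca$trait == tr),
               stringsAsFactors = FALSE)
  }))
  res$recovery <- recov
  emit(recov, "recovery.tsv", "truth-vs-estimate recovery metrics")
  finish_run(res, files, cfg, hash)
}

finish_run <- function(res, files, cfg, hash) {
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         bytes = file.size(files), stringsAsFactors = FALSE)
  write_table_with_header(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                          hash, cfg$seed, "run manifest")
  res$manifest <- manifest
  invisible(res)
}
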