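# shared fixture builders; everything is generated in code

# small hand-made map: 2 chromosomes, explicit Mb coordinates
tiny_map <- function() {
  genetic_map(marker = c("m1", "m2", "m3", "m4", "m5", "m6"),
              chrom = c("1", "1", "1", "2", "2", "2"),
              pos_cM = c(0, 10, 20, 0, 5, 30),
              pos_Mb = c(1, 12, 25, 2, 9, 40))
}

tiny_geno <- function(map = tiny_map()) {
  g <- matrix(c("P1", "P1", "P2", "P2", "Het", "P1",
                "P2", "P2", "P2", "P1", "P1", "P1",
                "P1", "Het", "P1", "P2", "P2", "P2",
                "P2", "P1", "Missing", "P1", "P2", "Het",
                "P1", "P1", "P1", "P2", "P2", "P2"),
              nrow = 5, byrow = TRUE,
              dimnames = list(sprintf("L%03d", 1:5), map$marker))
  geno_matrix(g, map)
}

# balanced long-format phenotype table from an entry-effect vector
balanced_pheno <- function(entry_eff, locations = c("A", "B"),
                           years = c("y1", "y2"), reps = 2, trait = "tr",
                           population = "RIL", env_eff = NULL, noise_sd = 0,
                           seed = 1) {
  set.seed(seed)
  entries <- names(entry_eff)
  grid <- expand.grid(entry = entries, location = locations, year = years,
                      rep = as.character(seq_len(reps)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ek <- paste(grid$location, grid$year)
  ee <- if (is.null(env_eff)) 0 else env_eff[ek]
  data.frame(entry = grid$entry, population = population,
             location = grid$location, year = grid$year, rep = grid$rep,
             trait = trait,
             value = entry_eff[grid$entry] + ee +
               stats::rnorm(nrow(grid), 0, noise_sd),
             stringsAsFactors = FALSE)
}

# hybrid phenotype table from a full line x tester cell-mean matrix
hybrid_pheno_from_cells <- function(cells, design, locations = "A",
                                    years = "y1", reps = 1, noise_sd = 0,
                                    trait = "tr", seed = 1) {
  set.seed(seed)
  ht <- design$hybrid_table
  vals <- cells[cbind(ht$line, ht$tester)]
  grid <- expand.grid(i = seq_len(nrow(ht)), location = locations,
                      year = years, rep = as.character(seq_len(reps)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(entry = ht$hybrid[grid$i], population = ht$tester[grid$i],
             location = grid$location, year = grid$year, rep = grid$rep,
             trait = trait,
             value = vals[grid$i] + stats::rnorm(nrow(grid), 0, noise_sd),
             stringsAsFactors = FALSE)
}

# minimal QTL record row for the compare module
qtl_rec <- function(id, trait = "T", chrom = "1", dataset = "joint",
                    peak_Mb = 10, lo_Mb = peak_Mb - 2, hi_Mb = peak_Mb + 2,
                    lod = 5, add = 1, pve = 5) {
  r <- data.frame(trait = trait, name = id, chrom = chrom, dataset = dataset,
                  peak_cM = peak_Mb, peak_Mb = peak_Mb,
                  lo_cM = lo_Mb, hi_cM = hi_Mb, lo_Mb = lo_Mb, hi_Mb = hi_Mb,
                  lod = lod, pve = pve, add = add, n = 100,
                  id = id, stringsAsFactors = FALSE)
  class(r) <- c("qtl_records", "data.frame")
  r
}

qtl_recs <- function(...) {
  r <- do.call(rbind, list(...))
  class(r) <- c("qtl_records", "data.frame")
  r
}
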