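# File I/O for the rotated "cross" CSV dialect, the map TSV, and the
# long-format phenotype CSV.
#
# Cross CSV layout (columns = phenotype columns first, then markers):
#   row 1: "id", phenotype names, marker names
#   row 2: blanks under id/phenotypes, chromosome per marker
#   row 3: blanks under id/phenotypes, cM position per marker
#   rows 4+: one line per individual: id, phenotype values, genotype codes
# Missing genotypes are written as "-" (empty cells are also accepted on
# read); missing phenotypes as "NA".

#' Write genotypes, map and line phenotypes in the rotated cross CSV dialect
#'
#' @param path Output file path.
#' @param geno Genotype matrix (lines x markers).
#' @param map [genetic_map()] matching `geno` (Mb positions are not part of
#'   this format; see [write_map_tsv()]).
#' @param pheno Optional data.frame of per-line phenotype columns, one row per
#'   line of `geno` (row order must match).
#' @return `path`, invisibly.
#' @export
write_cross_csv <- function(path, geno, map, pheno = NULL) {
  stopifnot(inherits(map, "genmap"))
  if (ncol(geno) != nrow(map)) stop_bad("genotypes do not match the map")
  if (!is.null(pheno)) {
    pheno <- as.data.frame(pheno)
    if (nrow(pheno) != nrow(geno))
      stop_bad("phenotype rows (%d) do not match genotype lines (%d)",
               nrow(pheno), nrow(geno))
  }
  np <- if (is.null(pheno)) 0L else ncol(pheno)
  g <- unclass(geno)
  g[g == "Missing"] <- "-"
  fmt <- function(x) {
    out <- vapply(x, function(v) format(v, digits = 15, scientific = FALSE,
                                        trim = TRUE), character(1))
    out[is.na(x)] <- "NA"
    out
  }
  header <- c("id", if (np) colnames(pheno), map$marker)
  row2 <- c(rep("", 1L + np), map$chrom)
  row3 <- c(rep("", 1L + np), fmt(map$pos_cM))
  body <- cbind(rownames(geno) %||% sprintf("L%03d", seq_len(nrow(g))),
                if (np) do.call(cbind, lapply(pheno, fmt)), g)
  lines <- c(paste(header, collapse = ","),
             paste(row2, collapse = ","),
             paste(row3, collapse = ","),
             apply(body, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a rotated cross CSV file
#'
#' Parses the format written by [write_cross_csv()], validating header
#' structure, genotype codes and marker positions; parse errors report the
#' offending row and column.
#'
#' @param path File path.
#' @return List with `map` ([genetic_map()], no Mb), `geno` (genotype matrix)
#'   and `pheno` (data.frame of phenotype columns plus line `id`s as row
#'   names; NULL when the file has no phenotype columns).
#' @export
read_cross_csv <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) < 4L) stop_bad("%s: need 3 header rows plus data", path)
  header <- as.character(raw[1L, ])
  chromr <- as.character(raw[2L, ])
  posr <- as.character(raw[3L, ])
  if (header[1L] != "id") stop_bad("%s: row 1, column 1 must be 'id'", path)
  is_marker <- chromr != ""
  is_marker[1L] <- FALSE
  if (!any(is_marker)) stop_bad("%s: no marker columns found (row 2 empty)", path)
  mcols <- which(is_marker)
  mstart <- min(mcols)
  if (any(chromr[seq(mstart, length(header))] == ""))
    stop_bad("%s: phenotype columns must precede marker columns", path)
  pcols <- setdiff(seq_len(mstart - 1L), 1L)
  pos <- suppressWarnings(as.numeric(posr[mcols]))
  if (any(is.na(pos)))
    stop_bad("%s: row 3, column %d: cM position '%s' is not numeric",
             path, mcols[which(is.na(pos))[1L]], posr[mcols[which(is.na(pos))[1L]]])
  map <- genetic_map(header[mcols], chromr[mcols], pos)
  body <- raw[-(1:3), , drop = FALSE]
  ids <- body[[1L]]
  g <- as.matrix(body[, mcols, drop = FALSE])
  g[g == "-" | g == ""] <- "Missing"
  bad <- !(g %in% GENO_CODES)
  if (any(bad)) {
    idx <- which(bad)[1L]
    ri <- (idx - 1L) %% nrow(g) + 1L
    ci <- (idx - 1L) %/% nrow(g) + 1L
    stop_bad("%s: row %d, column %d (marker %s): unknown genotype code '%s'",
             path, ri + 3L, mcols[ci], map$marker[ci], g[idx])
  }
  dimnames(g) <- list(ids, map$marker)
  geno <- geno_matrix(g, map)
  pheno <- NULL
  if (length(pcols)) {
    pheno <- as.data.frame(lapply(body[, pcols, drop = FALSE], function(v) {
      v[v == ""] <- NA
      suppressWarnings(as.numeric(v))
    }))
    names(pheno) <- header[pcols]
    rownames(pheno) <- ids
  }
  list(map = map, geno = geno, pheno = pheno)
}

#' Write / read a genetic map as TSV (marker, chrom, cM, Mb)
#' @param map A [genetic_map()].
#' @param path File path.
#' @return `path` (write) or a [genetic_map()] (read).
#' @export
write_map_tsv <- function(map, path) {
  stopifnot(inherits(map, "genmap"))
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "chrom", "pos_cM")
  if (!all(need %in% names(d)))
    stop_bad("%s: map TSV needs columns marker, chrom, pos_cM", path)
  genetic_map(d$marker, d$chrom, d$pos_cM, d$pos_Mb %||% NULL)
}

PHENO_COLS <- c("entry", "population", "location", "year", "rep", "trait", "value")

#' Write / read the long-format phenotype table
#'
#' Columns: entry, population (RIL or a tester tag), location, year, rep,
#' trait, value.
#'
#' @param pheno Long-format phenotype data.frame.
#' @param path File path.
#' @export
write_pheno_csv <- function(pheno, path) {
  check_pheno(pheno)
  utils::write.csv(pheno[, PHENO_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pheno_csv
#' @export
read_pheno_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(rep("character", 5), "character", "numeric"))
  check_pheno(d)
}

check_pheno <- function(pheno) {
  if (!all(PHENO_COLS %in% names(pheno)))
    stop_bad("phenotype table needs columns: %s", paste(PHENO_COLS, collapse = ", "))
  pheno <- as.data.frame(pheno)
  for (cc in PHENO_COLS[1:6]) pheno[[cc]] <- as.character(pheno[[cc]])
  pheno$value <- as.numeric(pheno$value)
  key <- do.call(paste, c(pheno[c("entry", "location", "year", "rep", "trait")], sep = "\r"))
  if (anyDuplicated(key))
    stop_bad("duplicate (entry, location, year, rep, trait) records in phenotype table")
  pheno
}
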