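# Genotype matrix container and dosage coding.
#
# Codes: "P1" (female-parent homozygote), "P2" (male-parent homozygote),
# "Het" (residual heterozygote), "Missing".
# Additive dosage convention: x in {0, 0.5, 1} for {P1, Het, P2}; the signed
# scale s = 2x - 1 in {-1, 0, +1} is used by the phenotype simulator so that
# an additive effect a is half the difference between homozygote means.

GENO_CODES <- c("P1", "P2", "Het", "Missing")

#' Construct a line-by-marker genotype matrix
#'
#' @param x Character matrix of codes `P1`, `P2`, `Het`, `Missing`; rows are
#'   lines, columns are markers ordered as in `map`.
#' @param map A [genetic_map()] whose markers match `colnames(x)` (names are
#'   taken from the map when the matrix is unnamed).
#' @return The validated matrix with class `"genomat"`.
#' @export
geno_matrix <- function(x, map) {
  stopifnot(inherits(map, "genmap"))
  if (!is.matrix(x)) stop_bad("genotypes must be a matrix")
  x <- matrix(as.character(x), nrow(x), ncol(x), dimnames = dimnames(x))
  if (ncol(x) != nrow(map))
    stop_bad("genotype matrix has %d columns but the map has %d markers",
             ncol(x), nrow(map))
  if (is.null(colnames(x))) colnames(x) <- map$marker
  if (!identical(colnames(x), map$marker))
    stop_bad("genotype matrix columns are not in map order")
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("L%03d", seq_len(nrow(x)))
  bad <- !(x %in% GENO_CODES)
  if (any(bad)) {
    idx <- which(bad)[1L]
    stop_bad("unknown genotype code '%s' at line %d, marker %s",
             x[idx], (idx - 1L) %% nrow(x) + 1L,
             colnames(x)[(idx - 1L) %/% nrow(x) + 1L])
  }
  class(x) <- c("genomat", class(x))
  x
}

#' Additive dosage scores from genotype codes
#'
#' @param geno Genotype matrix of codes.
#' @return Numeric matrix with P1 = 0, Het = 0.5, P2 = 1, Missing = NA.
#' @export
geno_dosage <- function(geno) {
  d <- matrix(NA_real_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  d[geno == "P1"] <- 0
  d[geno == "Het"] <- 0.5
  d[geno == "P2"] <- 1
  d
}

# signed coding in {-1, 0, +1}; used by the generative model
geno_signed <- function(geno) 2 * geno_dosage(geno) - 1
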