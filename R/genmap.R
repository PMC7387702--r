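#' Haldane map function: genetic distance to recombination fraction
#'
#' Converts a genetic distance in centiMorgans to a recombination fraction
#' under the Haldane (no-interference) model, `r = 0.5 * (1 - exp(-2 d / 100))`.
#'
#' @param d_cM Numeric vector of genetic distances in cM; must be `>= 0`.
#' @return Recombination fractions in `[0, 0.5)`.
#' @seealso [r_to_haldane()], [ril_recomb()]
#' @export
#' @examples
#' haldane_to_r(10)   # ~0.0906
haldane_to_r <- function(d_cM) {
  if (!is.numeric(d_cM) || any(!is.finite(d_cM)) || any(d_cM < 0))
    stop_bad("genetic distances must be finite and >= 0")
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' Inverse Haldane map function
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Genetic distance(s) in cM.
#' @export
r_to_haldane <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0) || any(r >= 0.5))
    stop_bad("recombination fractions must lie in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' Recombination fraction observed in selfed RILs
#'
#' Map expansion for recombinant inbred lines produced by selfing: a
#' single-meiosis recombination fraction `r` is observed in the fixed lines as
#' `r* = 2 r / (1 + 2 r)` (Haldane-Waddington).
#'
#' @param r Single-meiosis recombination fraction(s) in `[0, 0.5]`.
#' @return RIL-scale recombination fraction(s).
#' @export
ril_recomb <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0) || any(r > 0.5))
    stop_bad("recombination fractions must lie in [0, 0.5]")
  2 * r / (1 + 2 * r)
}

#' Construct a genetic map
#'
#' A genetic map holds one row per marker with its chromosome, genetic (cM)
#' position and, optionally, physical (Mb) position.  Within a chromosome the
#' cM positions must be non-decreasing in the order given, and Mb positions
#' (when present) strictly increasing; marker names must be unique genome-wide.
#' cM positions are 0-based within chromosome; Mb positions are 1-based
#' physical coordinates.
#'
#' @param marker Character vector of unique marker names.
#' @param chrom Chromosome identifier per marker (coerced to character;
#'   chromosome order is the order of first appearance).
#' @param pos_cM Genetic position per marker in cM.
#' @param pos_Mb Optional physical position per marker in Mb.
#' @return A `data.frame` of class `"genmap"` with columns `marker`, `chrom`,
#'   `pos_cM`, `pos_Mb`.
#' @export
genetic_map <- function(marker, chrom, pos_cM, pos_Mb = NULL) {
  marker <- as.character(marker)
  chrom <- as.character(chrom)
  n <- length(marker)
  if (n == 0L) stop_bad("a genetic map needs at least one marker")
  if (length(chrom) != n || length(pos_cM) != n)
    stop_bad("marker, chrom and pos_cM must have equal length")
  if (anyDuplicated(marker))
    stop_bad("duplicate marker names: %s",
             paste(unique(marker[duplicated(marker)])[1:min(3, n)], collapse = ", "))
  if (any(!is.finite(pos_cM)) || any(pos_cM < 0))
    stop_bad("cM positions must be finite and >= 0")
  if (is.null(pos_Mb)) pos_Mb <- rep(NA_real_, n)
  if (length(pos_Mb) != n) stop_bad("pos_Mb must match the number of markers")
  for (cc in unique(chrom)) {
    i <- which(chrom == cc)
    if (is.unsorted(pos_cM[i]))
      stop_bad("cM positions on chromosome %s are not non-decreasing", cc)
    mb <- pos_Mb[i]
    if (all(is.finite(mb)) && any(diff(mb) <= 0))
      stop_bad("Mb positions on chromosome %s are not strictly increasing", cc)
  }
  out <- data.frame(marker = marker, chrom = chrom, pos_cM = as.numeric(pos_cM),
                    pos_Mb = as.numeric(pos_Mb), stringsAsFactors = FALSE)
  class(out) <- c("genmap", "data.frame")
  out
}

chrom_levels <- function(map) unique(map$chrom)

#' Summarise a genetic map
#'
#' Reports per-chromosome and genome-wide marker counts and map lengths, plus
#' two mean inter-marker spacings: `spacing` uses `total length /
#' (markers - chromosomes)` (spacing is undefined across chromosome breaks)
#' and `spacing_naive` uses `total length / markers` for cross-checking
#' against published arithmetic.
#'
#' @param map A [genetic_map()].
#' @return A list with `per_chrom` (data.frame), `n_markers`, `n_chrom`,
#'   `total_cM`, `spacing`, `spacing_naive`.
#' @export
map_summary <- function(map) {
  stopifnot(inherits(map, "genmap"))
  chroms <- chrom_levels(map)
  per <- do.call(rbind, lapply(chroms, function(cc) {
    p <- map$pos_cM[map$chrom == cc]
    data.frame(chrom = cc, n_markers = length(p), length_cM = max(p) - min(p),
               stringsAsFactors = FALSE)
  }))
  total <- sum(per$length_cM)
  list(per_chrom = per,
       n_markers = nrow(map),
       n_chrom = length(chroms),
       total_cM = total,
       spacing = mean_marker_spacing(total, nrow(map), length(chroms)),
       spacing_naive = total / nrow(map))
}

#' Mean inter-marker spacing from map totals
#'
#' `total_cM / (n_markers - n_chrom)`: the denominator counts inter-marker
#' gaps, which do not span chromosome breaks.
#'
#' @param total_cM Total map length in cM.
#' @param n_markers Number of markers.
#' @param n_chrom Number of chromosomes (linkage groups).
#' @return Mean spacing in cM.
#' @export
#' @examples
#' round(mean_marker_spacing(1533.72, 4602, 10), 2)  # 0.33
mean_marker_spacing <- function(total_cM, n_markers, n_chrom) {
  total_cM <- check_number(total_cM, "total_cM", min = 0)
  n_markers <- check_count(n_markers, "n_markers", min = 2L)
  n_chrom <- check_count(n_chrom, "n_chrom", min = 1L)
  if (n_markers <= n_chrom) stop_bad("need more markers than chromosomes")
  total_cM / (n_markers - n_chrom)
}
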