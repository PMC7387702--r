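# Consolidation of QTL across environments, per se vs GCA co-localization
# and classification, and pleiotropy grouping across traits.
#
# Co-localization rule: two QTL on the same chromosome match when their
# physical support intervals overlap (closed intervals) OR their peaks are
# within max_peak_dist_Mb (default 20 Mb) of each other.

#' Co-localize two QTL record sets
#'
#' @param qtls_a,qtls_b `"qtl_records"` data.frames (see [call_qtl()]); rows
#'   lacking Mb coordinates are skipped with a warning.
#' @param max_peak_dist_Mb Peak-distance rule threshold in Mb.
#' @return data.frame of matches: `id_a`, `id_b`, `chrom`, `basis`
#'   (`"interval-overlap"` or `"peak-distance"`), `peak_dist_Mb`.
#' @export
colocalize <- function(qtls_a, qtls_b, max_peak_dist_Mb = 20) {
  max_peak_dist_Mb <- check_number(max_peak_dist_Mb, "max_peak_dist_Mb", min = 0)
  ok_a <- stats::complete.cases(qtls_a[, c("peak_Mb", "lo_Mb", "hi_Mb")])
  ok_b <- stats::complete.cases(qtls_b[, c("peak_Mb", "lo_Mb", "hi_Mb")])
  if (any(!ok_a) || any(!ok_b))
    warning("skipping QTL records without Mb coordinates", call. = FALSE)
  a <- qtls_a[ok_a, , drop = FALSE]
  b <- qtls_b[ok_b, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(a))) {
    j <- which(b$chrom == a$chrom[i])
    if (!length(j)) next
    overlap <- a$lo_Mb[i] <= b$hi_Mb[j] & b$lo_Mb[j] <= a$hi_Mb[i]
    pd <- abs(a$peak_Mb[i] - b$peak_Mb[j])
    hit <- overlap | pd <= max_peak_dist_Mb
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        id_a = a$id[i], id_b = b$id[j[hit]], chrom = a$chrom[i],
        basis = ifelse(overlap[hit], "interval-overlap", "peak-distance"),
        peak_dist_Mb = pd[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(id_a = character(0), id_b = character(0),
                      chrom = character(0), basis = character(0),
                      peak_dist_Mb = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# transitive-closure components of a single record set under the
# co-localization relation (self-matches removed); returns integer labels
coloc_components <- function(recs, max_peak_dist_Mb = 20) {
  n <- nrow(recs)
  if (!n) return(integer(0))
  tmp <- recs
  tmp$id <- as.character(seq_len(n))
  m <- colocalize(tmp, tmp, max_peak_dist_Mb)
  m <- m[m$id_a != m$id_b, , drop = FALSE]
  union_find(n, cbind(as.integer(m$id_a), as.integer(m$id_b)))
}

#' Consolidate QTL detected in single environments and the joint analysis
#'
#' Keeps only the loci detected in two or more environments (per-trait
#' clusters under the co-localization rule) or present in the joint
#' analysis.  Each cluster is reported once: the joint record when available
#' (highest-LOD joint record if several), otherwise the highest-LOD
#' environment record.
#'
#' @param records A `"qtl_records"` data.frame pooling environment-specific
#'   and joint records (dataset column distinguishes them), or a list of such
#'   frames.
#' @param joint_label Dataset tag of the joint analysis (default `"joint"`;
#'   `"C"` is also recognised).
#' @param max_peak_dist_Mb Co-localization threshold.
#' @return A consolidated `"qtl_records"` data.frame with extra columns
#'   `n_env`, `envs` (slash-separated dataset tags) and `members`.
#' @export
consolidate_environments <- function(records, joint_label = "joint",
                                     max_peak_dist_Mb = 20) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  if (!nrow(records)) return(cbind(empty_qtl_records(),
                                   n_env = integer(0), envs = character(0),
                                   members = character(0)))
  out <- list()
  for (tr in unique(records$trait)) {
    recs <- records[records$trait == tr, , drop = FALSE]
    comp <- coloc_components(recs, max_peak_dist_Mb)
    for (k in unique(comp)) {
      idx <- which(comp == k)
      is_joint <- recs$dataset[idx] %in% c(joint_label, "C")
      envs <- unique(recs$dataset[idx][!is_joint])
      if (length(envs) < 2L && !any(is_joint)) next
      rep_idx <- if (any(is_joint)) {
        jj <- idx[is_joint]
        jj[which.max(recs$lod[jj])]
      } else idx[which.max(recs$lod[idx])]
      rec <- recs[rep_idx, , drop = FALSE]
      rec$n_env <- length(envs)
      rec$envs <- paste(unique(c(envs, if (any(is_joint)) joint_label)),
                        collapse = "/")
      rec$members <- paste(recs$id[idx], collapse = ",")
      out[[length(out) + 1L]] <- rec
    }
  }
  if (!length(out))
    return(cbind(empty_qtl_records(), n_env = integer(0), envs = character(0),
                 members = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$trait, res$chrom, res$peak_cM), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("qtl_records", "data.frame")
  res
}

#' Classify consolidated loci as shared, per-se-only, or GCA-only
#'
#' Matches consolidated per se loci against consolidated GCA loci of the
#' same trait under the co-localization rule.  Shared ("both") loci carry a
#' sign-concordance flag comparing the additive-effect directions.
#'
#' @param perse_qtls,gca_qtls Consolidated `"qtl_records"` for the per se and
#'   GCA analyses.
#' @param max_peak_dist_Mb Co-localization threshold.
#' @return List with `table` (one row per locus: trait, category, ids, sign
#'   concordance) and `counts` (per trait and total counts of both /
#'   per-se-only / gca-only).
#' @export
classify_perse_vs_gca <- function(perse_qtls, gca_qtls, max_peak_dist_Mb = 20) {
  rows <- list()
  traits <- union(unique(perse_qtls$trait), unique(gca_qtls$trait))
  for (tr in traits) {
    p <- perse_qtls[perse_qtls$trait == tr, , drop = FALSE]
    g <- gca_qtls[gca_qtls$trait == tr, , drop = FALSE]
    m <- if (nrow(p) && nrow(g)) colocalize(p, g, max_peak_dist_Mb)
    else data.frame(id_a = character(0), id_b = character(0))
    for (i in seq_len(nrow(p))) {
      hits <- m$id_b[m$id_a == p$id[i]]
      if (length(hits)) {
        j <- match(hits[1L], g$id)
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, category = "both", id_perse = p$id[i], id_gca = g$id[j],
          chrom = p$chrom[i], peak_Mb_perse = p$peak_Mb[i],
          peak_Mb_gca = g$peak_Mb[j],
          sign_concordant = sign(p$add[i]) == sign(g$add[j]),
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, category = "per-se-only", id_perse = p$id[i],
          id_gca = NA_character_, chrom = p$chrom[i],
          peak_Mb_perse = p$peak_Mb[i], peak_Mb_gca = NA_real_,
          sign_concordant = NA, stringsAsFactors = FALSE)
      }
    }
    unmatched_g <- setdiff(g$id, m$id_b)
    for (idb in unmatched_g) {
      j <- match(idb, g$id)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, category = "GCA-only", id_perse = NA_character_,
        id_gca = idb, chrom = g$chrom[j], peak_Mb_perse = NA_real_,
        peak_Mb_gca = g$peak_Mb[j], sign_concordant = NA,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait = character(0), category = character(0),
               id_perse = character(0), id_gca = character(0),
               chrom = character(0), peak_Mb_perse = numeric(0),
               peak_Mb_gca = numeric(0), sign_concordant = logical(0),
               stringsAsFactors = FALSE)
  counts <- as.data.frame.matrix(table(tab$trait,
                                       factor(tab$category,
                                              c("both", "per-se-only", "GCA-only"))))
  list(table = tab, counts = counts,
       totals = colSums(counts[, , drop = FALSE]))
}

#' Group QTL into pleiotropic loci across traits
#'
#' Builds the transitive closure of pairwise co-localization matches across
#' all records (any trait) and reports one component per locus with the set
#' of traits it affects.
#'
#' @param records A `"qtl_records"` data.frame across traits.
#' @param max_peak_dist_Mb Co-localization threshold.
#' @return List with `components` (data.frame: component, chrom, n_traits,
#'   traits, members) and `by_n_traits` (table of component counts by number
#'   of affected traits).
#' @export
pleiotropy_report <- function(records, max_peak_dist_Mb = 20) {
  if (!nrow(records))
    return(list(components = data.frame(component = integer(0),
                                        chrom = character(0),
                                        n_traits = integer(0),
                                        traits = character(0),
                                        members = character(0)),
                by_n_traits = table(integer(0))))
  comp <- coloc_components(records, max_peak_dist_Mb)
  comps <- do.call(rbind, lapply(sort(unique(comp)), function(k) {
    idx <- which(comp == k)
    trs <- sort(unique(records$trait[idx]))
    data.frame(component = k, chrom = records$chrom[idx[1L]],
               n_traits = length(trs), traits = paste(trs, collapse = "/"),
               members = paste(records$id[idx], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  list(components = comps, by_n_traits = table(comps$n_traits))
}
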