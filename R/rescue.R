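# Rescued CAGE Peaks (RCP): assign genes to un-annotated destination
# peaks via their matched, annotated, projected source peaks and an
# orthology table, with a maximum gene distance.

# minimum gap in bp between [a1,b1) and [a2,b2); 0 when overlapping
.interval_gap <- function(a1, b1, a2, b2) {
  pmax(0L, pmax(a2 - b1 + 1L, a1 - b2 + 1L) - 1L)
}

#' Rescue un-annotated destination peaks through orthology
#'
#' A destination peak is rescued iff (a) it has zero gene associations
#' in every annotation set, (b) it has a boundary match to a projected
#' source peak, (c) that source peak is annotated with at least one
#' source gene, (d) the orthology table maps such a gene to a
#' destination gene, and (e) some model of that destination gene lies
#' within `max_gene_dist` bp of the peak (minimum gap between the peak
#' interval and the gene span; 0 when overlapping). When several
#' ortholog routes qualify, all are reported, nearest gene first.
#' Orthology rows naming genes absent from the source associations or
#' destination models are skipped (with a warning when they drop a
#' candidate route). Output ordering is deterministic and independent of
#' input row order.
#'
#' @param dest_peaks Destination peak table.
#' @param dest_associations [associate_peaks_to_genes()] output for the
#'   destination peaks over all annotation sets.
#' @param matches [match_projected_peaks()] output.
#' @param source_associations Association table for the source peaks
#'   (the well-annotated reference species).
#' @param orthology Table with columns `source_gene`, `dest_gene`.
#' @param dest_models Destination gene model table (used for distances;
#'   typically a superset of the annotation actually loaded, e.g. genes
#'   missing from the destination annotation sets).
#' @param max_gene_dist Maximum peak-to-gene distance (default 10000).
#' @return `data.table` of class rows: `dest_peak`, `source_peak`,
#'   `source_gene`, `dest_gene`, `gene_distance`, `width`.
#' @export
rescue_unannotated_peaks <- function(dest_peaks, dest_associations,
                                     matches, source_associations,
                                     orthology, dest_models,
                                     max_gene_dist = 10000) {
  dp <- as.data.table(dest_peaks)
  da <- as.data.table(dest_associations)
  mt <- as.data.table(matches)[!is.na(dest_peak)]
  sa <- as.data.table(source_associations)
  ot <- as.data.table(orthology)
  gm <- as.data.table(dest_models)
  empty <- data.table(dest_peak = character(), source_peak = character(),
                      source_gene = character(), dest_gene = character(),
                      gene_distance = integer(), width = integer())
  if (nrow(dp) == 0L || nrow(mt) == 0L) return(empty)
  unannotated <- setdiff(dp$name, unique(da$peak))
  mt <- mt[dest_peak %in% unannotated]
  if (nrow(mt) == 0L) return(empty)
  out <- list()
  skipped <- 0L
  for (i in seq_len(nrow(mt))) {
    src_genes <- unique(sa[peak == mt$source_peak[i], gene_id])
    if (length(src_genes) == 0L) next
    pk <- dp[name == mt$dest_peak[i]]
    for (g in src_genes) {
      dest_genes <- unique(ot[source_gene == g, dest_gene])
      if (length(dest_genes) == 0L) next
      for (g2 in dest_genes) {
        models <- gm[gene_id == g2 & chrom == pk$chrom]
        if (nrow(models) == 0L) {
          if (nrow(gm[gene_id == g2]) == 0L) skipped <- skipped + 1L
          next
        }
        d <- min(.interval_gap(pk$start, pk$end,
                               models$tx_start, models$tx_end))
        if (d <= max_gene_dist) {
          out[[length(out) + 1L]] <- data.table(
            dest_peak = mt$dest_peak[i], source_peak = mt$source_peak[i],
            source_gene = g, dest_gene = g2,
            gene_distance = as.integer(d),
            width = pk$end - pk$start)
        }
      }
    }
  }
  if (skipped > 0L) {
    warning(skipped, " orthology route(s) referenced genes without ",
            "destination models; skipped", call. = FALSE)
  }
  res <- rbindlist(out)
  if (nrow(res) == 0L) return(empty)
  res <- unique(res, by = c("dest_peak", "dest_gene"))
  setorder(res, dest_peak, gene_distance, dest_gene)
  res[]
}

#' Summary statistics of a rescued peak set
#'
#' @param rescued Output of [rescue_unannotated_peaks()].
#' @param dest_models Destination gene model table.
#' @param tf_list Optional character vector of transcription factor gene
#'   ids to intersect with the rescued genes.
#' @return List: `n_rcp` (distinct rescued peaks), `n_genes`,
#'   `median_width` (bp), `median_gene_length` (bp, span of the longest
#'   model per rescued gene), `frac_orf_like` (fraction of rescued genes
#'   whose transcription start coincides with the coding start),
#'   `rcp_per_gene` (named integer vector), `tf_genes` (intersection
#'   with `tf_list`). All numeric entries are `NA`/empty for an empty
#'   rescue set.
#' @export
rcp_summary_stats <- function(rescued, dest_models, tf_list = NULL) {
  r <- as.data.table(rescued)
  gm <- as.data.table(dest_models)
  if (nrow(r) == 0L) {
    return(list(n_rcp = 0L, n_genes = 0L, median_width = NA_real_,
                median_gene_length = NA_real_, frac_orf_like = NA_real_,
                rcp_per_gene = integer(), tf_genes = character()))
  }
  widths <- unique(r, by = "dest_peak")$width
  genes <- unique(r$dest_gene)
  gene_len <- vapply(genes, function(g) {
    m <- gm[gene_id == g]
    if (nrow(m) == 0L) return(NA_real_)
    max(m$tx_end - m$tx_start)
  }, numeric(1))
  orf_like <- vapply(genes, function(g) {
    m <- gm[gene_id == g & !is.na(cds_start)]
    if (nrow(m) == 0L) return(NA)
    any(ifelse(m$strand == "+", m$tx_start == m$cds_start,
               m$tx_end == m$cds_end))
  }, logical(1))
  per_gene <- r[, .(n = uniqueN(dest_peak)), by = dest_gene]
  rcp_per_gene <- stats::setNames(per_gene$n, per_gene$dest_gene)
  list(n_rcp = uniqueN(r$dest_peak),
       n_genes = length(genes),
       median_width = stats::median(widths),
       median_gene_length = stats::median(gene_len, na.rm = TRUE),
       frac_orf_like = mean(orf_like, na.rm = TRUE),
       rcp_per_gene = rcp_per_gene,
       tf_genes = if (is.null(tf_list)) character() else
         intersect(genes, tf_list))
}
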