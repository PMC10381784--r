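#' Zone summary table of a motif scan
#'
#' One row per order: promoters considered, promoters without any motif,
#' coding/noncoding motif counts per TSS-distance zone, per-strand totals,
#' and the mean motif count per species.
#'
#' @param motifs Motif table from [scan_set()].
#' @param set The scanned `promoter_set`.
#' @return One-row data.frame.
#' @export
report_zone_table <- function(motifs, set) {
  zones <- c("core", "proximal", "distal")
  strands <- c("coding", "noncoding")
  n_prom <- nrow(set$promoters)
  with_motifs <- unique(motifs$species_code)
  counts <- sapply(strands, function(st) {
    sapply(zones, function(z) {
      sum(motifs$strand == st & motifs$zone == z)
    })
  })
  out <- data.frame(order_code = set$order_code, n_promoters = n_prom,
                    n_no_motifs = sum(!(set$promoters$species_code %in% with_motifs)))
  for (z in zones) {
    for (st in strands) out[[paste(z, st, sep = "_")]] <- counts[z, st]
  }
  out$total_coding <- sum(motifs$strand == "coding")
  out$total_noncoding <- sum(motifs$strand == "noncoding")
  out$mean_motifs_per_species <- if (n_prom) nrow(motifs) / n_prom else 0
  out
}

#' Binned TSS-distance histogram per strand
#'
#' @param motifs Motif table.
#' @param bin_width Bin width in nt (default 50).
#' @param max_distance Upper edge of the last bin (default 1000).
#' @return Data.frame bin_start, bin_end, coding, noncoding.
#' @export
report_distance_histogram <- function(motifs, bin_width = 50L,
                                      max_distance = 1000L) {
  starts <- seq(0L, max_distance - bin_width, by = bin_width)
  data.frame(
    bin_start = starts, bin_end = starts + bin_width - 1L,
    coding = vapply(starts, function(s) {
      sum(motifs$strand == "coding" & motifs$tss_distance >= s &
            motifs$tss_distance < s + bin_width)
    }, 0L),
    noncoding = vapply(starts, function(s) {
      sum(motifs$strand == "noncoding" & motifs$tss_distance >= s &
            motifs$tss_distance < s + bin_width)
    }, 0L))
}

#' Run the full analysis for one promoter set (one order)
#'
#' scan -> blocks -> clusters -> groups -> substitutions -> loop-vs-control
#' test. Deterministic for a fixed input.
#'
#' @param set A `promoter_set`.
#' @param min_intersection Cluster intersection size (default 12).
#' @param min_identity,min_width Block reliability criteria.
#' @param k Anchor k-mer size for block building.
#' @param blocks Optional pre-built block list (e.g. imported via
#'   [read_blocks()]); built with [build_blocks()] when `NULL`.
#' @param min_members Minimum conserved-group size.
#' @return List: set, motifs, blocks, clusters, groups, group_summary,
#'   loop_subs, tract_subs, test (from [run_order_test()]), zone_table,
#'   histogram.
#' @export
run_order_analysis <- function(set, min_intersection = 12L,
                               min_identity = 0.8, min_width = 100L,
                               k = 12L, blocks = NULL, min_members = 2L) {
  motifs <- scan_set(set)
  if (is.null(blocks)) {
    blocks <- build_blocks(set, k = k, min_identity = min_identity,
                           min_width = min_width)
  }
  clusters <- cluster_blocks(blocks, motifs, min_intersection)
  groups <- call_groups(blocks, clusters, set, min_members)
  loop_subs <- do.call(rbind, c(list(sub_record_df()), lapply(groups, function(g) {
    count_loop_substitutions(g, blocks[[g$block_name]])
  })))
  tract_subs <- do.call(rbind, lapply(groups, function(g) {
    count_tract_substitutions(g, blocks[[g$block_name]], motifs)
  }))
  test <- run_order_test(groups, blocks, motifs, set$order_code)
  list(set = set, motifs = motifs, blocks = blocks, clusters = clusters,
       groups = groups,
       group_summary = summarize_groups(groups, set$order_code),
       loop_subs = loop_subs, tract_subs = tract_subs, test = test,
       zone_table = report_zone_table(motifs, set),
       histogram = report_distance_histogram(
         motifs, max_distance = max(set$promoters$length)))
}

#' Run several orders and adjust the test family
#'
#' @param sets Named list of `promoter_set`s (one per order).
#' @param ... Passed to [run_order_analysis()].
#' @return List: per-order results plus `family` — the Table-3-shaped
#'   data.frame with Holm-adjusted p-values across the orders run together.
#' @export
run_all_orders <- function(sets, ...) {
  results <- lapply(sets, run_order_analysis, ...)
  family <- adjust_family(lapply(results, `[[`, "test"))
  list(orders = results, family = family)
}

#' Substitution-type spectrum table
#'
#' Counts of unordered substitution-type labels (coding-strand orientation)
#' by strand, the shape used for tract- and loop-substitution spectra.
#'
#' @param subs Substitution record data.frame carrying a `type` column.
#' @param groups Group list (to attach each record's strand).
#' @return Data.frame strand, type, n.
#' @export
spectrum_table <- function(subs, groups) {
  if (is.null(subs) || nrow(subs) == 0) {
    return(data.frame(strand = character(), type = character(), n = integer()))
  }
  strand_of <- setNames(vapply(groups, `[[`, "", "strand"),
                        vapply(groups, `[[`, "", "group_id"))
  subs$strand <- strand_of[subs$group_id]
  agg <- aggregate(list(n = seq_len(nrow(subs))),
                   by = list(strand = subs$strand, type = subs$type),
                   FUN = length)
  agg[order(agg$strand, agg$type), ]
}

#' Write the result tables of one order analysis
#'
#' Emits every table as TSV with a JSON twin: motif table, block index and
#' aligned FASTA, cluster table, group summary, substitution records,
#' density pairs and the test row.
#'
#' @param res Result of [run_order_analysis()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_order_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, stem) {
    write_tsv(df, file.path(dir, paste0(stem, ".tsv")))
    jsonlite::write_json(df, file.path(dir, paste0(stem, ".json")),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  emit(res$motifs, "motifs")
  write_blocks(res$blocks, file.path(dir, "blocks"))
  emit(cluster_table(res$clusters), "clusters")
  emit(res$group_summary$counts, "group_counts")
  emit(res$group_summary$lengths, "group_lengths")
  emit(res$loop_subs, "loop_substitutions")
  if (!is.null(res$tract_subs)) emit(res$tract_subs, "tract_substitutions")
  if (!is.null(res$test$pairs)) emit(res$test$pairs, "density_pairs")
  emit(res$zone_table, "zone_table")
  emit(res$histogram, "tss_distance_histogram")
  invisible(dir)
}
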