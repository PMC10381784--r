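#!/usr/bin/env Rscript

# Cluster motif coordinates inside block alignments and call groups of
# conserved G4 motifs (shared G-tract columns, membership maximised by
# locally shifting tracts within longer runs). Tabulate groups per order,
# strand and zone, plus the group length distribution, and check recovery
# of the planted motifs.

library(g4cons)

out <- "results/analysis"
manifest <- read.delim(file.path(out, "manifest.tsv"))

counts <- NULL; lengths <- NULL; recovery <- NULL
for (i in seq_len(nrow(manifest))) {
  ord <- manifest$order[i]
  set <- read_promoters(manifest$fasta[i], ord)
  blocks <- read_blocks(file.path(out, paste0("blocks_", ord)), set = set)
  motifs <- read.delim(file.path(out, paste0("motifs_", ord, ".tsv")))
  clusters <- cluster_blocks(blocks, motifs)
  groups <- call_groups(blocks, clusters, set)
  saveRDS_path <- file.path(out, paste0("groups_", ord, ".tsv"))
  gdf <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group_id = g$group_id, block = g$block_name, strand = g$strand,
               n_members = length(g$members), zone = g$zone,
               tract_cols = paste(t(g$tract_cols), collapse = ","),
               members = paste(g$members, collapse = ","))
  }))
  write.table(gdf, saveRDS_path, sep = "\t", quote = FALSE, row.names = FALSE)
  sm <- summarize_groups(groups, ord)
  counts <- rbind(counts, sm$counts)
  if (nrow(sm$lengths)) {
    lengths <- rbind(lengths, cbind(order = ord, sm$lengths))
  }
  planted <- read.delim(file.path(out, paste0("planted_", ord, ".tsv")))
  rec <- sum(vapply(seq_len(nrow(planted)), function(mi) {
    tv <- matrix(unlist(planted[mi, 5:12]), ncol = 2, byrow = TRUE)
    any(vapply(groups, function(g) {
      g$strand == planted$strand[mi] &&
        any(apply(g$member_tract_pos, 1, function(r) {
          rm <- matrix(r, ncol = 2, byrow = TRUE)
          all(rm[, 1] >= tv[, 1] & rm[, 2] <= tv[, 2])
        }))
    }, logical(1)))
  }, logical(1)))
  recovery <- rbind(recovery, data.frame(order = ord, planted = nrow(planted),
                                         recovered = rec))
  cat(sprintf("order %s: %d clusters -> %d conserved groups; %d/%d planted recovered\n",
              ord, length(clusters), length(groups), rec, nrow(planted)))
}
write.table(counts, file.path(out, "group_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(lengths, file.path(out, "group_lengths.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(recovery, file.path(out, "planted_recovery.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("total groups by strand:\n")
print(tapply(counts$n, counts$strand, sum))
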