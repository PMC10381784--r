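#' Enumerate feasible tract placements for each cluster member
#'
#' For every member species of a cluster, all placements of four tracts on
#' the motif-bearing strand are enumerated from the letter-runs (G-runs for
#' coding-strand motifs, C-runs on the coding-strand row for noncoding
#' motifs) of the species' ungapped fragment sequence near the cluster's
#' common window. Longer runs contribute the whole run plus every length-3
#' sub-run (coordinate shifting). Scanner constraints are re-checked on the
#' ungapped sequence: loops of 1-30 nt, span <= 45 nt, every tract inside
#' the 45-nt window anchored at the first tract's start.
#'
#' @param cluster One cluster from [find_clusters()].
#' @param block The `alignment_block` the cluster lives in.
#' @param margin Columns around the common window searched for runs
#'   (default 50).
#' @return Named list (by species) of placement matrices with column
#'   intervals `c1s..c4e` and ungapped fragment coordinates `u1s..u4e`,
#'   one row per placement.
#' @export
enumerate_placements <- function(cluster, block, margin = 50L,
                                 row_cache = NULL) {
  species <- unique(cluster$members$species_code)
  letter <- if (cluster$strand == "coding") "G" else "C"
  lo <- cluster$common_first - margin
  hi <- cluster$common_last + margin
  res <- list()
  for (sp in species) {
    i <- match(sp, block$species)
    if (!is.null(row_cache)) {
      cols <- row_cache$cols[[i]]; useq <- row_cache$useq[i]
    } else {
      cols <- which(strsplit(block$rows[i], "")[[1]] != "-")
      useq <- gsub("-", "", block$rows[i], fixed = TRUE)
    }
    runs <- base_runs(useq, letter, 3L)
    if (nrow(runs)) {
      rc_start <- cols[runs$start]; rc_end <- cols[runs$end]
      runs <- runs[rc_end >= lo & rc_start <= hi, , drop = FALSE]
    }
    res[[sp]] <- placements_from_runs(runs, cols)
  }
  res
}

# 4-tuple enumeration over tract placements in ungapped coordinates, with
# column projections. Mirrors the scanner's constraints. Returns a 16-column
# integer matrix (c1s..c4e, u1s..u4e).
placements_from_runs <- function(runs, cols) {
  empty <- matrix(integer(), ncol = 16, nrow = 0,
                  dimnames = list(NULL, placement_names()))
  if (nrow(runs) < 1) return(empty)
  tr <- tract_placements(runs)
  if (nrow(tr) < 4) return(empty)
  u <- enumerate_tuples(tr$start, tr$end)
  if (nrow(u) == 0) return(empty)
  out <- cbind(matrix(cols[u], nrow = nrow(u)), u)
  colnames(out) <- placement_names()
  out
}

placement_names <- function() {
  c("c1s", "c1e", "c2s", "c2e", "c3s", "c3e", "c4s", "c4e",
    "u1s", "u1e", "u2s", "u2e", "u3s", "u3e", "u4s", "u4e")
}

#' Call a conserved group from enumerated placements
#'
#' Selects the 4-tuple of tract column intervals realizable by the largest
#' number of species (ties: larger column overlap with the cluster's common
#' window — anchoring the group to the motifs that formed the cluster —
#' then more total tract columns, then smaller first column, then
#' lexicographic signature). Returns `NULL` when the best
#' support is below `min_members`. Species of the block without a feasible
#' placement at the chosen columns are attached as non-member rows for
#' downstream tract-substitution counting.
#'
#' @param placements Output of [enumerate_placements()].
#' @param cluster,block The cluster and block the placements came from.
#' @param promoter_length Named vector of promoter lengths by species code
#'   (used for per-member TSS distances and the group zone).
#' @param min_members Minimum member count (default 2).
#' @return A `conserved_group` list or `NULL`: block_name, strand,
#'   tract_cols (4x2 matrix), loop_cols (3x2 matrix), members, member
#'   coordinates, nonmembers, zone, low_confidence flag.
#' @export
call_group <- function(placements, cluster, block, promoter_length,
                       min_members = 2L) {
  sp_keys <- list(); sp_mat <- list()
  for (sp in names(placements)) {
    pl <- placements[[sp]]
    if (nrow(pl) == 0) next
    key <- paste(pl[, 1], pl[, 2], pl[, 3], pl[, 4], pl[, 5], pl[, 6],
                 pl[, 7], pl[, 8], sep = ":")
    first <- !duplicated(key)
    sp_keys[[sp]] <- key[first]
    sp_mat[[sp]] <- pl[first, , drop = FALSE]
  }
  if (length(sp_keys) == 0) return(NULL)
  keys_all <- unlist(sp_keys, use.names = FALSE)
  species_all <- rep(names(sp_keys), lengths(sp_keys))
  mat_all <- do.call(rbind, sp_mat)
  tb <- table(keys_all)
  keys <- names(tb)
  support <- as.integer(tb)
  frow <- match(keys, keys_all)
  cols <- mat_all[frow, 1:8, drop = FALSE]
  total_cols <- rowSums(cols[, c(2, 4, 6, 8), drop = FALSE] -
                          cols[, c(1, 3, 5, 7), drop = FALSE] + 1L)
  # anchor to the cluster: prefer variants overlapping the common window
  overlap <- pmax(0L, pmin(cols[, 8], cluster$common_last) -
                    pmax(cols[, 1], cluster$common_first) + 1L)
  ord <- order(-support, -overlap, -total_cols, cols[, 1], keys)
  best <- ord[1]
  if (support[best] < min_members) return(NULL)
  tract_cols <- matrix(cols[best, ], ncol = 2, byrow = TRUE)
  loop_cols <- cbind(tract_cols[1:3, 2] + 1L, tract_cols[2:4, 1] - 1L)
  hit <- which(keys_all == keys[best])
  # columns flanking a tract where every member still carries the tract
  # letter belong to the conserved run (tracts of "three or more" G), not to
  # the loop: trim them so loop densities are not diluted by invariant G/C
  loop_cols <- trim_conserved_run_columns(
    loop_cols, block, species_all[hit],
    if (cluster$strand == "coding") "G" else "C")
  members <- species_all[hit]
  o <- order(members)
  members <- members[o]
  member_u <- mat_all[hit[o], 9:16, drop = FALSE]
  fi <- match(members, block$species)
  tract_pos <- member_u + block$start[fi] - 1L  # promoter coordinates
  rownames(tract_pos) <- members
  mstart <- tract_pos[, 1]
  mend <- tract_pos[, 8]
  zones <- zone_of(promoter_length[members] - mend)
  zone <- modal_zone(zones)
  partial <- cluster$members$partial[match(members, cluster$members$species_code)]
  structure(list(
    block_name = block$name, strand = cluster$strand,
    tract_cols = tract_cols, loop_cols = loop_cols,
    members = members,
    member_start = setNames(as.integer(mstart), members),
    member_end = setNames(as.integer(mend), members),
    member_tract_pos = tract_pos,
    member_zone = setNames(zones, members),
    nonmembers = setdiff(block$species, members),
    zone = zone,
    low_confidence = all(partial %in% TRUE),
    group_id = NA_character_
  ), class = "conserved_group")
}

trim_conserved_run_columns <- function(loop_cols, block, members, letter) {
  m <- do.call(rbind, strsplit(block$rows[match(members, block$species)], ""))
  all_letter <- colSums(m != letter) == 0
  for (l in 1:3) {
    a <- loop_cols[l, 1]; b <- loop_cols[l, 2]
    while (a <= b && all_letter[a]) a <- a + 1L
    while (b >= a && all_letter[b]) b <- b - 1L
    loop_cols[l, ] <- c(a, b)
  }
  loop_cols
}

zone_of <- function(d) {
  ifelse(d <= 180L, "core", ifelse(d <= 500L, "proximal", "distal"))
}

# Modal zone; ties resolved toward the TSS (core < proximal < distal).
modal_zone <- function(zones) {
  lv <- c("core", "proximal", "distal")
  tb <- table(factor(zones, levels = lv))
  lv[which.max(tb)]
}

#' Call conserved groups for all clusters of an analysis
#'
#' @param blocks Named list of `alignment_block`s.
#' @param clusters List from [cluster_blocks()].
#' @param set The `promoter_set` (for promoter lengths).
#' @param min_members Minimum group size (default 2).
#' @return List of `conserved_group` objects with assigned `group_id`s.
#' @export
call_groups <- function(blocks, clusters, set, min_members = 2L) {
  plen <- setNames(set$promoters$length, set$promoters$species_code)
  caches <- lapply(blocks, function(b) {
    list(cols = lapply(strsplit(b$rows, ""), function(ch) which(ch != "-")),
         useq = gsub("-", "", b$rows, fixed = TRUE))
  })
  out <- list()
  seen <- character()
  for (cl in clusters) {
    b <- blocks[[cl$block_name]]
    pl <- enumerate_placements(cl, b, row_cache = caches[[cl$block_name]])
    g <- call_group(pl, cl, b, plen, min_members)
    if (is.null(g)) next
    key <- paste(g$block_name, g$strand, paste(t(g$tract_cols), collapse = ":"))
    if (key %in% seen) next  # two clusters can resolve to one group
    seen <- c(seen, key)
    out[[length(out) + 1]] <- g
  }
  for (i in seq_along(out)) out[[i]]$group_id <- sprintf("g%03d", i)
  out
}

#' @export
print.conserved_group <- function(x, ...) {
  cat(sprintf("conserved_group %s: %s strand, block %s, %d members, zone %s\n",
              x$group_id, x$strand, x$block_name, length(x$members), x$zone))
  invisible(x)
}

#' Group summary tables
#'
#' Counts of conserved groups by strand and TSS-distance zone, and the group
#' length distribution (length = median ungapped member span).
#'
#' @param groups List of `conserved_group`s.
#' @param order_code Order label attached to the table.
#' @return List with `counts` (order, strand, zone, n) and `lengths`
#'   (group_id, length).
#' @export
summarize_groups <- function(groups, order_code = "Unk") {
  zones <- c("core", "proximal", "distal")
  strands <- c("coding", "noncoding")
  counts <- expand.grid(order_code = order_code, strand = strands,
                        zone = zones, stringsAsFactors = FALSE)
  counts$n <- 0L
  lengths <- data.frame(group_id = character(), length = numeric())
  for (g in groups) {
    i <- which(counts$strand == g$strand & counts$zone == g$zone)
    counts$n[i] <- counts$n[i] + 1L
    lengths <- rbind(lengths, data.frame(
      group_id = g$group_id,
      length = median(g$member_end - g$member_start + 1)))
  }
  list(counts = counts, lengths = lengths)
}
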