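#' Map a motif to alignment columns of a block fragment
#'
#' Projects the motif's coding-strand interval onto the alignment columns of
#' the fragment belonging to the same species, using the fragment's gap
#' structure. Motifs extending past the fragment edge are returned with
#' `partial = TRUE`; motifs with no overlap yield `NULL`.
#'
#' @param motif One row of a motif table (list or single-row data.frame).
#' @param block An `alignment_block` containing a fragment of the motif's
#'   species (species mismatch is an error).
#' @return A one-row data.frame: block_name, species_code, strand,
#'   first_col, last_col, partial — or `NULL` if the motif misses the
#'   fragment.
#' @export
map_motif_to_columns <- function(motif, block) {
  i <- match(motif$species_code, block$species)
  if (is.na(i)) stop("species mismatch: ", motif$species_code,
                     " has no fragment in block ", block$name, call. = FALSE)
  cols <- which(strsplit(block$rows[i], "")[[1]] != "-")
  fs <- block$start[i]; fe <- block$end[i]
  s <- max(motif$start, fs); e <- min(motif$end, fe)
  if (s > e) return(NULL)
  data.frame(block_name = block$name, species_code = motif$species_code,
             strand = motif$strand,
             first_col = cols[s - fs + 1L], last_col = cols[e - fs + 1L],
             partial = motif$start < fs || motif$end > fe,
             stringsAsFactors = FALSE)
}

#' Map all motifs of a motif table into a block
#'
#' @param motifs Motif table from [scan_set()].
#' @param block An `alignment_block`.
#' @return Data.frame of column intervals (possibly 0 rows), with a
#'   `motif_row` column indexing back into `motifs`.
#' @export
map_block_motifs <- function(motifs, block) {
  empty <- data.frame(block_name = character(), species_code = character(),
                      strand = character(), first_col = integer(),
                      last_col = integer(), partial = logical(),
                      motif_row = integer())
  out <- list()
  for (i in seq_along(block$species)) {
    rows <- which(motifs$species_code == block$species[i])
    if (length(rows) == 0) next
    cols <- which(strsplit(block$rows[i], "")[[1]] != "-")
    fs <- block$start[i]; fe <- block$end[i]
    s <- pmax(motifs$start[rows], fs)
    e <- pmin(motifs$end[rows], fe)
    keep <- s <= e
    if (!any(keep)) next
    rows <- rows[keep]; s <- s[keep]; e <- e[keep]
    out[[length(out) + 1]] <- data.frame(
      block_name = block$name, species_code = block$species[i],
      strand = motifs$strand[rows],
      first_col = cols[s - fs + 1L], last_col = cols[e - fs + 1L],
      partial = motifs$start[rows] < fs | motifs$end[rows] > fe,
      motif_row = rows, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$motif_row), , drop = FALSE]
}

#' Cluster motif column intervals within one block and strand
#'
#' Clusters are maximal sets of intervals (>= 2 distinct species) sharing a
#' common column window of at least `min_intersection` columns; for 1-D
#' intervals, pairwise intersection of the required size is certified by the
#' common window. Each interval joins at most one cluster; clusters are
#' emitted greedily by largest common window (ties: smaller common start,
#' more members, lexicographic species list). Two intervals of the same
#' species never join one cluster together: the one with the smaller start
#' (then smaller end) is taken and the other is left for further clusters.
#' Singletons are never emitted.
#'
#' @param intervals Data.frame from [map_block_motifs()] — one block, one
#'   strand (mixed strands are an error).
#' @param min_intersection Minimum shared columns (default 12, the minimal
#'   shared content of two motifs: four tracts x 3 G).
#' @return List of clusters: each a list with `block_name`, `strand`,
#'   `members` (interval rows), `common_first`, `common_last`.
#' @export
find_clusters <- function(intervals, min_intersection = 12L) {
  if (nrow(intervals) == 0) return(list())
  if (length(unique(intervals$strand)) > 1) {
    stop("find_clusters expects intervals from a single strand", call. = FALSE)
  }
  if (length(unique(intervals$block_name)) > 1) {
    stop("find_clusters expects intervals from a single block", call. = FALSE)
  }
  avail <- seq_len(nrow(intervals))
  clusters <- list()
  repeat {
    cand <- best_cluster(intervals, avail, min_intersection)
    if (is.null(cand)) break
    clusters[[length(clusters) + 1]] <- cand$cluster
    avail <- setdiff(avail, cand$used)
  }
  clusters
}

best_cluster <- function(iv, avail, m) {
  if (length(avail) < 2) return(NULL)
  fc <- iv$first_col[avail]; lc <- iv$last_col[avail]
  windows <- expand.grid(a = sort(unique(fc)), b = sort(unique(lc)))
  windows <- windows[windows$b - windows$a + 1 >= m, , drop = FALSE]
  if (nrow(windows) == 0) return(NULL)
  best <- NULL
  for (r in seq_len(nrow(windows))) {
    a <- windows$a[r]; b <- windows$b[r]
    hit <- avail[fc <= a & lc >= b]
    if (length(hit) < 2) next
    # one interval per species: smaller start, then smaller end, then order
    o <- hit[order(iv$first_col[hit], iv$last_col[hit], hit)]
    o <- o[!duplicated(iv$species_code[o])]
    if (length(o) < 2) next
    cf <- max(iv$first_col[o]); cl <- min(iv$last_col[o])
    key <- list(len = cl - cf + 1, cf = cf, n = length(o),
                sp = paste(sort(iv$species_code[o]), collapse = ","))
    if (is.null(best) || better_cluster_key(key, best$key)) {
      best <- list(key = key, used = o,
                   cluster = list(block_name = iv$block_name[o[1]],
                                  strand = iv$strand[o[1]],
                                  members = iv[o, , drop = FALSE],
                                  common_first = cf, common_last = cl))
    }
  }
  best
}

better_cluster_key <- function(a, b) {
  if (a$len != b$len) return(a$len > b$len)
  if (a$cf != b$cf) return(a$cf < b$cf)
  if (a$n != b$n) return(a$n > b$n)
  a$sp < b$sp
}

#' Cluster all motifs over a list of blocks
#'
#' Runs [map_block_motifs()] and [find_clusters()] per block and strand.
#'
#' @param blocks List of `alignment_block`s.
#' @param motifs Motif table.
#' @param min_intersection See [find_clusters()].
#' @return Flat list of clusters across blocks and strands.
#' @export
cluster_blocks <- function(blocks, motifs, min_intersection = 12L) {
  out <- list()
  for (b in blocks) {
    iv <- map_block_motifs(motifs, b)
    for (st in c("coding", "noncoding")) {
      sub <- iv[iv$strand == st, , drop = FALSE]
      out <- c(out, find_clusters(sub, min_intersection))
    }
  }
  out
}

#' Cluster table for reporting
#' @param clusters List from [cluster_blocks()].
#' @return Data.frame, one row per cluster member.
#' @export
cluster_table <- function(clusters) {
  if (length(clusters) == 0) {
    return(data.frame(block_name = character(), cluster_id = integer(),
                      strand = character(), common_first = integer(),
                      common_last = integer(), species_code = character(),
                      first_col = integer(), last_col = integer(),
                      partial = logical()))
  }
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(block_name = cl$block_name, cluster_id = i, strand = cl$strand,
               common_first = cl$common_first, common_last = cl$common_last,
               species_code = cl$members$species_code,
               first_col = cl$members$first_col,
               last_col = cl$members$last_col,
               partial = cl$members$partial, stringsAsFactors = FALSE)
  }))
}
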