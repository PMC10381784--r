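#' G4 motif scanning under QGRS-style constraints
#'
#' A G4 motif is four G-tracts of at least three consecutive guanines,
#' separated by three loops of 1-30 nt, with a total span of at most 45 nt.
#' Every tract must lie inside the 45-nt window anchored at the first tract's
#' start, and tracts are strictly ordered without overlap. `N` never counts
#' as `G`, so an `N` breaks a G-tract; loops may contain any base including
#' `N`.
#'
#' Candidate tracts are taken from maximal G-runs: a run of length three is a
#' single tract; a longer run contributes the whole run plus every length-3
#' sub-run as alternative placements (the shifting used downstream when
#' matching tract coordinates across species).
#'
#' @param seq A nucleotide string over `{A,C,G,T,N}`.
#' @return `find_candidates()`: a data.frame of candidate motifs, one row per
#'   tract-placement tuple, with tract intervals `t1_start` .. `t4_end`
#'   (1-based, inclusive), loop sequences, loop lengths, `start`, `end` and
#'   `total_length`. Candidates may overlap.
#' @examples
#' find_candidates("GGGAGGGAGGGAGGG")
#' @export
find_candidates <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) == 0) return(empty_candidate_df())
  assert_dna(seq)
  runs <- base_runs(seq, "G", 3L)
  if (nrow(runs) == 0) return(empty_candidate_df())

  tr <- tract_placements(runs)
  if (nrow(tr) < 4L) return(empty_candidate_df())
  m <- enumerate_tuples(tr$start, tr$end)
  if (nrow(m) == 0L) return(empty_candidate_df())
  cand <- data.frame(
    start = m[, 1], end = m[, 8],
    t1_start = m[, 1], t1_end = m[, 2], t2_start = m[, 3], t2_end = m[, 4],
    t3_start = m[, 5], t3_end = m[, 6], t4_start = m[, 7], t4_end = m[, 8]
  )
  cand$total_length <- cand$end - cand$start + 1L
  cand$loop1 <- substring(seq, m[, 2] + 1L, m[, 3] - 1L)
  cand$loop2 <- substring(seq, m[, 4] + 1L, m[, 5] - 1L)
  cand$loop3 <- substring(seq, m[, 6] + 1L, m[, 7] - 1L)
  cand$loop_len1 <- m[, 3] - m[, 2] - 1L
  cand$loop_len2 <- m[, 5] - m[, 4] - 1L
  cand$loop_len3 <- m[, 7] - m[, 6] - 1L
  cand
}

# Enumerate all 4-tuples of tract placements with loops of 1-30 nt and every
# tract inside the 45-nt window anchored at the first tract's start (which,
# given the ordering, also caps the span at 45). Vectorised staged join over
# placements sorted by start. Returns an 8-column integer matrix
# (t1s,t1e,...,t4s,t4e).
enumerate_tuples <- function(start, end) {
  o <- order(start, end)
  ts <- as.integer(start[o]); te <- as.integer(end[o])
  first <- which(te <= ts + 44L)
  if (length(first) == 0L) return(matrix(integer(), ncol = 8))
  hist <- matrix(first, ncol = 1)
  e_last <- te[first]
  wend <- ts[first] + 44L
  for (level in 2:4) {
    lo <- findInterval(e_last + 1.5, ts) + 1L
    hi <- findInterval(e_last + 31.5, ts)
    cnt <- pmax(0L, hi - lo + 1L)
    idx <- rep(seq_along(e_last), cnt)
    nxt <- sequence(cnt) + rep(lo, cnt) - 1L
    keep <- te[nxt] <= wend[idx]
    idx <- idx[keep]; nxt <- nxt[keep]
    if (length(idx) == 0L) return(matrix(integer(), ncol = 8))
    hist <- cbind(hist[idx, , drop = FALSE], nxt)
    e_last <- te[nxt]
    wend <- wend[idx]
  }
  out <- matrix(0L, nrow(hist), 8)
  out[, c(1, 3, 5, 7)] <- matrix(ts[hist], nrow(hist), 4)
  out[, c(2, 4, 6, 8)] <- matrix(te[hist], nrow(hist), 4)
  out
}

# Tract placements derived from maximal G-runs: whole run plus all length-3
# sub-runs of longer runs. Maximal runs are disjoint, so no duplicates.
tract_placements <- function(runs) {
  long <- which(runs$length > 3L)
  counts <- runs$length[long] - 2L
  sub_start <- rep(runs$start[long], counts) + sequence(counts) - 1L
  data.frame(start = c(runs$start, sub_start),
             end = c(runs$end, sub_start + 2L))
}

empty_candidate_df <- function() {
  data.frame(start = integer(), end = integer(),
             t1_start = integer(), t1_end = integer(),
             t2_start = integer(), t2_end = integer(),
             t3_start = integer(), t3_end = integer(),
             t4_start = integer(), t4_end = integer(),
             total_length = integer(),
             loop1 = character(), loop2 = character(), loop3 = character(),
             loop_len1 = integer(), loop_len2 = integer(),
             loop_len3 = integer())
}

#' Candidate score used for non-overlap selection
#'
#' `10 * min(tract lengths, capped at 5) - population variance of the three
#' loop lengths - (total_length - 15) / 2`. Favours long tracts, short equal
#' loops, and compact motifs. Evaluated in exact integer arithmetic (scaled
#' by 18) so candidate ranking is free of floating-point ties.
#'
#' @param cand Candidate data.frame from [find_candidates()].
#' @return Numeric score vector.
#' @export
candidate_score <- function(cand) {
  mint <- pmin(cand$t1_end - cand$t1_start, cand$t2_end - cand$t2_start,
               cand$t3_end - cand$t3_start, cand$t4_end - cand$t4_start) + 1L
  mint <- pmin(mint, 5L)
  s <- cand$loop_len1 + cand$loop_len2 + cand$loop_len3
  q <- cand$loop_len1^2 + cand$loop_len2^2 + cand$loop_len3^2
  # population variance of the loops is (3q - s^2) / 9; everything times 18
  # stays integral
  score18 <- 180 * mint - 2 * (3 * q - s^2) - 9 * (cand$total_length - 15)
  score18 / 18
}

#' Greedy selection of non-overlapping motifs
#'
#' Candidates are ranked by descending [candidate_score()]; ties are broken by
#' smaller start, then shorter total length, then lexicographic concatenation
#' of the three loop sequences. Candidates overlapping an already-selected
#' motif are dropped.
#'
#' @param cand Candidate data.frame from [find_candidates()] (one strand of
#'   one promoter).
#' @return The selected subset, ordered by `start`.
#' @export
select_nonoverlapping <- function(cand) {
  if (nrow(cand) == 0) return(cand)
  sc <- candidate_score(cand)
  loopcat <- paste0(cand$loop1, cand$loop2, cand$loop3)
  ord <- order(-sc, cand$start, cand$total_length, loopcat)
  kept <- integer()
  for (i in ord) {
    if (!any(cand$start[i] <= cand$end[kept] & cand$end[i] >= cand$start[kept])) {
      kept <- c(kept, i)
    }
  }
  res <- cand[kept[order(cand$start[kept])], , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan both strands of a promoter for non-overlapping G4 motifs
#'
#' The coding strand is scanned as given; the noncoding strand is scanned on
#' the reverse complement and results are mapped back to coding-strand
#' coordinates (noncoding motifs appear as C-tract intervals on the coding
#' strand). Selection of non-overlapping motifs is independent per strand.
#' Tract intervals are reported in ascending coding-strand order; loop
#' sequences are read 5'->3' on the motif-bearing strand.
#'
#' @param sequence Promoter sequence (coding strand, 5'->3'; its last position
#'   abuts the TSS).
#' @param species_code Label attached to each reported motif.
#' @return A motif data.frame with strand, coordinates, tract intervals, loop
#'   sequences/lengths, `total_length`, `tss_distance` and `zone`.
#' @examples
#' scan_promoter("TTGGGAGGGAGGGAGGGTT", "PriHOsap")
#' @export
scan_promoter <- function(sequence, species_code = NA_character_) {
  sequence <- toupper(sequence)
  assert_dna(sequence)
  L <- nchar(sequence)

  coding <- select_nonoverlapping(find_candidates(sequence))
  if (nrow(coding)) coding$strand <- "coding"

  nc <- select_nonoverlapping(find_candidates(revcomp(sequence)))
  if (nrow(nc)) {
    nc <- mirror_coordinates(nc, L)
    nc$strand <- "noncoding"
  }

  res <- rbind(coding, if (nrow(nc)) nc else NULL)
  if (is.null(res) || nrow(res) == 0) {
    res <- empty_candidate_df()
    res$strand <- character()
  }
  res$species_code <- rep(species_code, nrow(res))
  res <- assign_zone(res, L)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res[, motif_columns()]
}

motif_columns <- function() {
  c("species_code", "strand", "start", "end",
    "t1_start", "t1_end", "t2_start", "t2_end",
    "t3_start", "t3_end", "t4_start", "t4_end",
    "loop1", "loop2", "loop3", "loop_len1", "loop_len2", "loop_len3",
    "total_length", "tss_distance", "zone")
}

# Map candidate coordinates found on the reverse complement back to the
# coding strand. Tract order is reversed so reported tracts ascend in coding
# coordinates; loops stay in motif-strand (5'->3' on noncoding) order.
mirror_coordinates <- function(cand, L) {
  mir <- function(s, e) list(start = L - e + 1L, end = L - s + 1L)
  t1 <- mir(cand$t1_start, cand$t1_end); t2 <- mir(cand$t2_start, cand$t2_end)
  t3 <- mir(cand$t3_start, cand$t3_end); t4 <- mir(cand$t4_start, cand$t4_end)
  out <- cand
  out$start <- L - cand$end + 1L
  out$end <- L - cand$start + 1L
  # motif-strand tract 4 is the leftmost interval on the coding strand
  out$t1_start <- t4$start; out$t1_end <- t4$end
  out$t2_start <- t3$start; out$t2_end <- t3$end
  out$t3_start <- t2$start; out$t3_end <- t2$end
  out$t4_start <- t1$start; out$t4_end <- t1$end
  out
}

#' Assign TSS-distance zones to motifs
#'
#' The promoter's last position abuts the TSS, so
#' `tss_distance = promoter_length - end` (the motif's TSS-proximal edge).
#' Zones: core 0-180, proximal 181-500, distal 501 and beyond.
#'
#' @param motifs Motif data.frame with an `end` column.
#' @param promoter_length Length of the promoter the motifs came from.
#' @return `motifs` with `tss_distance` and `zone` columns filled in.
#' @export
assign_zone <- function(motifs, promoter_length) {
  if (nrow(motifs) && any(motifs$end > promoter_length | motifs$start < 1)) {
    stop("motif coordinates fall outside the promoter", call. = FALSE)
  }
  d <- promoter_length - motifs$end
  motifs$tss_distance <- as.integer(d)
  motifs$zone <- ifelse(d <= 180L, "core", ifelse(d <= 500L, "proximal", "distal"))
  if (nrow(motifs) == 0) {
    motifs$tss_distance <- integer()
    motifs$zone <- character()
  }
  motifs
}

#' Scan every promoter of a set
#'
#' @param set A `promoter_set` (see [promoter_set()]).
#' @return Combined motif table for all species in the set.
#' @export
scan_set <- function(set) {
  stopifnot(inherits(set, "promoter_set"))
  res <- lapply(seq_len(nrow(set$promoters)), function(i) {
    scan_promoter(set$promoters$sequence[i], set$promoters$species_code[i])
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- scan_promoter("A", "x")[0, ]
  }
  rownames(out) <- NULL
  out
}
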