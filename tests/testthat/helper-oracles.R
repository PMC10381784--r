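# Independent oracles and fixture builders. These deliberately use naive
# loop-based implementations, separate from the package's vectorised code.

random_dna <- function(n, g = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rest <- (1 - g) / 3
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(rest, rest, g, rest)), collapse = "")
}

# Maximal runs of a letter, by character walk.
oracle_runs <- function(seq, letter = "G", min_len = 3L) {
  ch <- strsplit(seq, "")[[1]]
  out <- NULL
  i <- 1L
  while (i <= length(ch)) {
    if (ch[i] == letter) {
      j <- i
      while (j < length(ch) && ch[j + 1L] == letter) j <- j + 1L
      if (j - i + 1L >= min_len) out <- rbind(out, c(i, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(out)) matrix(integer(), ncol = 2) else out
}

# Tract placement universe: whole maximal run plus all length-3 sub-runs.
oracle_placements <- function(runs) {
  if (nrow(runs) == 0) return(matrix(integer(), ncol = 2))
  out <- NULL
  for (r in seq_len(nrow(runs))) {
    s <- runs[r, 1]; e <- runs[r, 2]
    out <- rbind(out, c(s, e))
    if (e - s + 1L > 3L) {
      for (a in s:(e - 2L)) out <- rbind(out, c(a, a + 2L))
    }
  }
  unique(out)
}

# Exhaustive candidate enumeration: every ordered 4-tuple of placements with
# loops 1-30 and all tracts inside the 45-nt window of the first tract.
oracle_candidates <- function(seq) {
  pl <- oracle_placements(oracle_runs(seq))
  if (nrow(pl) < 4) return(matrix(integer(), ncol = 8))
  pl <- pl[order(pl[, 1], pl[, 2]), , drop = FALSE]
  n <- nrow(pl)
  out <- NULL
  for (a in seq_len(n)) {
    wend <- pl[a, 1] + 44L
    if (pl[a, 2] > wend) next
    for (b in seq_len(n)) {
      if (pl[b, 1] < pl[a, 2] + 2L || pl[b, 1] > pl[a, 2] + 31L ||
          pl[b, 2] > wend) next
      for (cc in seq_len(n)) {
        if (pl[cc, 1] < pl[b, 2] + 2L || pl[cc, 1] > pl[b, 2] + 31L ||
            pl[cc, 2] > wend) next
        for (d in seq_len(n)) {
          if (pl[d, 1] < pl[cc, 2] + 2L || pl[d, 1] > pl[cc, 2] + 31L ||
              pl[d, 2] > wend) next
          out <- rbind(out, c(pl[a, ], pl[b, ], pl[cc, ], pl[d, ]))
        }
      }
    }
  }
  if (is.null(out)) matrix(integer(), ncol = 8) else out
}

candidate_matrix <- function(cand) {
  if (nrow(cand) == 0) return(matrix(integer(), ncol = 8))
  m <- as.matrix(cand[, c("t1_start", "t1_end", "t2_start", "t2_end",
                          "t3_start", "t3_end", "t4_start", "t4_end")])
  dimnames(m) <- NULL
  sort_tuples(m)
}

sort_tuples <- function(m) {
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  if (nrow(m) == 0) return(matrix(integer(), ncol = 8))
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

# Independent greedy selection: scalar score, explicit tie-breaks.
oracle_select <- function(cand) {
  if (nrow(cand) == 0) return(integer())
  n <- nrow(cand)
  sc <- numeric(n)
  for (i in seq_len(n)) {
    tl <- c(cand$t1_end[i] - cand$t1_start[i], cand$t2_end[i] - cand$t2_start[i],
            cand$t3_end[i] - cand$t3_start[i], cand$t4_end[i] - cand$t4_start[i]) + 1
    ll <- c(cand$loop_len1[i], cand$loop_len2[i], cand$loop_len3[i])
    # 18 * (10*min - popvar(ll) - (len-15)/2), integral: popvar*18 =
    # 6*sum(ll^2) - 2*sum(ll)^2 ... / 9 * 18 = 2*(3*sum(ll^2) - sum(ll)^2)
    sc[i] <- 180 * min(min(tl), 5) - (6 * sum(ll^2) - 2 * sum(ll)^2) -
      9 * (cand$total_length[i] - 15)
  }
  ord <- order(-sc, cand$start, cand$total_length,
               paste0(cand$loop1, cand$loop2, cand$loop3))
  kept <- integer()
  for (i in ord) {
    clash <- FALSE
    for (j in kept) {
      if (cand$start[i] <= cand$end[j] && cand$end[i] >= cand$start[j]) {
        clash <- TRUE; break
      }
    }
    if (!clash) kept <- c(kept, i)
  }
  sort(kept)
}

# Exact one-sided signed-rank p by enumerating the subset-sum distribution.
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  if (length(d) == 0) return(NA_real_)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  sums <- 0
  for (ri in r) sums <- c(sums, sums + ri)
  mean(sums >= W - 1e-9)
}

# Column consensus by explicit counting.
oracle_consensus <- function(rows, cols) {
  m <- do.call(rbind, strsplit(rows, ""))
  sapply(cols, function(j) {
    v <- m[, j]
    v <- v[v %in% c("A", "C", "G", "T")]
    if (length(v) == 0) return("-")
    tb <- sort(table(v), decreasing = TRUE)
    best <- names(tb)[tb == max(tb)]
    sort(best)[1]
  })
}

# Identity fraction by per-column walk.
oracle_identity <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  ok <- 0L
  for (j in seq_len(ncol(m))) {
    u <- unique(m[, j])
    if (length(u) == 1 && u %in% c("A", "C", "G", "T")) ok <- ok + 1L
  }
  ok / ncol(m)
}

# A gapless block over identical-coordinate fragments.
make_test_block <- function(rows, species = sprintf("TstSP%03d", seq_along(rows)),
                            start = rep(1L, length(rows))) {
  wid <- nchar(gsub("-", "", rows, fixed = TRUE))
  alignment_block(species, start, start + wid - 1L, rows)
}

# Planted-motif recovery against a pipeline result. A planted motif counts
# as recovered when a same-strand group exists in which some member's four
# tract intervals are sub-intervals of the planted tract runs.
planted_recovery <- function(truth, groups, exact = FALSE) {
  pl <- truth$planted
  hits <- logical(nrow(pl))
  for (mi in seq_len(nrow(pl))) {
    tv <- matrix(unlist(pl[mi, c("t1_start", "t1_end", "t2_start", "t2_end",
                                 "t3_start", "t3_end", "t4_start", "t4_end")]),
                 ncol = 2, byrow = TRUE)
    hits[mi] <- any(vapply(groups, function(gr) {
      if (gr$strand != pl$strand[mi]) return(FALSE)
      any(apply(gr$member_tract_pos, 1, function(r) {
        rm <- matrix(r, ncol = 2, byrow = TRUE)
        if (exact) all(rm == tv)
        else all(rm[, 1] >= tv[, 1] & rm[, 2] <= tv[, 2])
      }))
    }, logical(1)))
  }
  hits
}

null_alt_base_config <- function(seed) {
  sim_config(n_species = 8L, promoter_length = 1600L, n_motifs = 20L,
             background_rate = 0.02, loop_len = c(2L, 8L), seed = seed)
}
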