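#' Column consensus of block rows
#'
#' Per column, the most frequent base among `A,C,G,T` over the rows
#' considered; ties go to the lexicographically smallest base; columns with
#' no base (all gap/N) yield `-`.
#'
#' @param rows Character vector of equal-width gapped rows.
#' @param columns Columns to evaluate (default: all).
#' @return Character vector of consensus symbols, one per requested column.
#' @export
column_consensus <- function(rows, columns = NULL) {
  m <- do.call(rbind, strsplit(rows, ""))
  if (is.null(columns)) columns <- seq_len(ncol(m))
  vapply(columns, function(j) {
    tb <- table(factor(m[, j], levels = c("A", "C", "G", "T")))
    if (sum(tb) == 0) "-" else names(tb)[which.max(tb)]
  }, "")
}

#' Total loop length of a group in columns
#' @param group A `conserved_group`.
#' @return Sum of the three loop column counts (empty loops count 0).
#' @export
loop_total_length <- function(group) {
  sum(pmax(0L, group$loop_cols[, 2] - group$loop_cols[, 1] + 1L))
}

sub_record_df <- function() {
  data.frame(group_id = character(), column = integer(), region = character(),
             species_code = character(), observed = character(),
             consensus = character(), type = character(),
             stringsAsFactors = FALSE)
}

# Unordered substitution pair label in coding-strand orientation.
sub_type <- function(a, b) {
  p <- sort(c(a, b))
  paste0(p[1], "<->", p[2])
}

#' Count loop substitutions of a conserved group
#'
#' In each loop column, every member-row base differing from the consensus
#' (computed over member rows) counts as one substitution. Gaps and `N` are
#' never substitutions; gap columns still count toward loop length.
#'
#' @param group A `conserved_group`.
#' @param block Its `alignment_block`.
#' @return Data.frame of substitution records (region `loop1..loop3`).
#' @export
count_loop_substitutions <- function(group, block) {
  idx <- match(group$members, block$species)
  m <- do.call(rbind, strsplit(block$rows[idx], ""))
  recs <- lapply(1:3, function(l) {
    cc <- group$loop_cols[l, ]
    if (cc[2] < cc[1]) return(NULL)
    r <- consensus_mismatches(m, cc[1]:cc[2], group$members)
    if (nrow(r)) r$region <- paste0("loop", l)
    r
  })
  out <- do.call(rbind, c(list(NULL), recs))
  if (is.null(out) || nrow(out) == 0) return(sub_record_df())
  out$group_id <- group$group_id
  out[, names(sub_record_df())]
}

# All (row, column) cells differing from the per-column consensus over the
# given rows; gaps and N are neither consensus nor substitution.
consensus_mismatches <- function(m, cols, row_names) {
  cons <- column_consensus_matrix(m, cols)
  sub <- m[, cols, drop = FALSE]
  ok <- sub == "A" | sub == "C" | sub == "G" | sub == "T"
  mism <- ok & sub != rep(cons, each = nrow(sub)) &
    rep(cons != "-", each = nrow(sub))
  hit <- which(mism, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(data.frame(group_id = character(), column = integer(),
                      region = character(), species_code = character(),
                      observed = character(), consensus = character(),
                      type = character(), stringsAsFactors = FALSE))
  }
  obs <- sub[hit]
  cns <- cons[hit[, 2]]
  data.frame(group_id = NA_character_, column = cols[hit[, 2]],
             region = NA_character_, species_code = row_names[hit[, 1]],
             observed = obs, consensus = cns,
             type = mapply(sub_type, obs, cns, USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

# Vectorised consensus over a character matrix restricted to `cols`.
column_consensus_matrix <- function(m, cols) {
  sub <- m[, cols, drop = FALSE]
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) colSums(sub == b), numeric(length(cols)))
  counts <- matrix(counts, nrow = length(cols))
  top <- max.col(counts, ties.method = "first")  # first = lexicographic tie
  cons <- c("A", "C", "G", "T")[top]
  cons[rowSums(counts) == 0] <- "-"
  cons
}

#' Count tract substitutions against non-member rows
#'
#' Member tract columns carry no substitutions by definition of a conserved
#' group; disruptive substitutions are read off the block rows of species
#' that are not group members. The tract consensus is `G` on the coding
#' strand and `C` for noncoding-strand motifs (coding-strand orientation).
#'
#' @param group A `conserved_group` (with attached non-member species).
#' @param block Its `alignment_block`.
#' @param motifs Optional motif table used to flag non-member rows whose own
#'   predicted motifs partially overlap the group columns.
#' @return Data.frame of substitution records (region `tract1..tract4`) with
#'   a `partial_overlap` flag column.
#' @export
count_tract_substitutions <- function(group, block, motifs = NULL) {
  cons_base <- if (group$strand == "coding") "G" else "C"
  out <- sub_record_df()
  out$partial_overlap <- logical()
  if (length(group$nonmembers) == 0) return(out)
  idx <- match(group$nonmembers, block$species)
  m <- do.call(rbind, strsplit(block$rows[idx], ""))
  overlap_flag <- vapply(seq_along(idx), function(i) {
    if (is.null(motifs)) return(FALSE)
    sp <- group$nonmembers[i]
    sub <- motifs[motifs$species_code == sp & motifs$strand == group$strand, ,
                  drop = FALSE]
    if (nrow(sub) == 0) return(FALSE)
    iv <- map_block_motifs(sub, block)
    any(iv$first_col <= group$tract_cols[4, 2] &
          iv$last_col >= group$tract_cols[1, 1])
  }, logical(1))
  for (t in 1:4) {
    cols <- group$tract_cols[t, 1]:group$tract_cols[t, 2]
    for (cl in cols) {
      obs <- m[, cl]
      bad <- which(obs %in% c("A", "C", "G", "T") & obs != cons_base)
      for (r in bad) {
        out <- rbind(out, data.frame(
          group_id = group$group_id, column = cl, region = paste0("tract", t),
          species_code = group$nonmembers[r], observed = obs[r],
          consensus = cons_base, type = sub_type(obs[r], cons_base),
          partial_overlap = overlap_flag[r], stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Substitution density
#' @param records Substitution record data.frame.
#' @param total_length Total region length in columns.
#' @return `nrow(records) / total_length`.
#' @export
density_of <- function(records, total_length) {
  stopifnot(total_length > 0)
  nrow(records) / total_length
}

#' Select a matched motif-free control sub-alignment for a group
#'
#' Searches for a column window with the same species rows as the group and
#' total length equal to the group's total loop length, that intersects no
#' predicted G4 motif of any species in any block, and contains no gap run
#' of 3 or more positions in any member row. Candidate windows are scanned
#' one column at a time: upstream-adjacent first, then downstream-adjacent,
#' then left-to-right in other blocks containing all member species, and
#' finally a split across two segments (upstream + downstream) in the home
#' block. Returns a `none` result with a reason when exhausted.
#'
#' @param group A `conserved_group`.
#' @param blocks Named list of all blocks.
#' @param motifs Motif table of all predicted motifs (both strands).
#' @return List with `found`, and when found: `block_name`, `segments`
#'   (list of column ranges), `source` (`same_block_upstream`,
#'   `same_block_downstream`, `same_block_split`, `other_block`); when not:
#'   `reason`.
#' @export
select_control <- function(group, blocks, motifs, cache = NULL) {
  Ltot <- loop_total_length(group)
  if (Ltot < 1) return(list(found = FALSE, reason = "empty_loops"))
  home <- blocks[[group$block_name]]
  gs <- group$tract_cols[1, 1]; ge <- group$tract_cols[4, 2]
  dat <- control_search_data(home, group$members, motifs, cache)

  up <- scan_side(dat, Ltot, edge = gs - 1L, dir = "up")
  if (!is.null(up)) {
    return(list(found = TRUE, block_name = home$name, segments = list(up),
                source = "same_block_upstream"))
  }
  down <- scan_side(dat, Ltot, edge = ge + 1L, dir = "down")
  if (!is.null(down)) {
    return(list(found = TRUE, block_name = home$name, segments = list(down),
                source = "same_block_downstream"))
  }
  for (b in blocks) {
    if (b$name == home$name) next
    if (!all(group$members %in% b$species)) next
    w <- scan_side(control_search_data(b, group$members, motifs, cache),
                   Ltot, edge = 1L, dir = "down")
    if (!is.null(w)) {
      return(list(found = TRUE, block_name = b$name, segments = list(w),
                  source = "other_block"))
    }
  }
  # split across upstream + downstream segments of the home block
  for (L1 in rev(seq_len(Ltot - 1L))) {
    s1 <- scan_side(dat, L1, edge = gs - 1L, dir = "up")
    if (is.null(s1)) next
    s2 <- scan_side(dat, Ltot - L1, edge = ge + 1L, dir = "down")
    if (!is.null(s2)) {
      return(list(found = TRUE, block_name = home$name,
                  segments = list(s1, s2), source = "same_block_split"))
    }
  }
  list(found = FALSE, reason = "no_eligible_window")
}

# Precompute, for one block and member set, cumulative sums of (i) columns
# covered by any predicted motif of any block species, and (ii) columns
# starting a gap run of >= 3 in some member row. `cache` is an optional
# environment keyed by block name + member set.
control_search_data <- function(block, members, motifs, cache = NULL) {
  key <- paste(block$name, paste(members, collapse = ","), sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  W <- block$width
  bad <- logical(W)
  iv <- map_block_motifs(motifs, block)
  for (r in seq_len(nrow(iv))) bad[iv$first_col[r]:iv$last_col[r]] <- TRUE
  gap3 <- logical(W)
  for (i in match(members, block$species)) {
    m <- gregexpr("-{3,}", block$rows[i])[[1]]
    if (m[1] != -1L) {
      len <- attr(m, "match.length")
      for (t in seq_along(m)) {
        gap3[m[t]:(m[t] + len[t] - 3L)] <- TRUE
      }
    }
  }
  dat <- list(W = W, forb_cum = c(0, cumsum(bad)), gap3_cum = c(0, cumsum(gap3)))
  if (!is.null(cache)) cache[[key]] <- dat
  dat
}

# First eligible window of length L: no forbidden column, no gap run of 3+
# inside the window. dir = "up": windows ending at edge, edge-1, ...;
# dir = "down": windows starting at edge, edge+1, ...
scan_side <- function(dat, L, edge, dir) {
  if (L < 1) return(NULL)
  W <- dat$W
  a_all <- seq_len(W - L + 1L)
  forb <- (dat$forb_cum[a_all + L] - dat$forb_cum[a_all]) > 0
  # a gap-3 run intersects [a, a+L-1] by >=3 columns iff one starts in
  # [a, a+L-3]
  gap <- if (L >= 3) {
    g_hi <- pmin(a_all + L - 2L, W + 1L)
    (dat$gap3_cum[g_hi] - dat$gap3_cum[a_all]) > 0
  } else FALSE
  ok <- !forb & !gap
  if (dir == "up") {
    cand <- which(ok & a_all + L - 1L <= edge)
    if (length(cand) == 0) return(NULL)
    a <- a_all[cand[length(cand)]]
  } else {
    cand <- which(ok & a_all >= edge)
    if (length(cand) == 0) return(NULL)
    a <- a_all[cand[1]]
  }
  c(a, a + L - 1L)
}

#' Loop-vs-control density pair for one group
#'
#' @param group A `conserved_group`.
#' @param blocks Named list of blocks.
#' @param motifs Motif table.
#' @return One-row data.frame (group_id, loop_density, control_density,
#'   loop_total_length, control_source) or `NULL` when no control exists.
#' @export
density_pair <- function(group, blocks, motifs, cache = NULL) {
  Ltot <- loop_total_length(group)
  if (Ltot < 1) return(NULL)
  loops <- count_loop_substitutions(group, blocks[[group$block_name]])
  ctrl <- select_control(group, blocks, motifs, cache)
  if (!ctrl$found) return(NULL)
  cb <- blocks[[ctrl$block_name]]
  idx <- match(group$members, cb$species)
  m <- do.call(rbind, strsplit(cb$rows[idx], ""))
  nsub <- 0L
  for (seg in ctrl$segments) {
    nsub <- nsub + nrow(consensus_mismatches(m, seg[1]:seg[2], group$members))
  }
  data.frame(group_id = group$group_id,
             loop_density = density_of(loops, Ltot),
             control_density = nsub / Ltot,
             loop_total_length = Ltot,
             control_source = ctrl$source, stringsAsFactors = FALSE)
}

#' One-sided paired Wilcoxon signed-rank test (loop > control)
#'
#' Zero differences are dropped. The exact null distribution is used when
#' the number of non-zero pairs is at most 25 and the absolute differences
#' are free of rank ties; otherwise the normal approximation with tie and
#' continuity correction is used. Returns `NA` (with method `"none"`) when
#' all differences are zero.
#'
#' @param loop,control Numeric vectors of paired densities.
#' @return List with `p`, `method` (`"exact"`, `"normal"`, `"none"`) and
#'   `n` (non-zero pairs used).
#' @export
wilcoxon_paired_greater <- function(loop, control) {
  stopifnot(length(loop) == length(control), length(loop) >= 1)
  d <- loop - control
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(p = NA_real_, method = "none", n = 0L))
  ties <- anyDuplicated(abs(d)) > 0
  exact <- n <= 25 && !ties
  ht <- suppressWarnings(
    wilcox.test(d, alternative = "greater", mu = 0, exact = exact,
                correct = TRUE))
  list(p = unname(ht$p.value), method = if (exact) "exact" else "normal",
       n = n)
}

#' Holm-Bonferroni step-down adjustment
#'
#' The i-th smallest p-value is multiplied by `m - i + 1`; a running maximum
#' enforces monotonicity and values are capped at 1. Returned in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @examples
#' holm_bonferroni(c(0.003947, 0.02381, 0.2648, 0.7797, 0.2092))
#' @export
holm_bonferroni <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "holm")
}

#' Run the loop-vs-control test for one order
#'
#' Builds density pairs for every group (groups without an eligible control
#' are excluded and reported), computes the one-sided paired Wilcoxon
#' p-value and the number of pairs whose loop density exceeds the control.
#' Family-wise Holm adjustment across orders is applied by
#' [adjust_family()].
#'
#' @param groups List of `conserved_group`s of the order.
#' @param blocks Named list of blocks.
#' @param motifs Motif table.
#' @param order_code Order label.
#' @return List: order_code, pairs (data.frame), n_pairs, n_excluded,
#'   p_raw, method, n_loop_exceeds_control.
#' @export
run_order_test <- function(groups, blocks, motifs, order_code = "Unk") {
  cache <- new.env(parent = emptyenv())
  pairs <- list(); excluded <- character()
  for (g in groups) {
    dp <- density_pair(g, blocks, motifs, cache)
    if (is.null(dp)) excluded <- c(excluded, g$group_id)
    else pairs[[length(pairs) + 1]] <- dp
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(list(order_code = order_code, pairs = NULL, n_pairs = 0L,
                n_excluded = length(excluded), p_raw = NA_real_,
                method = "none", n_loop_exceeds_control = 0L))
  }
  wt <- wilcoxon_paired_greater(pairs$loop_density, pairs$control_density)
  list(order_code = order_code, pairs = pairs, n_pairs = nrow(pairs),
       n_excluded = length(excluded), p_raw = wt$p, method = wt$method,
       n_loop_exceeds_control =
         sum(pairs$loop_density > pairs$control_density))
}

#' Holm adjustment across the orders of one run
#'
#' @param results List of [run_order_test()] results (the family).
#' @return Data.frame in Table-3 shape: order_code, n_pairs, p_raw, p_holm,
#'   n_loop_exceeds_control. Orders with no usable pairs carry `NA` and do
#'   not enter the family.
#' @export
adjust_family <- function(results) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(order_code = r$order_code, n_pairs = r$n_pairs,
               p_raw = r$p_raw,
               n_loop_exceeds_control = r$n_loop_exceeds_control,
               stringsAsFactors = FALSE)
  }))
  df$p_holm <- NA_real_
  usable <- !is.na(df$p_raw)
  df$p_holm[usable] <- holm_bonferroni(df$p_raw[usable])
  df[, c("order_code", "n_pairs", "p_raw", "p_holm",
         "n_loop_exceeds_control")]
}
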