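#' Alignment blocks
#'
#' An alignment block is a local multiple alignment of promoter fragments
#' from two or more species of one order. A block is "reliable" when at least
#' 80% of its columns are identical and it is at least 100 columns wide.
#' A column is identical only when every row carries the same non-gap,
#' non-`N` symbol. Block names follow the `h{n_fragments}x{width}` rule with
#' `-1`, `-2` suffixes on collisions.
#'
#' @param species Character vector of species codes (>= 2, distinct).
#' @param start,end 1-based inclusive coding-strand promoter coordinates of
#'   each fragment.
#' @param rows Gapped rows over `{A,C,G,T,N,-}`, all the same width; the
#'   ungapped row must equal the promoter subsequence `[start..end]`.
#' @param name Optional block name; computed from the naming rule if `NULL`.
#' @return An object of class `alignment_block` with fields `name`,
#'   `species`, `start`, `end`, `rows`, `width`, `identity`.
#' @export
alignment_block <- function(species, start, end, rows, name = NULL) {
  stopifnot(length(species) == length(rows), length(start) == length(rows),
            length(end) == length(rows))
  if (length(rows) < 2) stop("a block needs at least 2 fragments", call. = FALSE)
  if (anyDuplicated(species)) {
    stop("block fragments must come from distinct species", call. = FALSE)
  }
  w <- unique(nchar(rows))
  if (length(w) != 1) stop("all block rows must have equal width", call. = FALSE)
  ungapped <- gsub("-", "", rows, fixed = TRUE)
  if (any(nchar(ungapped) != end - start + 1)) {
    stop("fragment coordinates do not match ungapped row lengths", call. = FALSE)
  }
  b <- structure(list(name = name %||% "", species = as.character(species),
                      start = as.integer(start), end = as.integer(end),
                      rows = toupper(rows), width = as.integer(w),
                      identity = NA_real_),
                 class = "alignment_block")
  b$identity <- column_identity(b)
  if (is.null(name)) b$name <- sprintf("h%dx%d", length(rows), w)
  b
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("alignment_block %s: %d fragments x %d columns, identity %.3f\n",
              x$name, length(x$rows), x$width, x$identity))
  invisible(x)
}

# Character matrix view of the rows.
block_matrix <- function(block) {
  do.call(rbind, strsplit(block$rows, ""))
}

#' Fraction of identical columns of a block
#'
#' A column counts as identical only when all rows carry the same symbol and
#' that symbol is one of `A`, `C`, `G`, `T` (any gap or `N` disqualifies the
#' column).
#'
#' @param block An `alignment_block`.
#' @return Fraction in `[0, 1]`.
#' @export
column_identity <- function(block) {
  if (block$width == 0) stop("zero-width block", call. = FALSE)
  mean(identical_columns(block_matrix(block)))
}

identical_columns <- function(m) {
  first <- m[1, ]
  same <- colSums(m != rep(first, each = nrow(m))) == 0
  same & first %in% c("A", "C", "G", "T")
}

#' Validate a block against the reliability criteria
#'
#' @param block An `alignment_block`.
#' @param min_identity Minimum fraction of identical columns (default 0.8).
#' @param min_width Minimum number of columns (default 100).
#' @return `TRUE` iff the block passes both criteria. Maximality is a
#'   property of the construction in [build_blocks()], not checked here.
#' @export
validate_block <- function(block, min_identity = 0.8, min_width = 100L) {
  block$identity >= min_identity && block$width >= min_width
}

#' Write blocks as aligned FASTA plus an index
#'
#' One file per block named `<block name>.fa`, records
#' `>SPECIESCODE/start-end` with the gapped row; `index.tsv` lists name,
#' n_fragments, width, identity.
#'
#' @param blocks List of `alignment_block` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_blocks <- function(blocks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in blocks) {
    lines <- as.vector(rbind(sprintf(">%s/%d-%d", b$species, b$start, b$end),
                             b$rows))
    writeLines(lines, file.path(dir, paste0(b$name, ".fa")))
  }
  idx <- data.frame(
    name = vapply(blocks, `[[`, "", "name"),
    n_fragments = vapply(blocks, function(b) length(b$rows), 0L),
    width = vapply(blocks, `[[`, 0L, "width"),
    identity = vapply(blocks, `[[`, 0, "identity"))
  write_tsv(idx, file.path(dir, "index.tsv"))
  invisible(dir)
}

#' Read blocks from a directory of aligned FASTA files
#'
#' @param dir Directory produced by [write_blocks()] (or NPG-explorer style
#'   exports in the same dialect).
#' @param set Optional `promoter_set`; when given, every fragment's ungapped
#'   row is checked against the promoter subsequence and mismatches are an
#'   error.
#' @return List of `alignment_block` objects, named by block name.
#' @export
read_blocks <- function(dir, set = NULL) {
  files <- sort(list.files(dir, pattern = "\\.fa$", full.names = TRUE))
  blocks <- lapply(files, function(f) {
    lines <- readLines(f)
    hdr <- grep("^>", lines)
    if (length(hdr) < 2) stop("block file with <2 fragments: ", f, call. = FALSE)
    m <- regmatches(lines[hdr],
                    regexec("^>([A-Za-z0-9]+)/([0-9]+)-([0-9]+)$", lines[hdr]))
    if (any(lengths(m) != 4)) {
      stop("malformed block header in ", f, call. = FALSE)
    }
    species <- vapply(m, `[[`, "", 2)
    start <- as.integer(vapply(m, `[[`, "", 3))
    end <- as.integer(vapply(m, `[[`, "", 4))
    rows <- vapply(seq_along(hdr), function(i) {
      to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
      paste(lines[(hdr[i] + 1):to], collapse = "")
    }, "")
    b <- alignment_block(species, start, end, rows,
                         name = sub("\\.fa$", "", basename(f)))
    if (!is.null(set)) {
      for (i in seq_along(species)) {
        s <- set$promoters$sequence[match(species[i], set$promoters$species_code)]
        if (is.na(s) ||
            gsub("-", "", rows[i], fixed = TRUE) != substring(s, start[i], end[i])) {
          stop("fragment ", species[i], "/", start[i], "-", end[i],
               " does not match the promoter sequence", call. = FALSE)
        }
      }
    }
    b
  })
  names(blocks) <- vapply(blocks, `[[`, "", "name")
  blocks
}

#' Build reliable alignment blocks over a promoter set
#'
#' Stand-in for pangenome-style block construction: shared k-mers between
#' promoter pairs are chained colinearly into anchor chains; chains sharing
#' promoter intervals are grouped into proto-blocks; proto-block fragments
#' are aligned progressively (center-star over pairwise global alignments
#' with match +1 / mismatch -1 / gap -2, with a gap-free fast path when an
#' ungapped stacking already reaches the identity threshold); maximal column
#' windows satisfying the identity and width criteria are extracted and
#' greedily extended column-by-column until no single-column extension keeps
#' the block passing. Blocks may overlap. Deterministic for a fixed input.
#'
#' @param set A `promoter_set` with >= 2 promoters.
#' @param k Anchor k-mer size (default 12).
#' @param min_identity,min_width Reliability criteria (defaults 0.8 / 100).
#' @param min_anchors Minimum chained anchors to accept a pairwise chain.
#' @param max_shift Maximum anchor diagonal deviation within a chain.
#' @param allow_subthreshold Keep blocks failing the criteria after cleanup
#'   (flagged by their `identity`/`width`) instead of dropping them.
#' @return List of `alignment_block` objects (possibly empty), named.
#' @export
build_blocks <- function(set, k = 12L, min_identity = 0.8, min_width = 100L,
                         min_anchors = 3L, max_shift = 50L,
                         allow_subthreshold = FALSE) {
  stopifnot(inherits(set, "promoter_set"))
  n <- nrow(set$promoters)
  if (n < 2) return(list())
  seqs <- set$promoters$sequence
  codes <- set$promoters$species_code

  km <- lapply(seqs, unique_kmers, k = k)
  chains <- pair_chains(km, k, min_anchors, max_shift)
  protos <- group_chains(chains, n)

  blocks <- list()
  for (pb in protos) {
    frag_idx <- pb$promoter
    # widen every fragment to the component span so equally-long homologous
    # fragments stack gap-free; ragged ends are trimmed by the window step
    span_s <- min(pb$start); span_e <- max(pb$end)
    pb$start <- pmax(1L, span_s)
    pb$end <- pmin(nchar(seqs[frag_idx]), span_e)
    frags <- substring(seqs[frag_idx], pb$start, pb$end)
    msa <- center_star(frags, min_identity)
    found <- qualifying_windows(identical_columns(do.call(rbind, strsplit(msa, ""))),
                                min_identity, min_width)
    for (w in found) {
      b <- window_block(msa, w[1], w[2], codes[frag_idx], pb$start)
      if (is.null(b)) next
      if (validate_block(b, min_identity, min_width) || allow_subthreshold) {
        blocks[[length(blocks) + 1]] <- b
      }
    }
  }
  name_blocks(blocks)
}

# Positions of k-mers occurring exactly once in the sequence.
unique_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(data.frame(kmer = character(), pos = integer()))
  pos <- seq_len(L - k + 1L)
  kmer <- substring(seq, pos, pos + k - 1L)
  keep <- !(duplicated(kmer) | duplicated(kmer, fromLast = TRUE)) &
    !grepl("N", kmer, fixed = TRUE)
  data.frame(kmer = kmer[keep], pos = pos[keep], stringsAsFactors = FALSE)
}

# Colinear anchor chains for every promoter pair. Returns a data.frame of
# chain intervals: promoter indices i, j and their chained intervals.
pair_chains <- function(km, k, min_anchors, max_shift) {
  n <- length(km)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mi <- match(km[[i]]$kmer, km[[j]]$kmer)
      hit <- which(!is.na(mi))
      if (length(hit) < min_anchors) next
      pi <- km[[i]]$pos[hit]
      pj <- km[[j]]$pos[mi[hit]]
      o <- order(pi)
      pi <- pi[o]; pj <- pj[o]
      diag <- pj - pi
      keep <- abs(diag - median(diag)) <= max_shift
      pi <- pi[keep]; pj <- pj[keep]
      if (length(pi) < min_anchors) next
      # enforce strictly increasing subject positions
      sel <- logical(length(pi)); last <- -Inf
      for (t in seq_along(pi)) {
        if (pj[t] > last) { sel[t] <- TRUE; last <- pj[t] }
      }
      pi <- pi[sel]; pj <- pj[sel]
      if (length(pi) < min_anchors) next
      out[[length(out) + 1]] <- data.frame(
        i = i, j = j,
        i_start = min(pi), i_end = max(pi) + k - 1L,
        j_start = min(pj), j_end = max(pj) + k - 1L)
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# Group pairwise chains into proto-blocks via union-find over per-promoter
# merged intervals. Returns a list of data.frames (promoter, start, end).
group_chains <- function(chains, n) {
  if (is.null(chains)) return(list())
  # atoms: per promoter, merged overlapping chain intervals
  iv <- rbind(data.frame(p = chains$i, s = chains$i_start, e = chains$i_end),
              data.frame(p = chains$j, s = chains$j_start, e = chains$j_end))
  atoms <- list()
  for (p in sort(unique(iv$p))) {
    sub <- iv[iv$p == p, , drop = FALSE]
    sub <- sub[order(sub$s, sub$e), , drop = FALSE]
    s <- sub$s[1]; e <- sub$e[1]
    for (r in seq_len(nrow(sub))[-1]) {
      if (sub$s[r] <= e + 30L) e <- max(e, sub$e[r])
      else { atoms[[length(atoms) + 1]] <- c(p, s, e); s <- sub$s[r]; e <- sub$e[r] }
    }
    atoms[[length(atoms) + 1]] <- c(p, s, e)
  }
  am <- do.call(rbind, atoms)
  find_atom <- function(p, s, e) {
    which(am[, 1] == p & am[, 2] <= s & am[, 3] >= e)[1]
  }
  parent <- seq_len(nrow(am))
  findp <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in seq_len(nrow(chains))) {
    a <- find_atom(chains$i[r], chains$i_start[r], chains$i_end[r])
    b <- find_atom(chains$j[r], chains$j_start[r], chains$j_end[r])
    ra <- findp(a); rb <- findp(b)
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(nrow(am)), findp, 0L)
  protos <- lapply(unique(roots), function(rt) {
    sub <- am[roots == rt, , drop = FALSE]
    # one interval per promoter: overall span of its atoms in the component
    ag <- do.call(rbind, lapply(sort(unique(sub[, 1])), function(p) {
      c(p, min(sub[sub[, 1] == p, 2]), max(sub[sub[, 1] == p, 3]))
    }))
    data.frame(promoter = ag[, 1], start = ag[, 2], end = ag[, 3])
  })
  protos[vapply(protos, nrow, 0L) >= 2]
}

# Center-star progressive multiple alignment. The center is the longest
# fragment (ties: first). Each other fragment is aligned globally to the
# center; gaps are merged with the "once a gap, always a gap" rule. When a
# fragment has the center's length and its ungapped identity to the center
# already reaches `fast_identity`, the gap-free alignment is used directly.
center_star <- function(frags, fast_identity = 0.8) {
  nf <- length(frags)
  if (nf == 1) return(frags)
  ci <- which.max(nchar(frags))
  C <- frags[ci]
  nC <- nchar(C)
  Cchars <- strsplit(C, "")[[1]]
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  parts <- vector("list", nf)
  for (f in seq_len(nf)) {
    if (f == ci) {
      parts[[f]] <- list(ins = integer(nC + 1), ins_chars = rep(list(character()), nC + 1),
                         aligned = Cchars)
      next
    }
    Fj <- frags[f]
    if (nchar(Fj) == nC &&
        hamming_identity(C, Fj) >= fast_identity) {
      parts[[f]] <- list(ins = integer(nC + 1), ins_chars = rep(list(character()), nC + 1),
                         aligned = strsplit(Fj, "")[[1]])
      next
    }
    aln <- Biostrings::pairwiseAlignment(C, Fj, type = "global",
                                         substitutionMatrix = submat,
                                         gapOpening = 0, gapExtension = 2)
    cp <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    cs <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    gap <- cp == "-"
    posC <- cumsum(!gap)
    ins <- tabulate(posC[gap] + 1L, nbins = nC + 1L)
    ins_chars <- rep(list(character()), nC + 1)
    if (any(gap)) {
      sp <- split(cs[gap], posC[gap])
      ins_chars[as.integer(names(sp)) + 1L] <- sp
    }
    parts[[f]] <- list(ins = ins, ins_chars = ins_chars, aligned = cs[!gap])
  }
  master_ins <- Reduce(pmax, lapply(parts, `[[`, "ins"))
  vapply(parts, function(pt) {
    segs <- character(2 * nC + 1)
    for (p in 0:nC) {
      ic <- pt$ins_chars[[p + 1]]
      pad <- master_ins[p + 1] - length(ic)
      segs[2 * p + 1] <- paste0(paste(ic, collapse = ""),
                                strrep("-", pad))
      if (p < nC) segs[2 * p + 2] <- pt$aligned[p + 1]
    }
    paste(segs, collapse = "")
  }, "")
}

hamming_identity <- function(a, b) {
  mean(utf8ToInt(a) == utf8ToInt(b))
}

# All maximal qualifying windows over a logical identity vector: recursively
# take the widest window with mean >= min_identity and length >= min_width,
# recurse left and right, then greedily extend each seed over the full
# vector. Returns a list of c(start, end), deduplicated, sorted.
qualifying_windows <- function(flags, min_identity, min_width) {
  W <- length(flags)
  if (W < min_width) return(list())
  cs <- c(0, cumsum(flags))
  wsum <- function(a, b) cs[b + 1] - cs[a]
  best_in <- function(lo, hi) {
    span <- hi - lo + 1
    if (span < min_width) return(NULL)
    for (L in span:min_width) {
      a <- lo:(hi - L + 1)
      s <- cs[a + L] - cs[a]
      ok <- which(s >= min_identity * L - 1e-9)
      if (length(ok)) return(c(a[ok[1]], a[ok[1]] + L - 1))
    }
    NULL
  }
  seeds <- list()
  stack <- list(c(1, W))
  while (length(stack)) {
    r <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    w <- best_in(r[1], r[2])
    if (is.null(w)) next
    seeds[[length(seeds) + 1]] <- w
    stack <- c(stack, list(c(r[1], w[1] - 1)), list(c(w[2] + 1, r[2])))
  }
  out <- lapply(seeds, function(w) {
    a <- w[1]; b <- w[2]
    repeat {
      if (b < W && wsum(a, b + 1) >= min_identity * (b + 2 - a) - 1e-9) b <- b + 1
      else if (a > 1 && wsum(a - 1, b) >= min_identity * (b + 2 - a) - 1e-9) a <- a - 1
      else break
    }
    c(a, b)
  })
  out <- unique(out)
  out[order(vapply(out, `[`, 0, 1))]
}

# Cut a column window out of an MSA and assemble an alignment_block.
# frag_start gives each fragment's promoter start coordinate.
window_block <- function(msa, a, b, codes, frag_start) {
  rows <- substring(msa, a, b)
  chars <- strsplit(msa, "")
  nongap_before <- vapply(seq_along(msa), function(i) {
    sum(chars[[i]][seq_len(a - 1)] != "-")
  }, 0L)
  nongap_in <- vapply(seq_along(msa), function(i) {
    sum(chars[[i]][a:b] != "-")
  }, 0L)
  keep <- nongap_in > 0
  if (sum(keep) < 2) return(NULL)
  rows <- rows[keep]
  # drop columns that became all-gap
  rm <- do.call(rbind, strsplit(rows, ""))
  allgap <- colSums(rm != "-") == 0
  if (any(allgap)) {
    rows <- apply(rm[, !allgap, drop = FALSE], 1, paste, collapse = "")
  }
  start <- frag_start[keep] + nongap_before[keep]
  end <- start + nongap_in[keep] - 1L
  alignment_block(codes[keep], start, end, rows)
}

# Deterministic naming with collision suffixes.
name_blocks <- function(blocks) {
  if (length(blocks) == 0) return(list())
  ord <- order(-vapply(blocks, function(b) length(b$rows), 0L),
               -vapply(blocks, `[[`, 0L, "width"),
               vapply(blocks, function(b) paste(b$species, collapse = ","), ""),
               vapply(blocks, function(b) min(b$start), 0L))
  blocks <- blocks[ord]
  base <- vapply(blocks, function(b) sprintf("h%dx%d", length(b$rows), b$width), "")
  nm <- base
  for (u in unique(base[duplicated(base)])) {
    idx <- which(base == u)
    nm[idx] <- paste0(u, "-", seq_along(idx))
  }
  for (i in seq_along(blocks)) blocks[[i]]$name <- nm[i]
  names(blocks) <- nm
  blocks
}
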