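test_that("motif-to-column mapping does gap-aware offset arithmetic", {
  # gapless fragment at 101-400, motif at 151-180 -> columns 51-80
  b <- alignment_block(c("TstSPaaa", "TstSPbbb"), c(101L, 101L), c(400L, 400L),
                       rep(random_dna(300, seed = 1), 2))
  m <- list(species_code = "TstSPaaa", strand = "coding", start = 151L, end = 180L)
  ci <- map_motif_to_columns(m, b)
  expect_equal(c(ci$first_col, ci$last_col), c(51L, 80L))
  expect_false(ci$partial)
  # a gap column inserted at column 10 shifts everything past it by one
  row <- b$rows[1]
  gapped <- paste0(substr(row, 1, 9), "-", substr(row, 10, 300))
  b2 <- alignment_block(c("TstSPaaa", "TstSPbbb"), c(101L, 101L), c(400L, 401L),
                        c(gapped, paste0(substr(row, 1, 9), "A",
                                         substr(row, 10, 300))))
  ci2 <- map_motif_to_columns(m, b2)
  expect_equal(c(ci2$first_col, ci2$last_col), c(52L, 81L))
  expect_error(map_motif_to_columns(
    list(species_code = "TstSPzzz", strand = "coding", start = 1, end = 5), b),
    "species mismatch")
})

test_that("column mapping round-trips through random gap patterns", {
  for (i in 1:25) {
    set.seed(600 + i)
    n <- 80
    chars <- sample(c("A", "C", "G", "T", "-"), n, replace = TRUE,
                    prob = c(.2, .2, .2, .2, .2))
    if (all(chars == "-")) chars[1] <- "A"
    row <- paste(chars, collapse = "")
    ungapped <- sum(chars != "-")
    start <- sample(1:50, 1)
    b <- alignment_block(
      c("TstSPaaa", "TstSPbbb"), c(start, 1L), c(start + ungapped - 1L, n),
      c(row, paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")))
    cols <- which(chars != "-")
    s <- sample(seq_len(ungapped), 1)
    e <- s + sample.int(ungapped - s + 1L, 1) - 1L
    m <- list(species_code = "TstSPaaa", strand = "coding",
              start = start + s - 1L, end = start + e - 1L)
    ci <- map_motif_to_columns(m, b)
    # columns back to promoter coordinates: count non-gaps up to the column
    back <- function(col) start + sum(chars[1:col] != "-") - 1L
    expect_equal(back(ci$first_col), m$start)
    expect_equal(back(ci$last_col), m$end)
  }
})

make_intervals <- function(first, last, species, strand = "coding") {
  data.frame(block_name = "h2x100", species_code = species, strand = strand,
             first_col = as.integer(first), last_col = as.integer(last),
             partial = FALSE, motif_row = seq_along(first))
}

test_that("simple interval pairs cluster as documented", {
  iv <- make_intervals(c(10, 12), c(40, 38), c("TstSPaaa", "TstSPbbb"))
  cl <- find_clusters(iv, 20)
  expect_length(cl, 1L)
  expect_equal(c(cl[[1]]$common_first, cl[[1]]$common_last), c(12L, 38L))
  expect_length(find_clusters(make_intervals(c(10, 200), c(40, 230),
                                             c("TstSPaaa", "TstSPbbb")), 20), 0L)
  # same-species intervals never share a cluster
  iv3 <- make_intervals(c(10, 11, 12), c(40, 41, 38),
                        c("TstSPaaa", "TstSPaaa", "TstSPbbb"))
  cl3 <- find_clusters(iv3, 20)
  expect_true(all(vapply(cl3, function(x) {
    anyDuplicated(x$members$species_code) == 0L
  }, logical(1))))
  expect_error(find_clusters(make_intervals(c(1, 2), c(30, 30),
                                            c("TstSPaaa", "TstSPbbb"),
                                            strand = c("coding", "noncoding")), 5),
               "single strand")
})

# Independent re-implementation of the stated clustering rule: enumerate
# every candidate window naively, build its member set with explicit loops,
# emit greedily by the stated ordering.
oracle_clusters <- function(iv, m) {
  avail <- seq_len(nrow(iv))
  res <- list()
  repeat {
    cands <- list()
    for (a in sort(unique(iv$first_col[avail]))) {
      for (b in sort(unique(iv$last_col[avail]))) {
        if (b - a + 1 < m) next
        hit <- c()
        for (i in avail) {
          if (iv$first_col[i] <= a && iv$last_col[i] >= b) hit <- c(hit, i)
        }
        if (length(hit) < 2) next
        hit <- hit[order(iv$first_col[hit], iv$last_col[hit], hit)]
        keep <- c()
        for (i in hit) {
          if (!(iv$species_code[i] %in% iv$species_code[keep])) keep <- c(keep, i)
        }
        if (length(keep) < 2) next
        cands[[length(cands) + 1]] <- keep
      }
    }
    if (length(cands) == 0) break
    key <- function(k) {
      cf <- max(iv$first_col[k]); cl <- min(iv$last_col[k])
      list(len = cl - cf + 1, cf = cf, n = length(k),
           sp = paste(sort(iv$species_code[k]), collapse = ","))
    }
    best <- cands[[1]]
    for (k in cands[-1]) {
      a <- key(k); b <- key(best)
      better <- if (a$len != b$len) a$len > b$len else
        if (a$cf != b$cf) a$cf < b$cf else
          if (a$n != b$n) a$n > b$n else a$sp < b$sp
      if (better) best <- k
    }
    res[[length(res) + 1]] <- sort(best)
    avail <- setdiff(avail, best)
  }
  res
}

test_that("clustering equals the naive window-enumeration oracle", {
  for (i in 1:30) {
    set.seed(700 + i)
    n <- sample(6:14, 1)
    first <- sample(1:120, n, replace = TRUE)
    len <- sample(12:40, n, replace = TRUE)
    iv <- make_intervals(first, first + len - 1,
                         sprintf("TstSP%03d", sample(1:6, n, replace = TRUE)))
    got <- find_clusters(iv, 12)
    got_sets <- lapply(got, function(cl) sort(cl$members$motif_row))
    want <- oracle_clusters(iv, 12)
    expect_equal(got_sets, want, info = paste("seed", 700 + i))
  }
})

test_that("clustering is permutation-invariant and monotone in the threshold", {
  set.seed(42)
  n <- 12
  first <- sample(1:100, n, replace = TRUE)
  iv <- make_intervals(first, first + sample(15:40, n, TRUE) - 1,
                       sprintf("TstSP%03d", sample(1:5, n, TRUE)))
  base <- find_clusters(iv, 12)
  perm <- sample(n)
  iv2 <- iv[perm, ]
  iv2$motif_row <- iv$motif_row[perm]
  shuffled <- find_clusters(iv2, 12)
  canon <- function(cls) {
    sets <- lapply(cls, function(cl) sort(cl$members$motif_row))
    sets[order(vapply(sets, paste, "", collapse = ","))]
  }
  expect_equal(canon(shuffled), canon(base))
  sizes <- vapply(c(5, 12, 20, 30), function(m) {
    sum(lengths(lapply(find_clusters(iv, m), function(cl) cl$members$motif_row)))
  }, 0)
  expect_true(all(diff(sizes) <= 0))
  # every cluster's members pairwise intersect by at least the threshold
  for (cl in base) {
    f <- cl$members$first_col; l <- cl$members$last_col
    for (i in seq_along(f)) for (j in seq_along(f)) {
      expect_gte(min(l[i], l[j]) - max(f[i], f[j]) + 1, 12)
    }
  }
})
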