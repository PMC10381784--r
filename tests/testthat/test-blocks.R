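test_that("column identity counts only all-identical base columns", {
  expect_equal(column_identity(make_test_block(c("ACGT", "ACGT"))), 1.0)
  expect_equal(column_identity(make_test_block(c("ACGT", "A-GT"))), 0.75)
  expect_equal(column_identity(make_test_block(c("ACGT", "ACGN"))), 0.75)
  for (i in 1:20) {
    set.seed(400 + i)
    w <- sample(20:60, 1)
    rows <- vapply(1:3, function(j) {
      paste(sample(c("A", "C", "G", "T", "-", "N"), w, replace = TRUE,
                   prob = c(.4, .3, .1, .1, .06, .04)), collapse = "")
    }, "")
    b <- make_test_block(rows)
    expect_equal(column_identity(b), oracle_identity(b$rows))
  }
})

test_that("reliability validation uses sharp width and identity boundaries", {
  wide <- make_test_block(c(strrep("ACGT", 25), strrep("ACGT", 25)))
  expect_true(validate_block(wide))           # width 100, identity 1
  narrow <- make_test_block(rep(paste0(strrep("ACGT", 24), "ACG"), 2))
  expect_false(validate_block(narrow))        # width 99
  r1 <- paste0(strrep("A", 150))
  r2 <- paste0(strrep("A", 118), strrep("C", 32))
  expect_false(validate_block(make_test_block(c(r1, r2))))  # identity < 0.8
  r3 <- paste0(strrep("A", 120), strrep("C", 30))
  expect_true(validate_block(make_test_block(c(r1, r3))))   # identity 0.8
})

test_that("identical promoters give one full-width perfect block", {
  seqs <- rep(random_dna(300, seed = 21), 5)
  s <- promoter_set(sprintf("TstSP%03d", 1:5), seqs)
  b <- build_blocks(s)
  expect_length(b, 1L)
  expect_equal(b[[1]]$name, "h5x300")
  expect_equal(b[[1]]$width, 300L)
  expect_equal(b[[1]]$identity, 1.0)
  expect_equal(sort(b[[1]]$species), sort(s$promoters$species_code))
})

test_that("unrelated random promoters yield no reliable block", {
  s <- promoter_set(sprintf("TstSP%03d", 1:5),
                    vapply(1:5, function(i) random_dna(300, seed = 30 + i), ""))
  expect_length(build_blocks(s), 0L)
  # oracle: no pairwise ungapped 100-window reaches 80% identity
  for (i in 1:4) for (j in (i + 1):5) {
    a <- utf8ToInt(s$promoters$sequence[i])
    b <- utf8ToInt(s$promoters$sequence[j])
    for (off in -200:200) {
      ai <- max(1, 1 - off):min(300, 300 - off)
      if (length(ai) < 100) next
      match <- a[ai] == b[ai + off]
      cs <- c(0, cumsum(match))
      w <- 100
      sums <- cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
      expect_lt(max(sums) / w, 0.8)
    }
  }
})

test_that("blocks pass validation, satisfy fragment consistency, and are deterministic", {
  g <- generate_order(sim_config(n_species = 6, promoter_length = 600,
                                 n_motifs = 3, background_rate = 0.02,
                                 indel_rate = 5e-4, seed = 99))
  b1 <- build_blocks(g$set)
  b2 <- build_blocks(g$set)
  expect_gt(length(b1), 0)
  expect_identical(b1, b2)
  for (b in b1) {
    expect_true(validate_block(b))
    for (i in seq_along(b$species)) {
      prom <- g$set$promoters$sequence[match(b$species[i],
                                             g$set$promoters$species_code)]
      expect_equal(gsub("-", "", b$rows[i], fixed = TRUE),
                   substring(prom, b$start[i], b$end[i]))
    }
  }
})

test_that("planted conserved regions are covered by blocks at 5% divergence", {
  covered <- 0L; total <- 0L
  for (s in 1:5) {
    g <- generate_order(sim_config(n_species = 3, promoter_length = 1000,
                                   n_motifs = 5, background_rate = 0.05,
                                   seed = 500 + s))
    blocks <- build_blocks(g$set)
    pl <- g$truth$planted
    for (mi in seq_len(nrow(pl))) {
      total <- total + 1L
      covered <- covered + any(vapply(blocks, function(b) {
        i <- match("SimSP001", b$species)
        !is.na(i) && b$start[i] <= pl$start[mi] && b$end[i] >= pl$end[mi]
      }, logical(1)))
    }
  }
  expect_gte(covered / total, 0.9)
})

test_that("block files round-trip byte-identically and validate coordinates", {
  g <- generate_order(sim_config(n_species = 4, promoter_length = 400,
                                 n_motifs = 2, background_rate = 0.01,
                                 seed = 7))
  blocks <- build_blocks(g$set)
  d <- withr::local_tempdir()
  write_blocks(blocks, d)
  again <- read_blocks(d, set = g$set)
  expect_equal(again, blocks)
  d2 <- withr::local_tempdir()
  write_blocks(again, d2)
  f <- list.files(d, pattern = "\\.fa$")
  expect_equal(readLines(file.path(d2, f[1])), readLines(file.path(d, f[1])))
  # corrupt a header: coordinates no longer match the ungapped row
  lines <- readLines(file.path(d, f[1]))
  lines[1] <- sub("/[0-9]+-", "/2-", lines[1])
  writeLines(lines, file.path(d, f[1]))
  expect_error(read_blocks(d, set = g$set), "match")
})

test_that("block naming follows the h{n}x{width} rule", {
  b <- alignment_block(sprintf("TstSP%03d", 1:11), rep(1L, 11), rep(275L, 11),
                       rep(random_dna(275, seed = 3), 11))
  expect_equal(b$name, "h11x275")
})
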