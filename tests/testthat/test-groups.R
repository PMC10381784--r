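# A hand-built block with a noncoding-strand conserved motif (C-tracts on
# the coding rows), one species disrupted, loops with known substitutions.
fixture_block <- function() {
  #            1111111111222222222233333333334444444444
  #   1234567890123456789012345678901234567890123456789
  r1 <- "ATTACCCTACCCATTCCCGTACCCATTTTTTTTTTATTTTTTTTTTTGG"
  r2 <- "ATTACCCTACCCATTCCCGTACCCATTTTTTTTTTATTTTTTTTTTTGG"
  r3 <- "ATTACCCTACCCATTCCCTTACCCATTTTTTTTTTATTTTTTTTTTTGG"
  r4 <- "ATTACCATACCCATTCCCGTACCCATTTTTTTTTTATTTTTTTTTTTGG"  # tract1 broken
  alignment_block(sprintf("TstSP%03d", 1:4), rep(1L, 4), rep(49L, 4),
                  c(r1, r2, r3, r4))
}

fixture_motifs <- function() {
  rbind(
    scan_promoter("ATTACCCTACCCATTCCCGTACCCATTTTTTTTTTATTTTTTTTTTTGG", "TstSP001"),
    scan_promoter("ATTACCCTACCCATTCCCGTACCCATTTTTTTTTTATTTTTTTTTTTGG", "TstSP002"),
    scan_promoter("ATTACCCTACCCATTCCCTTACCCATTTTTTTTTTATTTTTTTTTTTGG", "TstSP003"),
    scan_promoter("ATTACCATACCCATTCCCGTACCCATTTTTTTTTTATTTTTTTTTTTGG", "TstSP004"))
}

fixture_cluster <- function(b, motifs) {
  iv <- map_block_motifs(motifs, b)
  cl <- find_clusters(iv[iv$strand == "noncoding", ], 12)
  expect_length(cl, 1L)
  cl[[1]]
}

test_that("placement enumeration includes whole runs and length-3 shifts", {
  b <- make_test_block(c("AGGGGATTAGGGATAGGGATTAGGGTT",
                         "AGGGGATTAGGGATAGGGATTAGGGTT"))
  cl <- list(block_name = b$name, strand = "coding",
             members = data.frame(species_code = b$species,
                                  first_col = 2L, last_col = 25L,
                                  partial = FALSE),
             common_first = 2L, common_last = 25L)
  pl <- enumerate_placements(cl, b)
  p1 <- pl[["TstSP001"]]
  # tract 1 comes from the GGGG run at 2-5: placements 2-5, 2-4, 3-5
  t1 <- unique(p1[, c("c1s", "c1e"), drop = FALSE])
  expect_setequal(paste(t1[, 1], t1[, 2]), c("2 5", "2 4", "3 5"))
  # brute-force oracle: all 4-tuples over the run sub-placements
  runs <- oracle_runs("AGGGGATTAGGGATAGGGATTAGGGTT")
  cand <- oracle_candidates("AGGGGATTAGGGATAGGGATTAGGGTT")
  expect_equal(sort_tuples(unname(p1[, 9:16, drop = FALSE])), sort_tuples(cand))
})

test_that("group calling maximises membership with the stated tie-breaks", {
  b <- fixture_block()
  motifs <- fixture_motifs()
  cl <- fixture_cluster(b, motifs)
  g <- call_group(enumerate_placements(cl, b), cl, b,
                  setNames(rep(49L, 4), b$species))
  # species 4 has a broken first C-tract: group keeps the other three
  expect_setequal(g$members, c("TstSP001", "TstSP002", "TstSP003"))
  expect_equal(g$nonmembers, "TstSP004")
  expect_equal(g$tract_cols, cbind(c(5L, 10L, 16L, 22L), c(7L, 12L, 18L, 24L)))
  expect_equal(g$strand, "noncoding")
  # all identical rows -> everyone joins, tracts are the shared whole runs
  b2 <- make_test_block(rep("TTGGGAGGGTAGGGCAGGGTT", 3))
  m2 <- do.call(rbind, lapply(b2$species, function(sp) {
    scan_promoter("TTGGGAGGGTAGGGCAGGGTT", sp)
  }))
  iv2 <- map_block_motifs(m2, b2)
  cl2 <- find_clusters(iv2, 12)[[1]]
  g2 <- call_group(enumerate_placements(cl2, b2), cl2, b2,
                   setNames(rep(21L, 3), b2$species))
  expect_length(g2$members, 3L)
  expect_equal(g2$tract_cols, cbind(c(3L, 7L, 12L, 17L), c(5L, 9L, 14L, 19L)))
})

test_that("a 5-species variant beats a 4-species variant", {
  rowA <- "TTGGGGATTGGGATAGGGTATGGGTT"   # GGGG at 3-6
  rowB <- "TTAGGGATTGGGATAGGGTATGGGTT"   # GGG at 4-6 only
  rows <- c(rowA, rowB, rowB, rowB, rowB)
  b <- make_test_block(rows)
  m <- do.call(rbind, lapply(seq_along(rows), function(i) {
    scan_promoter(rows[i], b$species[i])
  }))
  cl <- find_clusters(map_block_motifs(m, b), 12)[[1]]
  g <- call_group(enumerate_placements(cl, b), cl, b,
                  setNames(rep(26L, 5), b$species))
  expect_length(g$members, 5L)
  expect_equal(g$tract_cols[1, ], c(4L, 6L))  # shared sub-run, not GGGG
})

test_that("called groups re-validate: member tract columns all carry the motif letter", {
  g <- generate_order(sim_config(n_species = 6, promoter_length = 800,
                                 n_motifs = 4, background_rate = 0.03,
                                 tract_disruption_prob = 0.2, seed = 11))
  res <- run_order_analysis(g$set)
  expect_gt(length(res$groups), 0)
  for (gr in res$groups) {
    b <- res$blocks[[gr$block_name]]
    letter <- if (gr$strand == "coding") "G" else "C"
    m <- do.call(rbind, strsplit(b$rows[match(gr$members, b$species)], ""))
    for (t in 1:4) {
      expect_true(all(m[, gr$tract_cols[t, 1]:gr$tract_cols[t, 2]] == letter))
    }
    # member count equals the distinct species and >= 2
    expect_gte(length(gr$members), 2L)
    expect_equal(anyDuplicated(gr$members), 0L)
  }
})

test_that("group calling is invariant to species order", {
  b <- fixture_block()
  motifs <- fixture_motifs()
  cl <- fixture_cluster(b, motifs)
  pl <- enumerate_placements(cl, b)
  g1 <- call_group(pl, cl, b, setNames(rep(49L, 4), b$species))
  g2 <- call_group(rev(pl), cl, b, setNames(rep(49L, 4), b$species))
  expect_equal(g2$members, g1$members)
  expect_equal(g2$tract_cols, g1$tract_cols)
})

modal_zone_test <- function(z) g4cons:::modal_zone(z)

test_that("group summaries count by strand and zone with the modal-zone rule", {
  expect_equal(sum(summarize_groups(list())$counts$n), 0L)
  g <- generate_order(sim_config(n_species = 5, promoter_length = 1000,
                                 n_motifs = 4, background_rate = 0, seed = 31))
  res <- run_order_analysis(g$set)
  sm <- summarize_groups(res$groups, "Sim")
  expect_equal(sum(sm$counts$n), length(res$groups))
  truth_strands <- table(g$truth$planted$strand)
  got_strands <- tapply(sm$counts$n, sm$counts$strand, sum)
  for (st in names(truth_strands)) {
    expect_gte(got_strands[[st]], truth_strands[[st]])
  }
  expect_equal(modal_zone_test(c("core", "distal", "distal")), "distal")
  expect_equal(modal_zone_test(c("core", "distal")), "core")  # tie -> TSS side
})
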