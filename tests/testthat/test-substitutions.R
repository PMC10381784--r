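test_that("column consensus takes the most frequent base, ties lexicographic", {
  expect_equal(column_consensus(c("A", "A", "G")), "A")
  expect_equal(column_consensus(c("A", "A", "G", "G")), "A")
  expect_equal(column_consensus(c("-", "-", "-")), "-")
  expect_equal(column_consensus(c("N", "N", "T")), "T")
  for (i in 1:20) {
    set.seed(800 + i)
    rows <- vapply(1:5, function(j) {
      paste(sample(c("A", "C", "G", "T", "-", "N"), 40, TRUE), collapse = "")
    }, "")
    expect_equal(column_consensus(rows), oracle_consensus(rows, 1:40))
  }
})

# Shared fixture: a called noncoding group over a hand-built block with a
# known number of loop substitutions and one disrupted non-member row.
called_fixture <- function() {
  r1 <- "ATTACCCTACCCATTCCCGTACCCATTTTTTTTTTATTTTTTTTTTTGG"
  r3 <- "ATTACCCTACCCATTCCCTTACCCATTTTTTTTTTATTTTTTTTTTTGG"
  r4 <- "ATTACCATACCCATTCCCGTACCCATTTTTTTTTTATTTTTTTTTTTGG"
  b <- alignment_block(sprintf("TstSP%03d", 1:4), rep(1L, 4), rep(49L, 4),
                       c(r1, r1, r3, r4))
  motifs <- do.call(rbind, lapply(1:4, function(i) {
    scan_promoter(c(r1, r1, r3, r4)[i], sprintf("TstSP%03d", i))
  }))
  cl <- find_clusters(map_block_motifs(motifs, b), 12)[[1]]
  g <- call_group(enumerate_placements(cl, b), cl, b,
                  setNames(rep(49L, 4), b$species))
  g$group_id <- "g001"
  list(block = b, motifs = motifs, group = g)
}

test_that("loop substitutions are counted against the member consensus", {
  fx <- called_fixture()
  recs <- count_loop_substitutions(fx$group, fx$block)
  # the only member difference is column 19 G->T in species 3 (loop 2)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$column, 19L)
  expect_equal(recs$species_code, "TstSP003")
  expect_equal(recs$region, "loop3")
  expect_equal(recs$type, "G<->T")
  # identical member loops -> zero records
  b2 <- make_test_block(rep("TTGGGAGGGTAGGGCAGGGTT", 3))
  m2 <- do.call(rbind, lapply(b2$species, function(sp) {
    scan_promoter("TTGGGAGGGTAGGGCAGGGTT", sp)
  }))
  cl2 <- find_clusters(map_block_motifs(m2, b2), 12)[[1]]
  g2 <- call_group(enumerate_placements(cl2, b2), cl2, b2,
                   setNames(rep(21L, 3), b2$species))
  g2$group_id <- "g002"
  expect_equal(nrow(count_loop_substitutions(g2, b2)), 0L)
})

test_that("member tract columns contribute zero substitution records", {
  g <- generate_order(sim_config(n_species = 6, promoter_length = 800,
                                 n_motifs = 4, background_rate = 0.05,
                                 tract_disruption_prob = 0.3, seed = 13))
  res <- run_order_analysis(g$set)
  for (gr in res$groups) {
    recs <- count_loop_substitutions(gr, res$blocks[[gr$block_name]])
    tract_cols <- unlist(lapply(1:4, function(t) {
      gr$tract_cols[t, 1]:gr$tract_cols[t, 2]
    }))
    expect_false(any(recs$column %in% tract_cols))
  }
})

test_that("tract substitutions come only from non-member rows, typed on the coding strand", {
  fx <- called_fixture()
  recs <- count_tract_substitutions(fx$group, fx$block, fx$motifs)
  # non-member TstSP004 carries C->A at column 7 in tract 1 (C-tract: the
  # group is on the noncoding strand, so the tract consensus letter is C)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$column, 7L)
  expect_equal(recs$region, "tract1")
  expect_equal(recs$species_code, "TstSP004")
  expect_equal(recs$type, "A<->C")
})

test_that("substitution type labels are complement-swapped between strands", {
  cod <- "TTGGGAGGGTAGGGCAGGGTT"
  ncd <- g4cons:::revcomp(cod)
  mk <- function(base, mut) {
    rows <- c(rep(base, 3), mut)
    b <- make_test_block(rows)
    m <- do.call(rbind, lapply(seq_along(rows), function(i) {
      scan_promoter(rows[i], b$species[i])
    }))
    cl <- find_clusters(map_block_motifs(m, b), 12)[[1]]
    g <- call_group(enumerate_placements(cl, b), cl, b,
                    setNames(rep(nchar(base), 4), b$species))
    g$group_id <- "g001"
    count_loop_substitutions(g, b)
  }
  # same biological substitution seen from either strand: loop position 10
  # T->C on the coding-motif strand is A->G on the coding row of the
  # noncoding-motif block
  cod_mut <- sub("^(.{9})T", "\\1C", cod)
  ncd_mut <- g4cons:::revcomp(cod_mut)
  expect_equal(mk(cod, cod_mut)$type, "C<->T")
  expect_equal(mk(ncd, ncd_mut)$type, "A<->G")
})

test_that("matched controls avoid motifs and gap runs, searching upstream first", {
  fx <- called_fixture()
  ctrl <- select_control(fx$group, setNames(list(fx$block), fx$block$name),
                         fx$motifs)
  expect_true(ctrl$found)
  expect_equal(ctrl$source, "same_block_downstream")  # upstream is too short
  Ltot <- loop_total_length(fx$group)
  expect_equal(sum(vapply(ctrl$segments, function(s) s[2] - s[1] + 1L, 0L)),
               Ltot)
  # control must not touch any motif columns
  iv <- map_block_motifs(fx$motifs, fx$block)
  for (seg in ctrl$segments) {
    expect_false(any(iv$first_col <= seg[2] & iv$last_col >= seg[1]))
  }
  # saturating every flank with motifs leaves no control -> none result
  fake <- do.call(rbind, lapply(fx$group$members, function(sp) {
    m <- fx$motifs[fx$motifs$species_code == sp, , drop = FALSE]
    w <- m[rep(1, 3), ]
    w$start <- c(1, 26, 45); w$end <- c(25, 44, 50)
    w
  }))
  ctrl2 <- select_control(fx$group, setNames(list(fx$block), fx$block$name),
                          fake)
  expect_false(ctrl2$found)
})

test_that("density is substitutions per column of loop length", {
  expect_equal(density_of(data.frame(x = 1:4), 20), 0.2)
  expect_equal(density_of(data.frame(), 10), 0)
})

test_that("paired one-sided Wilcoxon matches exact enumeration and edge cases", {
  # 5 pairs, all loop > control, distinct magnitudes
  w <- wilcoxon_paired_greater(c(.5, .4, .3, .2, .1), rep(0, 5))
  expect_equal(w$p, 1 / 32)
  expect_equal(w$method, "exact")
  expect_equal(wilcoxon_paired_greater(0.3, 0.1)$p, 0.5)
  expect_equal(wilcoxon_paired_greater(c(.2, .2), c(.2, .2))$method, "none")
  set.seed(19)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    d <- round(runif(n, -1, 1), 3)
    d <- d[d != 0]
    if (length(d) < 1 || anyDuplicated(abs(d))) next
    got <- wilcoxon_paired_greater(d, rep(0, length(d)))
    expect_equal(got$p, oracle_signrank_p(d), tolerance = 1e-12)
    expect_equal(got$method, "exact")
  }
  # ties force the corrected normal approximation
  expect_equal(wilcoxon_paired_greater(c(.2, .2, .4), c(.1, .1, .1))$method,
               "normal")
})

test_that("Holm adjustment reproduces the worked five-order example", {
  p <- c(0.003947, 0.02381, 0.2648, 0.7797, 0.2092)
  expect_equal(round(holm_bonferroni(p), 6),
               c(0.019735, 0.095240, 0.627600, 0.779700, 0.627600))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(holm_bonferroni(c(0.6, 0.7)), c(1, 1))
  # monotone, elementwise >= input
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:8, 1))
    h <- holm_bonferroni(p)
    expect_true(all(h >= p))
    expect_true(all(diff(h[order(p)]) >= -1e-12))
    expect_true(all(h <= 1))
  }
})

test_that("the order-level test excludes control-less groups and counts exceedances", {
  g <- generate_order(sim_config(n_species = 6, promoter_length = 1000,
                                 n_motifs = 6, background_rate = 0.03,
                                 seed = 23))
  res <- run_order_analysis(g$set)
  tst <- res$test
  expect_equal(tst$n_pairs, nrow(tst$pairs))
  expect_equal(tst$n_loop_exceeds_control,
               sum(tst$pairs$loop_density > tst$pairs$control_density))
  expect_equal(run_order_test(list(), res$blocks, res$motifs)$method, "none")
  fam <- adjust_family(list(tst, tst))
  expect_true(all(fam$p_holm >= fam$p_raw, na.rm = TRUE))
})
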