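#' Simulation configuration for promoter-set evolution
#'
#' Describes a star-phylogeny promoter family: one random ancestor with
#' planted G4 motifs, from which each species descends independently by
#' point substitutions (optionally elevated in motif loops), optional
#' G-tract-disrupting substitutions, short indels and runs of N.
#'
#' Default rates reflect the regime in which reliable blocks (>= 80%
#' identical columns over >= 100 columns) exist for realistic set sizes:
#' under a star phylogeny the expected identical-column fraction is
#' `(1 - background_rate)^n_species`, so the default 0.005/site with 20
#' species gives ~0.90.
#'
#' @param n_species Number of descendant species (default 20).
#' @param promoter_length Promoter length in nt (default 1000; the last
#'   position abuts the TSS).
#' @param n_motifs Number of planted G4 motifs (default 6).
#' @param p_noncoding Probability a planted motif lies on the noncoding
#'   strand (default 0.5).
#' @param tract_len,loop_len Ranges for planted tract and loop lengths
#'   (defaults 3-5 and 1-7; the planted span never exceeds 45 nt).
#' @param background_rate Per-site substitution probability per species
#'   (default 0.005).
#' @param loop_multiplier Multiplier on the substitution rate inside planted
#'   motif loops (default 1 = null).
#' @param tract_disruption_prob Probability, per species and planted motif,
#'   of one disruptive substitution in a tract (default 0).
#' @param indel_rate Per-site indel event probability (default 0).
#' @param indel_max Maximum indel length (default 3).
#' @param n_run_prob Probability a species receives one run of N (default 0).
#' @param n_run_len Length range of injected N-runs (default c(5, 30)).
#' @param ts_prob Probability a substitution is a transition (default 1/3 =
#'   uniform over the three alternatives; raise to mimic C<->T / G<->A
#'   dominance).
#' @param base_freq Ancestor base composition, A/C/G/T (default uniform).
#' @param seed RNG seed (required).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_species = 20L, promoter_length = 1000L,
                       n_motifs = 6L, p_noncoding = 0.5,
                       tract_len = c(3L, 5L), loop_len = c(1L, 7L),
                       background_rate = 0.005, loop_multiplier = 1,
                       tract_disruption_prob = 0, indel_rate = 0,
                       indel_max = 3L, n_run_prob = 0,
                       n_run_len = c(5L, 30L), ts_prob = 1 / 3,
                       base_freq = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       seed) {
  stopifnot(n_species >= 1, promoter_length >= 50, n_motifs >= 0,
            p_noncoding >= 0, p_noncoding <= 1,
            background_rate >= 0, background_rate <= 1,
            loop_multiplier >= 0, tract_disruption_prob >= 0,
            tract_disruption_prob <= 1, indel_rate >= 0, indel_rate <= 1,
            n_run_prob >= 0, n_run_prob <= 1, ts_prob >= 0, ts_prob <= 1,
            tract_len[1] >= 3, loop_len[1] >= 1, loop_len[2] <= 30,
            length(base_freq) == 4, abs(sum(base_freq) - 1) < 1e-6,
            !missing(seed))
  structure(as.list(environment()), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# Uniform integers in [a, b], safe for degenerate single-value ranges.
rint <- function(a, b, n = 1L) a + sample.int(b - a + 1L, n, replace = TRUE) - 1L

# One random planted motif on the coding strand (tracts G, loops G-free),
# respecting the 45-nt span cap. Returns list(seq chars, tract/loop offsets).
random_motif <- function(cfg) {
  repeat {
    tl <- rint(cfg$tract_len[1], cfg$tract_len[2], 4)
    ll <- rint(cfg$loop_len[1], cfg$loop_len[2], 3)
    if (sum(tl) + sum(ll) <= 45) break
  }
  segs <- list()
  tract_off <- matrix(0L, 4, 2)
  loop_off <- matrix(0L, 3, 2)
  pos <- 0L
  for (i in 1:4) {
    tract_off[i, ] <- c(pos + 1L, pos + tl[i])
    segs[[length(segs) + 1]] <- rep("G", tl[i])
    pos <- pos + tl[i]
    if (i < 4) {
      loop_off[i, ] <- c(pos + 1L, pos + ll[i])
      segs[[length(segs) + 1]] <- sample(c("A", "C", "T"), ll[i], replace = TRUE)
      pos <- pos + ll[i]
    }
  }
  list(chars = unlist(segs), tract_off = tract_off, loop_off = loop_off,
       span = pos)
}

#' Generate one synthetic promoter set with ground truth
#'
#' The ancestor is assembled from the background composition with planted
#' motifs spaced across the promoter (one per equal-width slot, with
#' non-G/non-C flanking positions so planted tracts keep their boundaries).
#' Each species independently receives substitutions (loop positions at
#' `background_rate * loop_multiplier`, tract positions only through
#' `tract_disruption_prob`, background elsewhere), indels outside planted
#' motifs, and N-runs. Fully reproducible from the seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `set` (a `promoter_set`) and `truth`: ancestor string,
#'   planted motif table, per-species event records, region label vector,
#'   and `expected_motifs` — the scanner's motif table on the ancestor,
#'   which at zero noise is exactly the set of recoverable conserved groups.
#' @export
generate_order <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$promoter_length
  anc <- sample(BASES, L, replace = TRUE, prob = cfg$base_freq)
  region <- rep("background", L)
  motif_of <- integer(L)

  planted <- list()
  if (cfg$n_motifs > 0) {
    slot <- floor(L / cfg$n_motifs)
    for (mi in seq_len(cfg$n_motifs)) {
      m <- random_motif(cfg)
      if (m$span + 2 > slot) {
        stop("infeasible planting: motif span ", m$span,
             " does not fit slot of ", slot, " nt", call. = FALSE)
      }
      strand <- if (runif(1) < cfg$p_noncoding) "noncoding" else "coding"
      off <- sample.int(slot - m$span - 1L, 1)
      start <- (mi - 1L) * slot + off + 1L
      end <- start + m$span - 1L
      chars <- m$chars
      tr <- m$tract_off; lp <- m$loop_off
      if (strand == "noncoding") {
        chars <- rev(chartr("ACGT", "TGCA", chars))
        tr <- m$span + 1L - m$tract_off[4:1, 2:1, drop = FALSE]
        lp <- m$span + 1L - m$loop_off[3:1, 2:1, drop = FALSE]
      }
      anc[start:end] <- chars
      anc[start - 1L] <- sample(c("A", "T"), 1)
      if (end + 1L <= L) anc[end + 1L] <- sample(c("A", "T"), 1)
      for (t in 1:4) {
        region[(start + tr[t, 1] - 1L):(start + tr[t, 2] - 1L)] <- "tract"
      }
      for (l in 1:3) {
        region[(start + lp[l, 1] - 1L):(start + lp[l, 2] - 1L)] <- "loop"
      }
      motif_of[start:end] <- mi
      planted[[mi]] <- data.frame(
        motif_id = mi, strand = strand, start = start, end = end,
        t1_start = start + tr[1, 1] - 1L, t1_end = start + tr[1, 2] - 1L,
        t2_start = start + tr[2, 1] - 1L, t2_end = start + tr[2, 2] - 1L,
        t3_start = start + tr[3, 1] - 1L, t3_end = start + tr[3, 2] - 1L,
        t4_start = start + tr[4, 1] - 1L, t4_end = start + tr[4, 2] - 1L)
    }
  }
  planted <- if (length(planted)) do.call(rbind, planted) else NULL
  if (!is.null(planted)) {
    anc <- sanitize_flanks(anc, motif_of, planted)
  }
  anc_str <- paste(anc, collapse = "")

  rate <- rep(cfg$background_rate, L)
  rate[region == "loop"] <- pmin(1, cfg$background_rate * cfg$loop_multiplier)
  rate[region == "tract"] <- 0

  species <- sprintf("SimSP%03d", seq_len(cfg$n_species))
  seqs <- character(cfg$n_species)
  events <- vector("list", cfg$n_species)
  for (s in seq_len(cfg$n_species)) {
    ev <- evolve_species(anc, region, motif_of, rate, planted, cfg)
    seqs[s] <- ev$seq
    events[[s]] <- ev$events
  }
  names(events) <- species

  set <- promoter_set(species, seqs, order_code = "Sim")
  truth <- list(ancestor = anc_str, planted = planted, events = events,
                region = region, config = cfg,
                expected_motifs = scan_promoter(anc_str, "ancestor"))
  list(set = set, truth = truth)
}

# Break any G- or C-run of >= 3 in the 32-nt flanks of planted motifs (one
# loop length + 2) so no alternative tract placement competes with the
# planted tracts; planted motifs are then identifiable ground truth.
# Positions inside other planted motifs are never touched.
sanitize_flanks <- function(anc, motif_of, planted) {
  L <- length(anc)
  flank <- unique(unlist(lapply(seq_len(nrow(planted)), function(mi) {
    c(max(1L, planted$start[mi] - 32L):max(1L, planted$start[mi] - 1L),
      min(L, planted$end[mi] + 1L):min(L, planted$end[mi] + 32L))
  })))
  flank <- flank[motif_of[flank] == 0L]
  flank <- sort(flank)
  # walk flank positions; whenever 3 consecutive promoter positions in the
  # flank carry the same G/C letter, replace the third with A or T
  for (p in flank) {
    if (p < 3L) next
    b <- anc[p]
    if ((b == "G" || b == "C") && anc[p - 1L] == b && anc[p - 2L] == b) {
      anc[p] <- sample(c("A", "T"), 1)
    }
  }
  anc
}

# Apply one species' worth of evolution; returns sequence and event records.
evolve_species <- function(anc, region, motif_of, rate, planted, cfg) {
  L <- length(anc)
  chars <- anc
  subs <- which(runif(L) < rate)
  from <- anc[subs]
  to <- vapply(from, mutate_base, "", ts_prob = cfg$ts_prob)
  chars[subs] <- to
  sub_df <- data.frame(pos = subs, from = from, to = to,
                       region = region[subs], row.names = NULL,
                       stringsAsFactors = FALSE)

  if (!is.null(planted) && cfg$tract_disruption_prob > 0) {
    for (mi in seq_len(nrow(planted))) {
      if (runif(1) >= cfg$tract_disruption_prob) next
      tcols <- which(motif_of == planted$motif_id[mi] & region == "tract")
      p <- tcols[sample.int(length(tcols), 1)]
      alt <- setdiff(BASES, anc[p])
      chars[p] <- alt[sample.int(3, 1)]
      sub_df <- rbind(sub_df, data.frame(pos = p, from = anc[p],
                                         to = chars[p], region = "tract",
                                         stringsAsFactors = FALSE))
    }
  }

  n_df <- data.frame(pos = integer(), length = integer())
  if (cfg$n_run_prob > 0 && runif(1) < cfg$n_run_prob) {
    len <- rint(cfg$n_run_len[1], cfg$n_run_len[2])
    ok <- which(vapply(seq_len(L - len + 1L), function(p) {
      all(region[p:(p + len - 1L)] == "background")
    }, logical(1)))
    if (length(ok)) {
      p <- ok[sample.int(length(ok), 1)]
      chars[p:(p + len - 1L)] <- "N"
      n_df <- data.frame(pos = p, length = len)
    }
  }

  indel_df <- data.frame(pos = integer(), type = character(),
                         length = integer(), inserted = character(),
                         stringsAsFactors = FALSE)
  n_indel <- if (cfg$indel_rate > 0) rbinom(1, L, cfg$indel_rate) else 0L
  if (n_indel > 0) {
    bg <- which(region == "background")
    for (e in seq_len(n_indel)) {
      len <- sample.int(cfg$indel_max, 1)
      type <- if (runif(1) < 0.5) "ins" else "del"
      if (type == "del") {
        ok <- bg[bg + len - 1L <= L]
        ok <- ok[vapply(ok, function(p) {
          all(region[p:(p + len - 1L)] == "background")
        }, logical(1))]
        if (!length(ok)) next
        p <- ok[sample.int(length(ok), 1)]
        indel_df <- rbind(indel_df, data.frame(pos = p, type = "del",
                                               length = len, inserted = "",
                                               stringsAsFactors = FALSE))
      } else {
        p <- bg[sample.int(length(bg), 1)]
        ins <- paste(sample(BASES, len, replace = TRUE), collapse = "")
        indel_df <- rbind(indel_df, data.frame(pos = p, type = "ins",
                                               length = len, inserted = ins,
                                               stringsAsFactors = FALSE))
      }
    }
  }
  seq <- apply_indels(chars, indel_df)
  list(seq = seq, events = list(substitutions = sub_df, n_runs = n_df,
                                indels = indel_df))
}

mutate_base <- function(b, ts_prob) {
  transition <- c(A = "G", G = "A", C = "T", T = "C")[[b]]
  transversions <- setdiff(BASES, c(b, transition))
  if (runif(1) < ts_prob) transition else transversions[sample.int(2, 1)]
}

# Indels are recorded in ancestor coordinates and applied from the highest
# position down so earlier events do not shift later ones.
apply_indels <- function(chars, indel_df) {
  if (nrow(indel_df)) {
    for (r in order(indel_df$pos, decreasing = TRUE)) {
      p <- indel_df$pos[r]; len <- indel_df$length[r]
      if (indel_df$type[r] == "del") {
        chars <- chars[-(p:(p + len - 1L))]
      } else {
        chars <- append(chars, strsplit(indel_df$inserted[r], "")[[1]],
                        after = p)
      }
    }
  }
  paste(chars, collapse = "")
}

#' Replay recorded evolution events on the ancestor
#'
#' Reproduces a species' sequence exactly from the ground-truth event
#' record; used to verify the bookkeeping invariant.
#'
#' @param truth Ground truth from [generate_order()].
#' @param species_code Which species to replay.
#' @return The reconstructed sequence string.
#' @export
replay_species <- function(truth, species_code) {
  ev <- truth$events[[species_code]]
  chars <- strsplit(truth$ancestor, "")[[1]]
  if (nrow(ev$substitutions)) chars[ev$substitutions$pos] <- ev$substitutions$to
  if (nrow(ev$n_runs)) {
    p <- ev$n_runs$pos; len <- ev$n_runs$length
    chars[p:(p + len - 1L)] <- "N"
  }
  apply_indels(chars, ev$indels)
}

#' Configurations for null and alternative replicate batches
#'
#' @param cfg Base [sim_config()] (its `loop_multiplier` is overridden).
#' @param n_replicates Replicates per batch.
#' @param alt_multiplier Loop-rate multiplier of the alternative batch
#'   (default 2).
#' @return List with `null` and `alt` (lists of `sim_config`s with derived
#'   seeds) and a `manifest` data.frame.
#' @export
generate_null_and_alt_batches <- function(cfg, n_replicates,
                                          alt_multiplier = 2) {
  seeds <- if (n_replicates > 0) child_seeds(cfg$seed, 2 * n_replicates) else integer()
  mk <- function(i, mult) {
    c2 <- cfg
    c2$loop_multiplier <- mult
    c2$seed <- seeds[i]
    c2
  }
  null <- lapply(seq_len(n_replicates), mk, mult = 1)
  alt <- lapply(seq_len(n_replicates) + n_replicates, mk,
                mult = alt_multiplier)
  manifest <- data.frame(
    replicate = rep(seq_len(n_replicates), 2)[seq_len(2 * n_replicates)],
    batch = rep(c("null", "alt"), each = n_replicates),
    loop_multiplier = rep(c(1, alt_multiplier), each = n_replicates),
    seed = seeds)
  list(null = null, alt = alt, manifest = manifest)
}
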