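#' Species code from taxonomic names
#'
#' Codes concatenate the first three letters of the order (capitalised first
#' letter), the first two letters of the genus (upper case) and the first
#' three letters of each species epithet (lower case). Examples: Homo sapiens
#' in Primates -> `PriHOsap`; Canis lupus dingo -> `CarCAlupdin`.
#'
#' @param order_name Mammalian order name, at least 3 letters.
#' @param genus Genus name, at least 2 letters.
#' @param epithets Character vector of species epithets (>= 1, each >= 3
#'   letters).
#' @return The species code string (8-11 characters for 1-2 epithets).
#' @examples
#' make_species_code("Primates", "Homo", "sapiens")
#' @export
make_species_code <- function(order_name, genus, epithets) {
  if (!nzchar(order_name) || !nzchar(genus)) {
    stop("order_name and genus must be non-empty", call. = FALSE)
  }
  if (nchar(order_name) < 3 || nchar(genus) < 2 || length(epithets) < 1 ||
      any(!nzchar(epithets)) || any(nchar(epithets) < 3)) {
    stop("invalid taxonomic name: need >=3 letters of order, >=2 of genus, ",
         ">=3 of each epithet", call. = FALSE)
  }
  ord <- paste0(toupper(substr(order_name, 1, 1)),
                tolower(substr(order_name, 2, 3)))
  gen <- toupper(substr(genus, 1, 2))
  epi <- paste(tolower(substr(epithets, 1, 3)), collapse = "")
  paste0(ord, gen, epi)
}

#' Construct a promoter set
#'
#' A promoter set holds one coding-strand promoter sequence per species of a
#' single order. Position 1 is the distal end; the last position abuts the
#' TSS. Sequences are uppercased; characters outside `{A,C,G,T,N}` are an
#' error. Species codes must be unique.
#'
#' @param species_code Character vector of species codes.
#' @param sequence Character vector of promoter sequences.
#' @param order_code 3-character order code shared by the set.
#' @param source_id Optional free-text provenance per promoter.
#' @return An object of class `promoter_set`: list with `order_code`,
#'   `promoters` (data.frame species_code, sequence, length, source_id) and
#'   `discarded` (data.frame species_code, reason).
#' @export
promoter_set <- function(species_code, sequence, order_code = "Unk",
                         source_id = species_code) {
  stopifnot(length(species_code) == length(sequence))
  sequence <- toupper(sequence)
  for (i in seq_along(sequence)) {
    assert_dna(sequence[i], what = paste0("promoter ", species_code[i]))
    if (nchar(sequence[i]) < 1) stop("empty promoter sequence: ", species_code[i])
  }
  if (anyDuplicated(species_code)) {
    stop("species codes must be unique within a set", call. = FALSE)
  }
  structure(list(
    order_code = order_code,
    promoters = data.frame(species_code = as.character(species_code),
                           sequence = as.character(sequence),
                           length = nchar(sequence),
                           source_id = as.character(source_id),
                           stringsAsFactors = FALSE),
    discarded = data.frame(species_code = character(), reason = character(),
                           stringsAsFactors = FALSE)
  ), class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat("promoter_set: order", x$order_code, "-", nrow(x$promoters),
      "promoters,", nrow(x$discarded), "discarded\n")
  invisible(x)
}

#' Read a promoter set from FASTA
#'
#' Header grammar: `>SPECIESCODE [free text]`; one record per species.
#'
#' @param path FASTA file path.
#' @param order_code Order code to attach to the set.
#' @return A `promoter_set`.
#' @export
read_promoters <- function(path, order_code = "Unk") {
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  codes <- sub("\\s.*$", "", headers)
  promoter_set(codes, as.character(ss), order_code = order_code,
               source_id = headers)
}

#' Write a promoter set as FASTA
#' @param set A `promoter_set`.
#' @param path Output path.
#' @export
write_promoters <- function(set, path) {
  lines <- as.vector(rbind(paste0(">", set$promoters$species_code),
                           set$promoters$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Discard promoters with long runs of N
#'
#' Promoters containing a run of more than `max_run` consecutive `N` symbols
#' are moved to the discarded list with reason `n_run`. Separate shorter runs
#' are not concatenated; a run of exactly `max_run` is retained.
#'
#' @param set A `promoter_set`.
#' @param max_run Longest tolerated N-run (default 100).
#' @return The filtered `promoter_set`.
#' @export
filter_n_runs <- function(set, max_run = 100L) {
  stopifnot(inherits(set, "promoter_set"), max_run >= 1)
  runs <- vapply(set$promoters$sequence, longest_char_run, integer(1), ch = "N")
  bad <- runs > max_run
  if (any(bad)) {
    set$discarded <- rbind(set$discarded, data.frame(
      species_code = set$promoters$species_code[bad], reason = "n_run",
      stringsAsFactors = FALSE))
    set$promoters <- set$promoters[!bad, , drop = FALSE]
    rownames(set$promoters) <- NULL
  }
  set
}

#' Discard promoters without a significant match to a relative
#'
#' Every promoter is locally aligned (match +1, mismatch -1, gap -2) against
#' every other promoter of the set; a promoter is kept if any alignment
#' reaches at least `min_len` aligned columns at `min_identity` identity
#' (identical columns / aligned columns, gaps counted as columns). Promoters
#' with no such hit are discarded with reason `no_relative_match`.
#'
#' @param set A `promoter_set` with at least 2 promoters (a single-promoter
#'   set is returned unchanged with a warning).
#' @param min_len Minimum aligned columns (default 100).
#' @param min_identity Minimum identity fraction (default 0.70).
#' @return The filtered `promoter_set`.
#' @export
filter_relative_similarity <- function(set, min_len = 100L, min_identity = 0.70) {
  stopifnot(inherits(set, "promoter_set"))
  n <- nrow(set$promoters)
  if (n == 0) return(set)
  if (n == 1) {
    warning("single-promoter set: relative-similarity filter is a no-op")
    return(set)
  }
  seqs <- set$promoters$sequence
  keep <- logical(n)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-i]) {
      aln <- Biostrings::pairwiseAlignment(
        seqs[i], seqs[j], type = "local", substitutionMatrix = submat,
        gapOpening = 0, gapExtension = 2)
      p <- as.character(Biostrings::alignedPattern(aln))
      s <- as.character(Biostrings::alignedSubject(aln))
      cols <- nchar(p)
      if (cols < min_len) next
      ident <- sum(strsplit(p, "")[[1]] == strsplit(s, "")[[1]]) / cols
      if (ident >= min_identity) { keep[i] <- TRUE; break }
    }
  }
  if (any(!keep)) {
    set$discarded <- rbind(set$discarded, data.frame(
      species_code = set$promoters$species_code[!keep],
      reason = "no_relative_match", stringsAsFactors = FALSE))
    set$promoters <- set$promoters[keep, , drop = FALSE]
    rownames(set$promoters) <- NULL
  }
  set
}

#' Write the discard report
#' @param set A `promoter_set`.
#' @param path TSV output path (species_code, reason).
#' @export
write_discard_report <- function(set, path) {
  write_tsv(set$discarded, path)
}
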