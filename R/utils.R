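#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate median p.adjust rbinom runif setNames wilcox.test
#' @importFrom utils read.delim write.table head tail
NULL

# Reverse complement of an ACGTN string (upper case).
revcomp <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x))))
}

# Maximal runs of `base` of length >= min_len; data.frame(start, end, length),
# 1-based inclusive. N never extends a run.
base_runs <- function(seq, base = "G", min_len = 3L) {
  m <- gregexpr(paste0(base, "{", min_len, ",}"), seq)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer(), length = integer()))
  }
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m), end = as.integer(m) + len - 1L,
             length = as.integer(len))
}

# Longest run of a character (for N-run filtering).
longest_char_run <- function(seq, ch = "N") {
  m <- gregexpr(paste0(ch, "+"), seq)[[1]]
  if (m[1] == -1L) return(0L)
  max(attr(m, "match.length"))
}

assert_dna <- function(seq, allow_n = TRUE, what = "sequence") {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  if (grepl(paste0("[^", alphabet, "]"), seq)) {
    bad <- unique(strsplit(gsub(paste0("[", alphabet, "]"), "", seq), "")[[1]])
    stop(what, " contains characters outside {",
         paste(strsplit(alphabet, "")[[1]], collapse = ","), "}: ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  invisible(seq)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# Draw reproducible child seeds (< 2^31) from a master seed without
# disturbing the caller's RNG stream more than once.
child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
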