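#' Construct a validated nucleotide sequence
#'
#' Normalizes a character input (one string or a vector of single letters)
#' to the canonical uppercase DNA alphabet \{A, C, G, T\}, mapping U to T.
#' Any other symbol is rejected with the 1-based position of the first
#' offending character, because the mechanical parameter table has no row
#' for ambiguity codes.
#'
#' @param x A single string (e.g. `"ACGT"`) or a character vector of
#'   single-letter symbols.
#' @param id Optional identifier carried through to FASTA output.
#' @return An object of class `dna_sequence`: a list with `symbols`
#'   (character vector of single bases) and `id`.
#' @examples
#' s <- dna_sequence("acgu", id = "x")
#' as.character(s)  # "ACGT"
#' @export
dna_sequence <- function(x, id = "seq") {
  if (!is.character(x) || length(x) < 1L)
    stop("`x` must be a character string or vector of base symbols")
  symbols <- if (length(x) == 1L && nchar(x) != 1L)
    strsplit(x, "", fixed = TRUE)[[1L]] else as.character(x)
  if (length(symbols) < 1L) stop("sequence is empty")
  symbols <- chartr("acgtu", "ACGTU", symbols)
  symbols[symbols == "U"] <- "T"
  bad <- which(!symbols %in% c("A", "C", "G", "T"))
  if (length(bad) > 0L)
    stop(sprintf("invalid symbol '%s' at position %d (alphabet is A/C/G/T/U, any case)",
                 symbols[bad[1L]], bad[1L]))
  structure(list(symbols = symbols, id = as.character(id)[1L]),
            class = "dna_sequence")
}

#' @export
length.dna_sequence <- function(x) length(x$symbols)

#' @export
as.character.dna_sequence <- function(x, ...) paste(x$symbols, collapse = "")

#' @export
print.dna_sequence <- function(x, ...) {
  n <- length(x)
  head <- paste(utils::head(x$symbols, 60L), collapse = "")
  cat(sprintf("<dna_sequence> %s: %d bases\n  %s%s\n", x$id, n, head,
              if (n > 60L) "..." else ""))
  invisible(x)
}

#' Read the first record of a FASTA file
#'
#' Parsing is done by [Biostrings::readBStringSet()]; only the first record
#' is used (the model is defined on a single duplex). Symbols are normalized
#' as in [dna_sequence()].
#'
#' @param path Path to a FASTA file.
#' @return A `dna_sequence` with the record id preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 1L) stop(sprintf("no FASTA record in %s", path))
  rec <- as.character(set[[1L]])
  if (nchar(rec) < 1L) stop(sprintf("first FASTA record in %s is empty", path))
  id <- names(set)[1L]
  if (is.null(id) || !nzchar(id)) id <- "seq"
  # keep only the first whitespace-delimited token of the header
  id <- strsplit(id, "[[:space:]]+")[[1L]][1L]
  dna_sequence(rec, id = id)
}

#' Write a sequence as FASTA
#'
#' @param seq A `dna_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seq, path) {
  stopifnot(inherits(seq, "dna_sequence"))
  set <- Biostrings::BStringSet(stats::setNames(as.character(seq), seq$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Watson-Crick complement of base symbols
#'
#' @param base Character vector of bases in \{A, C, G, T\}.
#' @return The complementary bases (A<->T, G<->C).
#' @examples
#' complement_base(c("A", "G"))  # "T" "C"
#' @export
complement_base <- function(base) {
  if (!is.character(base) || any(!base %in% c("A", "C", "G", "T")))
    stop("`base` must be characters in {A, C, G, T}")
  chartr("ACGT", "TGCA", base)
}

#' Complement a whole chain
#'
#' Returns the base-wise complement (no reversal: position i of chain 2
#' faces position i of chain 1).
#'
#' @param seq A `dna_sequence`.
#' @return A `dna_sequence` of the same length.
#' @export
complement_sequence <- function(seq) {
  stopifnot(inherits(seq, "dna_sequence"))
  dna_sequence(complement_base(seq$symbols),
               id = paste0(seq$id, "_complement"))
}

#' Replace a contiguous block with a single base
#'
#' The homopolymer-substitution edit used by the block-replacement
#' experiments: positions `start` to `start + length - 1` (1-based,
#' inclusive) of chain 1 are set to `base`; everything else is untouched.
#' The input is not modified.
#'
#' @param seq A `dna_sequence`.
#' @param start 1-based start position of the block.
#' @param length Number of bases to replace (0 is a no-op).
#' @param base Replacement base, one of A/C/G/T.
#' @return A new `dna_sequence`; its id gains an edit descriptor such as
#'   `"_40A@471"`.
#' @examples
#' substitute_region(dna_sequence("ACGTACGT"), 3, 2, "A")  # ACAAACGT
#' @export
substitute_region <- function(seq, start, length, base) {
  stopifnot(inherits(seq, "dna_sequence"))
  n <- base::length(seq$symbols)
  start <- as.integer(start); len <- as.integer(length)
  if (is.na(start) || is.na(len) || len < 0L)
    stop("`start` and `length` must be non-negative integers")
  if (len == 0L) return(seq)
  base <- toupper(as.character(base)[1L])
  if (!base %in% c("A", "C", "G", "T"))
    stop("`base` must be one of A, C, G, T")
  if (start < 1L || start + len - 1L > n)
    stop(sprintf("region [%d, %d] out of bounds for a sequence of length %d",
                 start, start + len - 1L, n))
  symbols <- seq$symbols
  symbols[start:(start + len - 1L)] <- base
  structure(list(symbols = symbols,
                 id = sprintf("%s_%d%s@%d", seq$id, len, base, start)),
            class = "dna_sequence")
}

#' Centered homopolymer block coordinates
#'
#' Start position of a length-`block` homopolymer substitution centered in
#' an `n`-base sequence: for n = 980 this gives positions 471-510 for a
#' 40-base block and 441-540 for a 100-base block.
#'
#' @param n Sequence length.
#' @param block Block length (must not exceed `n`).
#' @return The 1-based start position.
#' @export
centered_block_start <- function(n, block) {
  n <- as.integer(n); block <- as.integer(block)
  if (block > n) stop("block longer than sequence")
  (n - block) %/% 2L + 1L
}

#' Generate a random synthetic sequence
#'
#' I.i.d. draws with P(G) = P(C) = `gc_fraction`/2 and
#' P(A) = P(T) = (1 - `gc_fraction`)/2, reproducible under `seed`. Used as
#' a stand-in for a heterogeneous natural sequence (e.g. a 980-base gene)
#' when the real one is not at hand. The caller's RNG state is left
#' untouched.
#'
#' @param n Number of bases (>= 1).
#' @param gc_fraction Target G+C proportion in \[0, 1\].
#' @param seed Integer seed.
#' @return A `dna_sequence` whose id records `n`, `gc_fraction` and `seed`.
#' @export
random_sequence <- function(n, gc_fraction = 0.5, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1")
  if (!is.numeric(gc_fraction) || gc_fraction < 0 || gc_fraction > 1)
    stop("`gc_fraction` must lie in [0, 1]")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  p <- c(A = (1 - gc_fraction) / 2, T = (1 - gc_fraction) / 2,
         G = gc_fraction / 2, C = gc_fraction / 2)
  symbols <- sample(names(p), n, replace = TRUE, prob = p)
  dna_sequence(symbols,
               id = sprintf("synthetic_n%d_gc%g_seed%d", n, gc_fraction,
                            as.integer(seed)))
}
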