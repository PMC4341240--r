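#' Reverse-complement a DNA sequence
#'
#' Plain character-vector reverse complement (DNA alphabet, uppercase).
#' Used throughout for strand handling of loci, reads and target sites.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
complement_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

## run `code` under a fixed RNG seed, restoring caller RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## random DNA string(s) of given lengths
random_dna <- function(lengths) {
  vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

## Hamming distance between equal-length strings (vectorized over x)
hamming <- function(x, y) {
  stopifnot(nchar(y) == nchar(x))
  mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)), x, y, USE.NAMES = FALSE)
}

## write a named character vector as FASTA
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

## TSV helpers with fixed conventions (no quoting, no row names)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
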