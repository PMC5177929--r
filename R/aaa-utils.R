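#' @import stats
#' @import utils
#' @importFrom stringi stri_detect_fixed stri_locate_all_fixed stri_locate_first_fixed
#'   stri_sub stri_length stri_rand_strings
NULL

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

#' Canonicalize a nucleotide string to the DNA alphabet
#'
#' All internal sequence matching is done after a single U->T
#' canonicalization, so RNA-alphabet inputs (mature miRNA catalogs,
#' adapters quoted in RNA form) and DNA-alphabet reads compare equal.
#'
#' @param x character vector of sequences.
#' @return character vector over A/C/G/T, uppercased.
#' @export
as_dna <- function(x) {
  chartr("acgtuU", "ACGTTT", x)
}

#' Canonicalize a nucleotide string to the RNA alphabet (T->U)
#' @param x character vector of sequences.
#' @return character vector over A/C/G/U, uppercased.
#' @export
as_rna <- function(x) {
  chartr("acgutT", "ACGUUU", x)
}

#' Reverse complement (DNA or RNA alphabet preserved)
#' @param x character vector of sequences.
#' @return reverse complements, in the same alphabet as the input.
#' @export
revcomp <- function(x) {
  is_rna <- grepl("U", toupper(x), fixed = TRUE) & !grepl("T", toupper(x), fixed = TRUE)
  comp <- chartr("ACGTUacgtu", "TGCAATGCAA", x)
  out <- vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), character(1))
  out[is_rna] <- chartr("T", "U", out[is_rna])
  out
}

stopifnot_seq <- function(x, alphabet = DNA_BASES, what = "sequence") {
  bad <- !grepl(sprintf("^[%s]*$", paste(alphabet, collapse = "")), x)
  if (any(bad)) {
    stop(sprintf("%s contains symbols outside {%s}: %s", what,
                 paste(alphabet, collapse = ","),
                 paste(utils::head(x[bad], 3), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Draw random nucleotide sequences
#' @param n number of sequences.
#' @param len length (scalar or vector recycled to `n`).
#' @param alphabet character vector of letters to draw from.
#' @return character vector of random sequences.
#' @export
random_seq <- function(n, len, alphabet = DNA_BASES) {
  len <- rep_len(len, n)
  vapply(len, function(l) paste(sample(alphabet, l, replace = TRUE), collapse = ""),
         character(1))
}

## Evaluate expr under a locally-seeded RNG stream, restoring the caller's
## RNG state afterwards so simulation functions are reproducible without
## clobbering the session RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences (DNA-canonicalized).
#' @export
read_fasta_seqs <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("unreadable FASTA '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  out <- as_dna(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(as_dna(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
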