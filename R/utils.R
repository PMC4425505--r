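DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a nucleotide string
#'
#' @param x A single DNA string (A/C/G/T, case-insensitive).
#' @return The reverse complement, upper-case.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# 0-based half-open substring, matching genomic coordinates as stored
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

# Run code under a seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, composition = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = composition), collapse = "")
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# sample n draws from a Dirichlet(alpha) via gamma representation
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}
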