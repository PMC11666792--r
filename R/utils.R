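# Shared low-level helpers: seeded substreams, base/trinucleotide coding,
# reverse complements. Internal coordinates are 0-based half-open throughout;
# conversion to 1-based happens only at file boundaries (VCF/SAM).

DNA_BASES <- c("A", "C", "G", "T")

#' All 64 trinucleotides in alphabetical order (AAA ... TTT)
#' @keywords internal
trinucleotides <- function() {
  g <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

# ASCII code -> 0..3 base index (A=0, C=1, G=2, T=3); others -> NA
.base_code_lut <- local({
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  lut
})

#' Encode a sequence string as integer base codes (A=0,C=1,G=2,T=3, NA else)
#' @keywords internal
encode_bases <- function(seq) {
  .base_code_lut[utf8ToInt(seq) + 1L]
}

#' Per-position trinucleotide ids (1..64) from base codes
#'
#' Position i (1-based vector index) gets the id of the top-strand
#' trinucleotide centred on i; ends and positions touching non-ACGT are NA.
#' Id 1 = AAA, 64 = TTT (alphabetical).
#' @keywords internal
context_ids <- function(codes) {
  n <- length(codes)
  out <- rep(NA_integer_, n)
  if (n >= 3L) {
    i <- 2:(n - 1L)
    out[i] <- 16L * codes[i - 1L] + 4L * codes[i] + codes[i + 1L] + 1L
  }
  out
}

# id of the reverse complement of each trinucleotide id
.revcomp_ctx_lut <- local({
  ids <- 0:63
  b1 <- ids %/% 16L; b2 <- (ids %/% 4L) %% 4L; b3 <- ids %% 4L
  16L * (3L - b3) + 4L * (3L - b2) + (3L - b1) + 1L
})

#' Reverse-complement a trinucleotide id
#' @keywords internal
revcomp_ctx_id <- function(id) .revcomp_ctx_lut[id]

#' Reverse complement of a DNA string (vectorised)
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Complement of single bases (vectorised over characters)
#' @keywords internal
comp_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

#' Derive a deterministic substream seed from a root seed and a stream name
#'
#' All generator randomness flows from one root seed through named substreams
#' so that adding a generator never perturbs the draws of another. The derived
#' seed stays below 2^31.
#' @keywords internal
substream_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 1000000007
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

#' Evaluate an expression under a temporary RNG state
#' @keywords internal
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

#' Fetch the top-strand base at a 0-based position
#' @param reference named character vector or `DNAStringSet` of contigs
#' @keywords internal
ref_base <- function(reference, contig, pos0) {
  seqs <- as_reference(reference)
  substr(seqs[[contig]], pos0 + 1L, pos0 + 1L)
}

#' Top-strand subsequence [start0, end0) of a contig
#' @keywords internal
ref_slice <- function(reference, contig, start0, end0) {
  seqs <- as_reference(reference)
  substr(seqs[[contig]], start0 + 1L, end0)
}

#' Normalise a reference to a named list of uppercase sequence strings
#' @keywords internal
as_reference <- function(reference) {
  if (is(reference, "DNAStringSet")) {
    out <- as.character(reference)
    return(as.list(out))
  }
  if (is.character(reference)) return(as.list(toupper(reference)))
  if (is.list(reference)) return(lapply(reference, toupper))
  stop("reference must be a DNAStringSet, named character vector, or list")
}

#' Contig lengths of a reference
#' @keywords internal
reference_lengths <- function(reference) {
  vapply(as_reference(reference), nchar, integer(1))
}

is <- methods::is
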