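# Lesion-capture alignment processing: SAM records -> single-nucleotide
# 8-oxoG lesion calls with strand. The filters mirror the damage-capture
# convention: only full-length <read_length>M alignments with bitwise flag
# exactly 0 or 16 on canonical contigs are used; the candidate column is the
# read's 5' alignment column (flag 0) or its rightmost column (flag 16), and
# the call is kept only when the strand-specific reference base there is G.

CANONICAL_CONTIGS <- c(paste0("chr", c(1:22, "X", "Y")))

#' Parse plain-text SAM alignment records
#'
#' Tolerant streaming parser for the 11 mandatory SAM columns; optional tags
#' are ignored. Records later rejected by [reads_to_lesions()] filters are
#' passed through unchanged.
#'
#' @param path SAM file (plain text, with header).
#' @return data frame: `qname`, `flag`, `contig`, `pos` (1-based leftmost),
#'   `cigar`, `read_length` (length of SEQ, NA when SEQ is "*").
#' @export
parse_sam_records <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  if (!any(startsWith(lines, "@SQ")))
    warning("SAM header has no @SQ lines")
  body_idx <- which(!is_hdr & nzchar(lines))
  if (length(body_idx) == 0) {
    return(data.frame(qname = character(), flag = integer(),
                      contig = character(), pos = integer(),
                      cigar = character(), read_length = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 11L)
  if (length(bad))
    stop("truncated SAM record at line ", body_idx[bad[1]],
         ": expected 11 mandatory fields")
  get <- function(k) vapply(fields, `[[`, character(1), k)
  seqf <- get(10)
  data.frame(qname = get(1), flag = as.integer(get(2)), contig = get(3),
             pos = as.integer(get(4)), cigar = get(6),
             read_length = ifelse(seqf == "*", NA_integer_, nchar(seqf)),
             stringsAsFactors = FALSE)
}

#' Convert lesion-capture reads to single-nucleotide lesion calls
#'
#' Applies, in order: flag filter (exactly 0 or 16), CIGAR filter (exactly
#' `<read_length>M`), contig whitelist, alignment-bounds check, then the
#' guanine filter — the candidate position is kept only when its
#' strand-specific reference base is G (top-strand G for flag 0, top-strand
#' C for flag 16). Candidate column: flag 0 -> `(pos - 1) + offset` on "+";
#' flag 16 -> `(pos - 1) + read_length - 1 - offset` on "-".
#'
#' @param reads data frame from [parse_sam_records()].
#' @param reference reference sequences covering the retained contigs.
#' @param read_length required alignment length (bp).
#' @param offset signed shift of the lesion column from the read's 5' end
#'   (0 = the 5' alignment column itself).
#' @param contigs contig whitelist; default the canonical chr1-22/X/Y set
#'   plus every contig present in `reference`.
#' @return data frame `contig`, `pos` (0-based), `strand`, `context`
#'   (top-strand trinucleotide), sorted canonically; attribute `rejected`
#'   holds counts by rejection reason (input = retained + sum(rejected)).
#' @export
reads_to_lesions <- function(reads, reference, read_length = 150L,
                             offset = 0L, contigs = NULL) {
  seqs <- as_reference(reference)
  lens <- reference_lengths(reference)
  if (is.null(contigs)) contigs <- union(CANONICAL_CONTIGS, names(seqs))
  rejected <- c(flag = 0L, cigar = 0L, contig = 0L, bounds = 0L, not_g = 0L)

  ok <- reads$flag %in% c(0L, 16L)
  rejected[["flag"]] <- sum(!ok)
  r <- reads[ok, , drop = FALSE]

  want <- paste0(read_length, "M")
  ok <- r$cigar == want
  rejected[["cigar"]] <- sum(!ok)
  r <- r[ok, , drop = FALSE]

  ok <- r$contig %in% intersect(contigs, names(seqs))
  rejected[["contig"]] <- sum(!ok)
  r <- r[ok, , drop = FALSE]

  cand <- ifelse(r$flag == 0L, r$pos - 1L + offset,
                 r$pos - 1L + read_length - 1L - offset)
  strand <- ifelse(r$flag == 0L, "+", "-")
  ok <- cand >= 0L & cand < lens[r$contig]
  rejected[["bounds"]] <- sum(!ok)
  r <- r[ok, , drop = FALSE]; cand <- cand[ok]; strand <- strand[ok]

  top <- character(nrow(r))
  for (ctg in unique(r$contig)) {
    sel <- r$contig == ctg
    top[sel] <- vapply(cand[sel] + 1L, function(p)
      substr(seqs[[ctg]], p, p), character(1))
  }
  ok <- (strand == "+" & top == "G") | (strand == "-" & top == "C")
  rejected[["not_g"]] <- sum(!ok)
  r <- r[ok, , drop = FALSE]; cand <- cand[ok]; strand <- strand[ok]

  ctx <- character(nrow(r))
  for (ctg in unique(r$contig)) {
    sel <- r$contig == ctg
    ctx[sel] <- vapply(cand[sel], function(p) {
      if (p < 1L || p > lens[[ctg]] - 2L) NA_character_
      else substr(seqs[[ctg]], p, p + 2L)
    }, character(1))
  }
  out <- data.frame(contig = r$contig, pos = cand, strand = strand,
                    context = ctx, stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}
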