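# File-format boundaries. Internal coordinates are 0-based half-open;
# 1-based conversion happens here and nowhere else.

#' Write a reference to FASTA
#' @export
write_fasta <- function(reference, path) {
  seqs <- Biostrings::DNAStringSet(unlist(as_reference(reference)))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA reference into a named character vector
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a BED track (3-6 columns, no header)
#'
#' `df` must carry `contig`, `start`, `end` (0-based half-open) and may carry
#' `name`, `score`, `strand`.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("contig", "start", "end", "name", "score", "strand"),
                    names(df))
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED track into a data frame
#'
#' Columns beyond the first three are named `name`, `score`, `strand` (BED6);
#' 4-column tracks keep their label in `name`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#", quote = "")
  names(df) <- c("contig", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  df
}

#' Write somatic calls as a minimal VCF 4.2
#'
#' @param calls data frame with `contig`, `pos` (0-based), `ref`, `alt`.
#' @param path output path.
#' @param contig_lengths optional named vector for `##contig` header lines.
#' @export
write_vcf <- function(calls, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=oxmut")
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(calls)) {
    filt <- if ("filter" %in% names(calls)) calls$filter else "PASS"
    sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.", calls$contig,
            as.integer(calls$pos) + 1L, calls$ref, calls$alt, filt)
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF call set into VariantCall rows
#'
#' Parses with `vcfR`, splits multi-allelic records into one call per ALT
#' allele, converts positions to 0-based, and classifies each call as SNV,
#' INS, DEL, or OTHER. The FILTER column is recorded; calls are dropped on
#' FILTER only when `pass_only = TRUE`.
#'
#' @param path VCF 4.x file.
#' @param sample_id sample the calls belong to.
#' @param caller caller name recorded on every call.
#' @param pass_only if TRUE keep only FILTER `PASS`/`.` records.
#' @return data frame: `contig`, `pos` (0-based), `ref`, `alt`, `class`,
#'   `filter`, `sample_id`, `caller`.
#' @export
read_vcf <- function(path, sample_id = NA_character_, caller = NA_character_,
                     pass_only = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs come back as a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      class = character(), filter = character(),
                      sample_id = character(), caller = character(),
                      stringsAsFactors = FALSE))
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  out <- data.frame(contig = fix$CHROM[idx],
                    pos = as.integer(fix$POS[idx]) - 1L,
                    ref = toupper(fix$REF[idx]),
                    alt = toupper(unlist(alts)),
                    filter = ifelse(is.na(fix$FILTER[idx]), ".",
                                    fix$FILTER[idx]),
                    sample_id = sample_id, caller = caller,
                    stringsAsFactors = FALSE)
  out$class <- variant_class(out$ref, out$alt)
  if (any(is.na(out$pos))) stop("malformed VCF record: non-numeric POS")
  if (pass_only) out <- out[out$filter %in% c("PASS", "."), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("contig", "pos", "ref", "alt", "class", "filter", "sample_id",
          "caller")]
}

#' Classify ref/alt allele pairs as SNV / INS / DEL / OTHER
#' @keywords internal
variant_class <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
    ifelse(nchar(ref) > nchar(alt), "DEL",
      ifelse(nchar(alt) > nchar(ref), "INS", "OTHER")))
}

#' Write alignment records as plain-text SAM
#'
#' @param records data frame from [make_sam_fixture()].
#' @param path output path.
#' @param contig_lengths named vector for the `@SQ` header lines.
#' @export
write_sam <- function(records, path, contig_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  body <- if (nrow(records)) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            records$qname, records$flag, records$rname, records$pos,
            records$mapq, records$cigar, records$seq)
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write lesion calls as BED6 or a minimal VCF-like file
#'
#' BED output uses the half-open convention (`pos`, `pos + 1`) with name "."
#' and score 0. VCF output reports the top-strand base (G for plus-strand
#' lesions, C for minus-strand) as REF and "." as ALT so lesions and
#' mutations travel through the same downstream profiling.
#'
#' @param lesions data frame with `contig`, `pos` (0-based), `strand`.
#' @export
write_lesions <- function(lesions, path, format = c("bed", "vcf"),
                          contig_lengths = NULL) {
  format <- match.arg(format)
  if (format == "bed") {
    n <- nrow(lesions)
    df <- data.frame(contig = lesions$contig, start = lesions$pos,
                     end = lesions$pos + 1L, name = rep(".", n),
                     score = rep(0L, n), strand = lesions$strand)
    write_bed(df, path)
  } else {
    calls <- data.frame(contig = lesions$contig, pos = lesions$pos,
                        ref = ifelse(lesions$strand == "+", "G", "C"),
                        alt = ".", stringsAsFactors = FALSE)
    write_vcf(calls, path, contig_lengths)
  }
  invisible(path)
}

#' Read lesions back from BED6
#' @export
read_lesions <- function(path) {
  if (length(readLines(path, n = 1)) == 0) {
    return(data.frame(contig = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  df <- read_bed(path)
  data.frame(contig = df$contig, pos = df$start, strand = df$strand,
             stringsAsFactors = FALSE)
}

#' Write a spectrum or signature catalog as TSV (channels x columns)
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  df <- data.frame(channel = spectrum$channels, count = spectrum$counts,
                   fraction = spectrum$fractions)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a COSMIC-style signature catalog TSV
#'
#' First column: channel labels; remaining columns: one signature each.
#' Columns are renormalised to sum to 1.
#' @export
read_signature_catalog <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  signature_catalog(mat)
}
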