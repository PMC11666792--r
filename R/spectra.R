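# Mutation and lesion spectra: SBS96 and ID83 channelisation, cosine
# similarity, differential spectra, non-negative least-squares refitting
# against a signature catalog, exposure correlation, and flanking-base
# composition around 1-bp deletions.

#' The 96 SBS channels in canonical (substitution-major) order
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) for (p5 in DNA_BASES) for (p3 in DNA_BASES) {
    out <- c(out, paste0(p5, "[", s, "]", p3))
  }
  out
}

#' The 83 indel channels in canonical COSMIC order
#'
#' Labels are `size:Del|Ins:C|T|R|M:k`. For homopolymer (1-bp) deletions `k`
#' is the homopolymer length minus 1 capped at 5 (length counted including
#' the deleted base); for 1-bp insertions `k` is the pre-existing run length
#' capped at 5 (excluding the inserted base). For longer indels at tandem
#' repeats `k` counts repeat copies (deletions: including the deleted copy,
#' minus 1, capped at 5; insertions: pre-existing copies capped at 5).
#' `M` channels are microhomology deletions with `k` the homology length.
#' @export
id83_channels <- function() {
  out <- character(0)
  for (b in c("C", "T")) out <- c(out, paste0("1:Del:", b, ":", 0:5))
  for (b in c("C", "T")) out <- c(out, paste0("1:Ins:", b, ":", 0:5))
  for (L in 2:5) out <- c(out, paste0(L, ":Del:R:", 0:5))
  for (L in 2:5) out <- c(out, paste0(L, ":Ins:R:", 0:5))
  out <- c(out, "2:Del:M:1", paste0("3:Del:M:", 1:2),
           paste0("4:Del:M:", 1:3), paste0("5:Del:M:", 1:5))
  out
}

#' Classify SNVs into SBS96 channels
#'
#' Purine-reference mutations are reverse-complemented (alleles and flanking
#' context) onto the pyrimidine-centred channel. Returns NA (counted as
#' unclassified) for calls at contig edges or with non-ACGT context.
#'
#' @param variants data frame with `contig`, `pos` (0-based), `ref`, `alt`.
#' @param reference reference sequences (for the flanking bases).
#' @return character vector of channels like `"T[C>A]A"`, NA when
#'   unclassifiable.
#' @export
classify_sbs96 <- function(variants, reference) {
  seqs <- as_reference(reference)
  lens <- reference_lengths(reference)
  n <- nrow(variants)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    p <- variants$pos[i]; ctg <- variants$contig[i]
    ref <- variants$ref[i]; alt <- variants$alt[i]
    if (nchar(ref) != 1L || nchar(alt) != 1L) next
    if (is.null(seqs[[ctg]]) || p < 1L || p > lens[[ctg]] - 2L) next
    ctx <- substr(seqs[[ctg]], p, p + 2L)
    if (grepl("[^ACGT]", ctx) || !ref %in% DNA_BASES || !alt %in% DNA_BASES)
      next
    if (ref %in% c("A", "G")) {
      ctx <- revcomp(ctx); ref <- comp_base(ref); alt <- comp_base(alt)
    }
    out[i] <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]",
                     substr(ctx, 3, 3))
  }
  out
}

# maximal run of base `b` in `seq` containing 1-based position `q`
.run_length_at <- function(seq, q, b) {
  n <- nchar(seq)
  if (substr(seq, q, q) != b) return(0L)
  l <- q
  while (l > 1L && substr(seq, l - 1L, l - 1L) == b) l <- l - 1L
  r <- q
  while (r < n && substr(seq, r + 1L, r + 1L) == b) r <- r + 1L
  r - l + 1L
}

# number of contiguous copies of motif `m` in `seq` around the block starting
# at 1-based position `q` (the copy at q itself included when present)
.repeat_copies <- function(seq, q, m) {
  L <- nchar(m); n <- nchar(seq)
  copies <- 0L
  p <- q
  while (p >= 1L && p + L - 1L <= n && substr(seq, p, p + L - 1L) == m) {
    copies <- copies + 1L; p <- p - L
  }
  p <- q + L
  while (p + L - 1L <= n && substr(seq, p, p + L - 1L) == m) {
    copies <- copies + 1L; p <- p + L
  }
  copies
}

#' Classify indels into ID83 channels
#'
#' Calls are left-normalised first. 1-bp deletions/insertions of A or G are
#' collapsed to T/C by complementation; homopolymer lengths follow the
#' conventions documented in [id83_channels()]. Longer deletions not in a
#' tandem repeat are checked for flanking microhomology.
#'
#' @param variants data frame with `contig`, `pos` (0-based), `ref`, `alt`
#'   in anchored VCF representation.
#' @param reference reference sequences.
#' @return character vector of ID83 channel labels, NA when unclassifiable
#'   (e.g. at contig edges).
#' @export
classify_indel <- function(variants, reference) {
  seqs <- as_reference(reference)
  variants <- left_normalize(variants, reference)
  n <- nrow(variants)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ref <- variants$ref[i]; alt <- variants$alt[i]
    ctg <- seqs[[variants$contig[i]]]
    if (is.null(ctg)) next
    pos <- variants$pos[i]
    nr <- nchar(ref); na <- nchar(alt)
    if (nr == na) next
    is_del <- nr > na
    # anchored form: shorter allele must be a prefix of the longer
    long <- if (is_del) ref else alt
    short <- if (is_del) alt else ref
    if (substr(long, 1, nchar(short)) != short) next
    S <- substr(long, nchar(short) + 1L, nchar(long))
    L <- nchar(S)
    q1 <- pos + nchar(short) + 1L  # 1-based start of the indel block
    if (q1 < 2L || q1 + L > nchar(ctg)) next
    if (grepl("[^ACGT]", S)) next
    if (L == 1L) {
      b <- S
      lab_base <- if (b %in% c("A", "G")) comp_base(b) else b
      if (is_del) {
        run <- .run_length_at(ctg, q1, b)  # includes the deleted base
        out[i] <- paste0("1:Del:", lab_base, ":", min(run, 6L) - 1L)
      } else {
        # pre-existing run adjacent to the insertion point, excluding the
        # inserted base: copies of b contiguous at/after q1 plus before it
        run <- 0L
        p <- q1
        while (p <= nchar(ctg) && substr(ctg, p, p) == b) { run <- run + 1L; p <- p + 1L }
        p <- q1 - 1L
        while (p >= 1L && substr(ctg, p, p) == b) { run <- run + 1L; p <- p - 1L }
        out[i] <- paste0("1:Ins:", lab_base, ":", min(run, 5L))
      }
    } else {
      sz <- min(L, 5L)
      if (is_del) {
        copies <- .repeat_copies(ctg, q1, S)  # includes the deleted copy
        if (copies >= 2L) {
          out[i] <- paste0(sz, ":Del:R:", min(copies, 6L) - 1L)
        } else {
          # microhomology: overlap between the deleted block and the
          # sequence beyond it (forward) or before it (backward)
          fwd <- 0L
          while (fwd < L - 1L && q1 + L + fwd <= nchar(ctg) &&
                 substr(S, fwd + 1L, fwd + 1L) ==
                 substr(ctg, q1 + L + fwd, q1 + L + fwd)) fwd <- fwd + 1L
          bwd <- 0L
          while (bwd < L - 1L && q1 - 1L - bwd >= 1L &&
                 substr(S, L - bwd, L - bwd) ==
                 substr(ctg, q1 - 1L - bwd, q1 - 1L - bwd)) bwd <- bwd + 1L
          mh <- max(fwd, bwd)
          if (mh >= 1L) {
            cap <- if (L >= 5L) 5L else L - 1L
            out[i] <- paste0(sz, ":Del:M:", min(mh, cap))
          } else {
            out[i] <- paste0(sz, ":Del:R:0")
          }
        }
      } else {
        copies <- .repeat_copies(ctg, q1, S)  # pre-existing copies only
        out[i] <- paste0(sz, ":Ins:R:", min(copies, 5L))
      }
    }
  }
  out
}

#' Build a mutation (or lesion) spectrum
#'
#' SNVs are channelised with [classify_sbs96()], indels with
#' [classify_indel()]. Lesions (rows with `strand` and no usable `alt`) are
#' channelised by the same pyrimidine-centred collapse of their G-centred
#' context and displayed in the C>A block — a presentation convention that
#' makes lesion and substitution spectra directly comparable, not a claim
#' that lesions are substitutions.
#'
#' @param events data frame of variants or lesions.
#' @param reference reference sequences.
#' @param schema `"SBS96"` or `"ID83"`.
#' @return object of class `oxmut_spectrum`: list with `schema`, `channels`,
#'   `counts`, `fractions`, `total`, `unclassified`.
#' @export
build_spectrum <- function(events, reference, schema = c("SBS96", "ID83")) {
  schema <- match.arg(schema)
  channels <- if (schema == "SBS96") sbs96_channels() else id83_channels()
  if (nrow(events) > 0 && schema == "SBS96" &&
      (!("alt" %in% names(events)) || all(events$alt %in% c(".", NA)))) {
    # lesion input: pseudo-substitution G>T on the lesion strand
    events$ref <- ifelse(events$strand == "+", "G", "C")
    events$alt <- ifelse(events$strand == "+", "T", "A")
  }
  ch <- if (nrow(events) == 0) character(0)
  else if (schema == "SBS96") classify_sbs96(events, reference)
  else classify_indel(events, reference)
  counts <- table(factor(ch, levels = channels))
  counts <- as.integer(counts)
  total <- sum(counts)
  structure(list(schema = schema, channels = channels, counts = counts,
                 fractions = if (total > 0) counts / total else
                   rep(0, length(channels)),
                 total = total, unclassified = sum(is.na(ch))),
            class = "oxmut_spectrum")
}

#' Sum two spectra of the same schema
#' @export
add_spectra <- function(a, b) {
  stopifnot(identical(a$channels, b$channels))
  counts <- a$counts + b$counts
  total <- sum(counts)
  structure(list(schema = a$schema, channels = a$channels, counts = counts,
                 fractions = if (total > 0) counts / total else
                   rep(0, length(counts)),
                 total = total, unclassified = a$unclassified + b$unclassified),
            class = "oxmut_spectrum")
}

.as_fraction_vector <- function(x, channels = NULL) {
  if (inherits(x, "oxmut_spectrum")) {
    v <- x$fractions; names(v) <- x$channels
  } else {
    v <- as.numeric(x)
    if (!is.null(names(x))) names(v) <- names(x)
  }
  if (!is.null(channels)) {
    if (is.null(names(v))) stop("channel restriction requires named vectors")
    v <- v[channels]
  }
  v
}

#' Cosine similarity between two spectra or signature vectors
#'
#' @param a,b spectra (`oxmut_spectrum`) or numeric vectors on the same
#'   channel schema.
#' @param channels optional channel subset (e.g. the 16 C>A channels).
#' @return value in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b, channels = NULL) {
  va <- .as_fraction_vector(a, channels)
  vb <- .as_fraction_vector(b, channels)
  if (length(va) != length(vb)) stop("schema mismatch")
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  sum(va * vb) / (na * nb)
}

#' Per-channel percentage differences between two spectra
#'
#' `100 * fractions(a) - 100 * fractions(b)`; the entries sum to zero.
#' @export
differential_spectrum <- function(a, b) {
  va <- .as_fraction_vector(a); vb <- .as_fraction_vector(b)
  if (length(va) != length(vb)) stop("schema mismatch")
  if (all(va == 0) || all(vb == 0)) stop("zero-total spectrum")
  100 * va - 100 * vb
}

#' Construct a signature catalog
#'
#' @param matrix channels x signatures nonnegative matrix; columns are
#'   renormalised to sum to 1.
#' @export
signature_catalog <- function(matrix) {
  if (ncol(matrix) == 0) stop("empty catalog")
  cs <- colSums(matrix)
  if (any(cs <= 0)) stop("catalog signature with zero mass")
  mat <- sweep(matrix, 2, cs, "/")
  structure(list(names = colnames(mat), matrix = mat),
            class = "oxmut_catalog")
}

#' Refit a spectrum onto a signature catalog (NNLS)
#'
#' Nonnegative least-squares attribution of channel counts to catalog
#' signatures, solved exactly (active-set KKT). Exposures are in mutation
#' counts.
#'
#' @param spectrum an `oxmut_spectrum` (or count vector on the catalog's
#'   channels).
#' @param catalog a [signature_catalog()].
#' @return list: `exposures` (named, >= 0), `residual` (L2 norm),
#'   `fitted` (catalog x exposures).
#' @export
refit_exposures <- function(spectrum, catalog) {
  counts <- if (inherits(spectrum, "oxmut_spectrum")) spectrum$counts
  else as.numeric(spectrum)
  if (length(counts) != nrow(catalog$matrix)) stop("schema mismatch")
  if (all(counts == 0)) {
    expo <- stats::setNames(rep(0, length(catalog$names)), catalog$names)
    return(list(exposures = expo, residual = 0,
                fitted = rep(0, length(counts))))
  }
  fit <- pracma::lsqnonneg(catalog$matrix, counts)
  expo <- stats::setNames(fit$x, catalog$names)
  fitted <- as.vector(catalog$matrix %*% fit$x)
  list(exposures = expo, residual = sqrt(sum((counts - fitted)^2)),
       fitted = fitted)
}

#' Correlate per-sample exposures of two signatures
#'
#' Samples are retained only when both exposures meet `min_mutations`;
#' the Pearson correlation is computed on log2 counts by default.
#'
#' @param exposures_a,exposures_b named per-sample exposure vectors (paired
#'   by name).
#' @param min_mutations minimum mutations attributed on both axes.
#' @param log_transform correlate log2 counts (TRUE) or raw counts.
#' @return list: `r`, `n_retained`, `retained` sample names, `p`.
#' @export
exposure_correlation <- function(exposures_a, exposures_b,
                                 min_mutations = 20, log_transform = TRUE) {
  common <- intersect(names(exposures_a), names(exposures_b))
  a <- exposures_a[common]; b <- exposures_b[common]
  keep <- a >= min_mutations & b >= min_mutations
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) {
    return(list(r = NA_real_, n_retained = length(a),
                retained = names(a), p = NA_real_,
                flagged = "fewer than 3 retained samples"))
  }
  if (log_transform) { a <- log2(a); b <- log2(b) }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), n_retained = length(a), retained = names(a),
       p = ct$p.value)
}

#' Base composition flanking 1-bp deletions
#'
#' For offsets -k..-1, +1..+k around the deleted base, in the orientation of
#' the deleted base's pyrimidine strand (deletions of A/G are
#' reverse-complemented), the frequency of each base. Offsets that fall off
#' a contig are skipped for that event.
#'
#' @param deletions data frame of 1-bp deletions (anchored VCF form).
#' @param reference reference sequences.
#' @param k flank width (bp).
#' @return matrix `2k x 4` of per-offset base frequencies (rows sum to 1),
#'   rownames the signed offsets.
#' @export
flanking_composition <- function(deletions, reference, k = 5L) {
  seqs <- as_reference(reference)
  lens <- reference_lengths(reference)
  deletions <- left_normalize(deletions, reference)
  offs <- c(-(k:1), 1:k)
  counts <- matrix(0L, nrow = 2L * k, ncol = 4L,
                   dimnames = list(offs, DNA_BASES))
  for (i in seq_len(nrow(deletions))) {
    ref <- deletions$ref[i]; alt <- deletions$alt[i]
    if (is.na(ref) || is.na(alt)) next
    if (nchar(ref) - nchar(alt) != 1L || substr(ref, 1, 1) != alt) next
    b <- substr(ref, 2, 2)
    q1 <- deletions$pos[i] + 2L  # 1-based deleted base
    ctg <- seqs[[deletions$contig[i]]]
    len <- lens[[deletions$contig[i]]]
    flip <- b %in% c("A", "G")
    for (o in offs) {
      p <- if (flip) q1 - o else q1 + o
      if (p < 1L || p > len) next
      base <- substr(ctg, p, p)
      if (flip) base <- comp_base(base)
      if (base %in% DNA_BASES)
        counts[as.character(o), base] <- counts[as.character(o), base] + 1L
    }
  }
  freq <- counts / pmax(rowSums(counts), 1L)
  freq
}
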