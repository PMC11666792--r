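# Consensus mutation filtering: intersection of per-caller call sets,
# cross-sample exclusion of shared variants, and per-genome burden summaries.
# Variant identity everywhere is the key (contig, 0-based position, ref, alt),
# with indels left-normalised first so representation differences between
# callers cannot cause spurious misses.

#' Consensus policy
#'
#' @param snv_required_callers callers that must all report an SNV for it to
#'   be retained (default: every caller present in the input).
#' @param indel_required_callers callers that must all report an indel
#'   (default: the indel-capable pair `strelka2` + `varscan2` when present,
#'   otherwise all callers).
#' @param cross_sample_max maximum number of samples a variant may appear in
#'   before it is removed everywhere (default 1).
#' @param position_only if TRUE, cross-sample matching ignores alleles and
#'   uses (contig, position) only.
#' @export
consensus_policy <- function(snv_required_callers = NULL,
                             indel_required_callers = NULL,
                             cross_sample_max = 1L,
                             position_only = FALSE) {
  structure(list(snv_required_callers = snv_required_callers,
                 indel_required_callers = indel_required_callers,
                 cross_sample_max = as.integer(cross_sample_max),
                 position_only = position_only),
            class = "oxmut_policy")
}

#' Variant identity key
#' @keywords internal
variant_key <- function(calls, position_only = FALSE) {
  if (position_only) paste(calls$contig, calls$pos)
  else paste(calls$contig, calls$pos, calls$ref, calls$alt)
}

#' Left-normalise indel calls
#'
#' Shifts each indel as far left as the flanking sequence allows and trims
#' shared prefix/suffix bases down to the usual single-anchor VCF form, so
#' equivalent representations from different callers produce identical keys.
#' SNVs pass through unchanged.
#'
#' @param calls data frame with `contig`, `pos` (0-based), `ref`, `alt`.
#' @param reference reference sequences (required when any indel is present).
#' @export
left_normalize <- function(calls, reference) {
  if (nrow(calls) == 0) return(calls)
  seqs <- as_reference(reference)
  is_indel <- nchar(calls$ref) != nchar(calls$alt)
  for (i in which(is_indel)) {
    ref <- calls$ref[i]; alt <- calls$alt[i]; pos <- calls$pos[i]
    ctg <- seqs[[calls$contig[i]]]
    repeat {
      nr <- nchar(ref); na <- nchar(alt)
      if (nr > 0 && na > 0 &&
          substr(ref, nr, nr) == substr(alt, na, na)) {
        if (nr > 1 && na > 1) {
          ref <- substr(ref, 1, nr - 1); alt <- substr(alt, 1, na - 1)
        } else if (pos > 0) {
          # extend left with the reference base, then drop the shared tail
          b <- substr(ctg, pos, pos)  # base at 0-based pos-1
          ref <- paste0(b, substr(ref, 1, nr - 1))
          alt <- paste0(b, substr(alt, 1, na - 1))
          pos <- pos - 1L
        } else break
      } else break
    }
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, 1, 1) == substr(alt, 1, 1)) {
      ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt))
      pos <- pos + 1L
    }
    calls$ref[i] <- ref; calls$alt[i] <- alt; calls$pos[i] <- pos
  }
  calls
}

#' Intersect per-caller call sets into the consensus for one sample
#'
#' SNVs are retained when their key is present in every caller of
#' `snv_required_callers`; indels when present in every caller of
#' `indel_required_callers` (keys compared after [left_normalize()] when a
#' reference is supplied). The output records the union of supporting
#' callers per variant.
#'
#' @param callsets named list: caller -> call data frame (one sample).
#' @param policy a [consensus_policy()].
#' @param reference reference sequences for indel normalisation (optional
#'   when the call sets contain no indels).
#' @return consensus call data frame with a `callers` column.
#' @export
consensus_intersect <- function(callsets, policy = consensus_policy(),
                                reference = NULL) {
  snv_req <- policy$snv_required_callers
  if (is.null(snv_req)) snv_req <- names(callsets)
  indel_req <- policy$indel_required_callers
  if (is.null(indel_req)) {
    indel_req <- intersect(c("strelka2", "varscan2"), names(callsets))
    if (length(indel_req) == 0) indel_req <- names(callsets)
  }
  missing <- setdiff(union(snv_req, indel_req), names(callsets))
  if (length(missing))
    stop("policy requires caller(s) absent from input: ",
         paste(missing, collapse = ", "))

  norm <- lapply(callsets, function(cs) {
    cs$class <- variant_class(cs$ref, cs$alt)
    if (any(cs$class %in% c("INS", "DEL"))) {
      if (is.null(reference))
        stop("reference required to left-normalise indel calls")
      cs <- left_normalize(cs, reference)
    }
    cs$key <- variant_key(cs)
    cs
  })
  keys_of <- function(caller, classes) {
    cs <- norm[[caller]]
    cs$key[cs$class %in% classes]
  }
  snv_keep <- Reduce(intersect, lapply(snv_req, keys_of, classes = "SNV"))
  indel_keep <- Reduce(intersect,
                       lapply(indel_req, keys_of, classes = c("INS", "DEL")))
  pool <- do.call(rbind, lapply(names(norm), function(cl) {
    cs <- norm[[cl]]; cs$caller <- rep(cl, nrow(cs)); cs
  }))
  keep <- pool[pool$key %in% c(snv_keep, indel_keep), , drop = FALSE]
  if (nrow(keep) == 0) {
    out <- keep[, setdiff(names(keep), "caller"), drop = FALSE]
    out$callers <- character(0)
    rownames(out) <- NULL
    return(out)
  }
  supp <- tapply(keep$caller, keep$key, function(x)
    paste(sort(unique(x)), collapse = ","))
  out <- keep[!duplicated(keep$key), , drop = FALSE]
  out$callers <- unname(supp[out$key])
  out$caller <- NULL
  out <- out[order(out$contig, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove variants shared across samples
#'
#' Any key present in more than `cross_sample_max` samples is removed from
#' every sample (shared calls are far more likely germline leakage or
#' recurrent artifacts than independent somatic hits). Removal counts are
#' attached as attribute `removed`.
#'
#' @param samples named list: sample -> call data frame.
#' @param policy a [consensus_policy()].
#' @return named list of filtered call data frames.
#' @export
remove_cross_sample <- function(samples, policy = consensus_policy()) {
  keys <- lapply(samples, variant_key, position_only = policy$position_only)
  n_samples_with <- table(unlist(lapply(keys, unique)))
  shared <- names(n_samples_with)[n_samples_with > policy$cross_sample_max]
  removed <- integer(length(samples))
  names(removed) <- names(samples)
  out <- samples
  for (s in names(samples)) {
    drop <- keys[[s]] %in% shared
    removed[[s]] <- sum(drop)
    out[[s]] <- samples[[s]][!drop, , drop = FALSE]
    rownames(out[[s]]) <- NULL
  }
  attr(out, "removed") <- removed
  out
}

#' Per-genome mutation burden and group fold changes
#'
#' Counts SNVs and indels per sample, takes group medians, and reports the
#' treated/untreated median fold change per class with an optional two-sided
#' Mann-Whitney U comparison.
#'
#' @param samples named list: sample -> call data frame (with `class`).
#' @param grouping named list: group -> character vector of sample names;
#'   fold changes are `grouping[[1]]` over `grouping[[2]]`.
#' @return list with `per_sample` counts, `medians`, `fold_change` (NA and
#'   flagged when the denominator median is 0), and `mann_whitney_p`.
#' @export
mutation_burden <- function(samples, grouping) {
  per_sample <- do.call(rbind, lapply(names(samples), function(s) {
    cls <- variant_class(samples[[s]]$ref, samples[[s]]$alt)
    data.frame(sample = s, snv = sum(cls == "SNV"),
               indel = sum(cls %in% c("INS", "DEL")),
               stringsAsFactors = FALSE)
  }))
  g1 <- grouping[[1]]; g2 <- grouping[[2]]
  med <- function(group, cls) stats::median(per_sample[[cls]][
    per_sample$sample %in% group])
  medians <- data.frame(
    group = names(grouping),
    snv = c(med(g1, "snv"), med(g2, "snv")),
    indel = c(med(g1, "indel"), med(g2, "indel")))
  fold <- function(cls) {
    if (medians[[cls]][2] == 0) NA_real_
    else medians[[cls]][1] / medians[[cls]][2]
  }
  mw <- function(cls) {
    x <- per_sample[[cls]][per_sample$sample %in% g1]
    y <- per_sample[[cls]][per_sample$sample %in% g2]
    if (length(x) < 1 || length(y) < 1) return(NA_real_)
    if (length(x) == 1 && length(y) == 1) return(NA_real_)
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }
  list(per_sample = per_sample, medians = medians,
       fold_change = c(snv = fold("snv"), indel = fold("indel")),
       fold_undefined = c(snv = medians$snv[2] == 0,
                          indel = medians$indel[2] == 0),
       mann_whitney_p = c(snv = mw("snv"), indel = mw("indel")))
}
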