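# Replication and transcription strand asymmetry of G-based events.
#
# Conventions (stated explicitly because published tools keep them
# internal): an event's strand is the strand carrying the G (top-strand G =
# "+", top-strand C = "-"). In a right-replicating domain (fork moving
# rightward) the top strand is the lagging-strand template and the bottom
# strand the leading-strand template; left-replicating domains flip. For a
# gene on strand s, a G on strand s lies on the non-transcribed (coding)
# strand; a G on the opposite strand lies on the transcribed (template)
# strand. Rates are events per Mb of strand-specific guanine.

#' Assign events to leading/lagging replication templates
#'
#' @param events data frame with `contig`, `pos`, `strand` (G strand).
#' @param repl_map data frame `contig`, `start`, `end`, `direction`
#'   (left/right), non-overlapping.
#' @return character vector `leading` / `lagging` / `unassigned`.
#' @export
assign_replication_strand <- function(events, repl_map) {
  out <- rep("unassigned", nrow(events))
  for (ctg in unique(events$contig)) {
    sel <- events$contig == ctg
    rp <- repl_map[repl_map$contig == ctg, ]
    rp <- rp[order(rp$start), ]
    if (nrow(rp) == 0) next
    dir <- .interval_lookup(events$pos[sel], rp$start, rp$end,
                            rp$direction, NA_character_)
    s <- events$strand[sel]
    out[sel] <- ifelse(is.na(dir), "unassigned",
      ifelse((dir == "right") == (s == "+"), "lagging", "leading"))
  }
  out
}

# merge overlapping same-strand gene intervals; regions covered by both
# strands are marked ambiguous
.gene_strand_masks <- function(genes, ctg) {
  g <- genes[genes$contig == ctg, ]
  merge_iv <- function(gg) {
    if (nrow(gg) == 0) return(gg[, c("start", "end")])
    ir <- IRanges::reduce(IRanges::IRanges(gg$start + 1L, gg$end))
    data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  }
  list(plus = merge_iv(g[g$strand == "+", ]),
       minus = merge_iv(g[g$strand == "-", ]))
}

#' Assign events to transcribed/non-transcribed gene strands
#'
#' Same-strand overlapping genes are merged; events inside opposite-strand
#' overlaps are excluded as `ambiguous` (and counted); events outside genes
#' are `intergenic`.
#'
#' @param events data frame with `contig`, `pos`, `strand` (G strand).
#' @param genes data frame `contig`, `start`, `end`, `strand`.
#' @return character vector `transcribed` / `non_transcribed` /
#'   `intergenic` / `ambiguous`.
#' @export
assign_transcription_strand <- function(events, genes) {
  out <- rep("intergenic", nrow(events))
  for (ctg in unique(events$contig)) {
    sel <- which(events$contig == ctg)
    m <- .gene_strand_masks(genes, ctg)
    inside <- function(pos, iv) {
      if (nrow(iv) == 0) return(rep(FALSE, length(pos)))
      !is.na(.interval_lookup(pos, iv$start, iv$end,
                              seq_len(nrow(iv)), NA_integer_))
    }
    pos <- events$pos[sel]
    in_p <- inside(pos, m$plus); in_m <- inside(pos, m$minus)
    s <- events$strand[sel]
    lab <- rep("intergenic", length(pos))
    lab[in_p & in_m] <- "ambiguous"
    only_p <- in_p & !in_m; only_m <- in_m & !in_p
    lab[only_p] <- ifelse(s[only_p] == "+", "non_transcribed", "transcribed")
    lab[only_m] <- ifelse(s[only_m] == "-", "non_transcribed", "transcribed")
    out[sel] <- lab
  }
  out
}

# cumulative G/C counts per contig for fast strand-specific G content
.gc_cumsums <- function(reference) {
  seqs <- as_reference(reference)
  lapply(seqs, function(s) {
    codes <- encode_bases(s)
    list(G = cumsum(codes == 2L), C = cumsum(codes == 1L))
  })
}

# guanine bp on top (+) and bottom (-) strands within half-open intervals
.strand_g_in <- function(cums, iv) {
  if (nrow(iv) == 0) return(c(top = 0, bottom = 0))
  gi <- function(v, s, e) sum(v[e]) - sum(ifelse(s > 0, v[pmax(s, 1L)], 0))
  c(top = gi(cums$G, iv$start, iv$end),
    bottom = gi(cums$C, iv$start, iv$end))
}

#' Strand-specific guanine content for a strand dichotomy
#'
#' @param reference reference sequences.
#' @param tracks either a replication map (`direction` column) or a gene set
#'   (`strand` column).
#' @param mode `"replication"` or `"transcription"`.
#' @return named numeric: G bp on each template/strand class
#'   (`leading`/`lagging` or `transcribed`/`non_transcribed`).
#' @export
strand_g_content <- function(reference, tracks, mode = c("replication",
                                                         "transcription")) {
  mode <- match.arg(mode)
  cums <- .gc_cumsums(reference)
  if (mode == "replication") {
    out <- c(leading = 0, lagging = 0)
    for (ctg in intersect(unique(tracks$contig), names(cums))) {
      tr <- tracks[tracks$contig == ctg, ]
      for (d in c("left", "right")) {
        g <- .strand_g_in(cums[[ctg]], tr[tr$direction == d, ])
        if (d == "right") {
          # top strand = lagging template in right-replicating domains
          out["lagging"] <- out["lagging"] + g[["top"]]
          out["leading"] <- out["leading"] + g[["bottom"]]
        } else {
          out["leading"] <- out["leading"] + g[["top"]]
          out["lagging"] <- out["lagging"] + g[["bottom"]]
        }
      }
    }
  } else {
    out <- c(transcribed = 0, non_transcribed = 0)
    for (ctg in intersect(unique(tracks$contig), names(cums))) {
      m <- .gene_strand_masks(tracks, ctg)
      # drop opposite-strand overlaps (ambiguous regions)
      if (nrow(m$plus) && nrow(m$minus)) {
        ovl <- IRanges::intersect(
          IRanges::IRanges(m$plus$start + 1L, m$plus$end),
          IRanges::IRanges(m$minus$start + 1L, m$minus$end))
        strip <- function(iv) {
          ir <- IRanges::setdiff(IRanges::IRanges(iv$start + 1L, iv$end), ovl)
          data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
        }
        m$plus <- strip(m$plus); m$minus <- strip(m$minus)
      }
      gp <- .strand_g_in(cums[[ctg]], m$plus)
      gm <- .strand_g_in(cums[[ctg]], m$minus)
      # + gene: non-transcribed strand is the top strand
      out["non_transcribed"] <- out["non_transcribed"] + gp[["top"]] +
        gm[["bottom"]]
      out["transcribed"] <- out["transcribed"] + gp[["bottom"]] + gm[["top"]]
    }
  }
  out
}

#' Per-strand normalised rates and log2 ratio
#'
#' @param counts named length-2 event counts (numerator class first).
#' @param g_bp named length-2 guanine bp matching `counts` names.
#' @return data frame with per-strand counts, G bp, rates (events/Mb of G)
#'   and the log2(first/second) ratio.
#' @export
strand_rates <- function(counts, g_bp) {
  if (any(g_bp <= 0)) stop("zero guanine content on a strand")
  g_bp <- g_bp[names(counts)]
  rates <- counts / g_bp * 1e6
  data.frame(strand = names(counts), count = as.numeric(counts),
             g_bp = as.numeric(g_bp), rate_per_mb = as.numeric(rates),
             log2_ratio = log2(rates[[1]] / rates[[2]]),
             stringsAsFactors = FALSE)
}

#' Test strand asymmetry
#'
#' With >= 2 samples: two-sided paired t-test on per-sample normalised rates
#' (strand A vs strand B). With a single sample: two-sided chi-square of the
#' two counts against expected proportions given by strand G content
#' (df = 1, no continuity correction).
#'
#' @param counts_a,counts_b per-sample event counts on the two strands
#'   (equal-length vectors; length 1 triggers the chi-square path).
#' @param g_a,g_b guanine bp on the two strands.
#' @return list: `method`, `statistic`, `p_value`, `n_samples`, `df` (chi-
#'   square only).
#' @export
asymmetry_test <- function(counts_a, counts_b, g_a, g_b) {
  n <- length(counts_a)
  stopifnot(length(counts_b) == n)
  if (n >= 2) {
    ra <- counts_a / g_a * 1e6
    rb <- counts_b / g_b * 1e6
    if (all(ra == rb)) {
      return(list(method = "paired_t", statistic = 0, p_value = 1,
                  n_samples = n))
    }
    tt <- stats::t.test(ra, rb, paired = TRUE)
    list(method = "paired_t", statistic = unname(tt$statistic),
         p_value = tt$p.value, n_samples = n)
  } else {
    tot <- counts_a + counts_b
    if (tot == 0) return(list(method = "chisq", statistic = NA_real_,
                              p_value = NA_real_, n_samples = 1L, df = 1L))
    p <- c(g_a, g_b) / (g_a + g_b)
    ct <- suppressWarnings(stats::chisq.test(c(counts_a, counts_b), p = p))
    list(method = "chisq", statistic = unname(ct$statistic),
         p_value = ct$p.value, n_samples = 1L, df = 1L)
  }
}

#' Full strand-asymmetry analysis per mutation class
#'
#' Assigns events to the strand dichotomy, computes per-class (G>T, G>C,
#' G>A, or a single `lesion` class) normalised rates and log2 ratios, and
#' runs the appropriate test across samples. The numerator strand follows
#' the display convention: leading (replication) and non-transcribed
#' (transcription), configurable via `numerator`.
#'
#' @param events data frame with `contig`, `pos`, `strand`, optional `class`
#'   and `sample_id`.
#' @param reference reference sequences.
#' @param tracks replication map or gene set (see [strand_g_content()]).
#' @param mode `"replication"` or `"transcription"`.
#' @param numerator numerator strand label for the log2 ratio.
#' @return data frame: one row per mutation class with per-strand counts,
#'   rates, `log2_ratio`, `statistic`, `p_value`, `method`; attribute
#'   `assignment_counts` records the assignment tally (conservation:
#'   assigned + unassigned classes = total events).
#' @export
strand_asymmetry <- function(events, reference, tracks,
                             mode = c("replication", "transcription"),
                             numerator = NULL) {
  mode <- match.arg(mode)
  assigned <- if (mode == "replication")
    assign_replication_strand(events, tracks)
  else assign_transcription_strand(events, tracks)
  pair <- if (mode == "replication") c("leading", "lagging")
  else c("non_transcribed", "transcribed")
  if (!is.null(numerator)) pair <- c(numerator, setdiff(pair, numerator))
  g_bp <- strand_g_content(reference, tracks, mode)
  cls <- if ("class" %in% names(events)) events$class
  else rep("lesion", nrow(events))
  samp <- if ("sample_id" %in% names(events)) events$sample_id
  else rep("all", nrow(events))
  samples <- sort(unique(samp))
  rows <- list()
  for (cl in sort(unique(cls))) {
    ca <- cb <- numeric(length(samples))
    for (k in seq_along(samples)) {
      sel <- cls == cl & samp == samples[k]
      ca[k] <- sum(sel & assigned == pair[1])
      cb[k] <- sum(sel & assigned == pair[2])
    }
    rates <- strand_rates(stats::setNames(c(sum(ca), sum(cb)), pair),
                          g_bp[pair])
    tst <- asymmetry_test(ca, cb, g_bp[[pair[1]]], g_bp[[pair[2]]])
    rows[[cl]] <- data.frame(
      class = cl, strand_a = pair[1], strand_b = pair[2],
      count_a = sum(ca), count_b = sum(cb),
      rate_a = rates$rate_per_mb[1], rate_b = rates$rate_per_mb[2],
      log2_ratio = rates$log2_ratio[1],
      method = tst$method, statistic = tst$statistic,
      p_value = tst$p_value, n_samples = tst$n_samples,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(unname(rows), list(make.row.names = FALSE)))
  attr(out, "assignment_counts") <- table(assigned)
  out
}
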