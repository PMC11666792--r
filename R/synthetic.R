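# Seeded synthetic-data generator. Plants G-centred events on a small genome
# with known trinucleotide bias, chromatin-state rate multipliers,
# rotational/translational periodicity around nucleosome dyads, and
# replication/transcription strand bias, then derives per-caller call sets
# and lesion-capture alignments. Every downstream analysis in the package can
# therefore be checked against recorded ground truth.

CHROMHMM15_STATES <- c(
  "1_Active_Promoter", "2_Weak_Promoter", "3_Poised_Promoter",
  "4_Strong_Enhancer", "5_Strong_Enhancer", "6_Weak_Enhancer",
  "7_Weak_Enhancer", "8_Insulator", "9_Txn_Transition",
  "10_Txn_Elongation", "11_Weak_Txn", "12_Repressed",
  "13_Heterochrom_lo", "14_Repetitive_CNV", "15_Repetitive_CNV"
)

#' Configuration for the synthetic oxidative-mutagenesis study
#'
#' Bundles every tunable of the generator. The defaults are the study
#' conditions used throughout the package's tests: two 2-Mb contigs with
#' uniform base composition, a nucleosome repeat of 192 bp (dyad spacing =
#' translational period), a 10.3 bp rotational period confined to the 147-bp
#' nucleosome core (half-width 73 bp), 150-bp lesion-capture reads, and
#' independent per-caller dropout/false-positive rates.
#'
#' @param seed integer root seed; all outputs are byte-identical under the
#'   same seed (randomness flows through named substreams, one per generator).
#' @param contig_lengths named integer vector of contig sizes (bp), each
#'   >= 10 kb.
#' @param base_composition probabilities for A, C, G, T; must sum to 1.
#' @param dyad_spacing nucleosome repeat length between consecutive dyads (bp).
#' @param n_dyads optional cap on dyads per contig (default: fill the contig).
#' @param nucleosome_halfwidth half of the nucleosome core footprint (bp);
#'   rotational modulation is applied only within this distance of a dyad.
#' @param rotational_period,rotational_amplitude,rotational_phase sinusoidal
#'   modulation of event intensity with dyad offset: period in bp, amplitude
#'   in `[0, 1)`, phase in radians (phase 0 puts intensity peaks at the dyad,
#'   i.e. at histone-proximal positions).
#' @param translational_period,translational_amplitude inter-nucleosome
#'   modulation (bp; amplitude in `[0, 1)`) applied along the whole dyad array.
#' @param state_rate_multipliers named positive factors scaling event
#'   intensity per chromatin state.
#' @param leading_lagging_bias odds factor multiplying intensity at positions
#'   whose G sits on the leading-strand template (given the replication
#'   domain direction); the expected leading/lagging log2 rate ratio is
#'   exactly `log2(leading_lagging_bias)`.
#' @param transcribed_bias odds factor multiplying intensity at gene-body
#'   positions whose G sits on the transcribed (template) strand.
#' @param context_weights named nonnegative weights over the 64
#'   trinucleotides, keyed by the G-strand (strand-specific) context of a
#'   candidate position; only G-centred contexts can ever be used.
#' @param n_events number of events to plant.
#' @param snv_class_probs probabilities of the three G-based substitution
#'   classes `G>T`, `G>C`, `G>A`.
#' @param caller_fn_rate,caller_fp_rate per-caller dropout probability and
#'   spurious-call rate (fraction of truth size), independent across callers.
#' @param read_length lesion-capture read/alignment length (bp).
#' @param state_segment_bp,replication_domain_bp tile sizes of the chromatin
#'   state and replication-direction tracks.
#' @param gene_length_bp,gene_gap_bp gene-body length and intergenic gap of
#'   the synthetic gene annotation (strands alternate).
#' @param n_tf_sites number of transcription-factor site midpoints.
#' @param dyad_margin distance kept free of dyads at contig ends (bp).
#' @return object of class `oxmut_config` (a validated list).
#' @export
synthetic_config <- function(seed = 1L,
                             contig_lengths = c(chrS1 = 2e6, chrS2 = 2e6),
                             base_composition = c(A = .25, C = .25, G = .25, T = .25),
                             dyad_spacing = 192L,
                             n_dyads = NULL,
                             nucleosome_halfwidth = 73L,
                             rotational_period = 10.3,
                             rotational_amplitude = 0,
                             rotational_phase = 0,
                             translational_period = 192,
                             translational_amplitude = 0,
                             state_rate_multipliers = NULL,
                             leading_lagging_bias = 1,
                             transcribed_bias = 1,
                             context_weights = NULL,
                             n_events = 50000L,
                             snv_class_probs = c("G>T" = .9, "G>C" = .05, "G>A" = .05),
                             caller_fn_rate = 0.1,
                             caller_fp_rate = 0.05,
                             read_length = 150L,
                             state_segment_bp = 10000L,
                             replication_domain_bp = 100000L,
                             gene_length_bp = 20000L,
                             gene_gap_bp = 30000L,
                             n_tf_sites = 2000L,
                             dyad_margin = 1000L) {
  if (is.null(state_rate_multipliers)) {
    state_rate_multipliers <- stats::setNames(rep(1, 15), CHROMHMM15_STATES)
  }
  if (is.null(context_weights)) {
    context_weights <- stats::setNames(rep(1, 64), trinucleotides())
  }
  cfg <- list(seed = as.integer(seed), contig_lengths = contig_lengths,
              base_composition = base_composition,
              dyad_spacing = as.integer(dyad_spacing), n_dyads = n_dyads,
              nucleosome_halfwidth = as.integer(nucleosome_halfwidth),
              rotational_period = rotational_period,
              rotational_amplitude = rotational_amplitude,
              rotational_phase = rotational_phase,
              translational_period = translational_period,
              translational_amplitude = translational_amplitude,
              state_rate_multipliers = state_rate_multipliers,
              leading_lagging_bias = leading_lagging_bias,
              transcribed_bias = transcribed_bias,
              context_weights = context_weights,
              n_events = as.integer(n_events),
              snv_class_probs = snv_class_probs,
              caller_fn_rate = caller_fn_rate,
              caller_fp_rate = caller_fp_rate,
              read_length = as.integer(read_length),
              state_segment_bp = as.integer(state_segment_bp),
              replication_domain_bp = as.integer(replication_domain_bp),
              gene_length_bp = as.integer(gene_length_bp),
              gene_gap_bp = as.integer(gene_gap_bp),
              n_tf_sites = as.integer(n_tf_sites),
              dyad_margin = as.integer(dyad_margin))
  validate_config(cfg)
  class(cfg) <- "oxmut_config"
  cfg
}

validate_config <- function(cfg) {
  if (any(cfg$contig_lengths <= 0)) stop("contig lengths must be positive")
  if (any(cfg$contig_lengths < 10000)) stop("contig lengths must be >= 10 kb")
  if (is.null(names(cfg$contig_lengths))) stop("contig_lengths must be named")
  if (abs(sum(cfg$base_composition) - 1) > 1e-9)
    stop("base_composition must sum to 1")
  if (cfg$rotational_amplitude < 0 || cfg$rotational_amplitude >= 1 ||
      cfg$translational_amplitude < 0 || cfg$translational_amplitude >= 1)
    stop("amplitudes must lie in [0, 1)")
  if (any(cfg$context_weights < 0) || all(cfg$context_weights == 0))
    stop("context weights must be nonnegative with at least one positive")
  if (any(cfg$state_rate_multipliers <= 0))
    stop("state rate multipliers must be positive")
  if (cfg$caller_fn_rate < 0 || cfg$caller_fn_rate > 1 ||
      cfg$caller_fp_rate < 0 || cfg$caller_fp_rate > 1)
    stop("caller error rates must lie in [0, 1]")
  invisible(cfg)
}

#' Generate the synthetic reference genome
#'
#' Samples each contig i.i.d. from `base_composition` under the
#' `reference/<contig>` substream of the root seed.
#'
#' @param config an [synthetic_config()] object.
#' @return named character vector of uppercase A/C/G/T sequences.
#' @export
make_reference <- function(config) {
  validate_config(config)
  out <- vapply(names(config$contig_lengths), function(ctg) {
    n <- as.integer(config$contig_lengths[[ctg]])
    with_substream(config$seed, paste0("reference/", ctg), {
      paste(sample(DNA_BASES, n, replace = TRUE,
                   prob = config$base_composition), collapse = "")
    })
  }, character(1))
  out
}

#' Generate annotation tracks matching a synthetic reference
#'
#' Produces the five interval tracks the downstream analyses consume:
#' nucleosome dyad positions (regular `dyad_spacing` grid), a chromatin-state
#' segmentation tiling each contig without overlap, alternating left/right
#' replication-direction domains, stranded gene bodies, and TF-site
#' midpoints.
#'
#' @param config an [synthetic_config()] object.
#' @param reference output of [make_reference()] (used for contig bounds).
#' @return list with data frames `dyads` (contig, pos), `states` (contig,
#'   start, end, state), `replication` (contig, start, end, direction),
#'   `genes` (contig, start, end, strand, name), `tf_sites` (contig, pos).
#'   All coordinates 0-based half-open.
#' @export
make_annotation_fixtures <- function(config, reference) {
  lens <- reference_lengths(reference)
  dyads <- states <- repl <- genes <- tfs <- list()
  for (ctg in names(lens)) {
    len <- lens[[ctg]]
    pos <- seq.int(config$dyad_margin, len - config$dyad_margin - 1L,
                   by = config$dyad_spacing)
    if (!is.null(config$n_dyads)) pos <- utils::head(pos, config$n_dyads)
    dyads[[ctg]] <- data.frame(contig = ctg, pos = as.integer(pos))

    starts <- seq.int(0L, len - 1L, by = config$state_segment_bp)
    ends <- pmin(starts + config$state_segment_bp, len)
    lab <- with_substream(config$seed, paste0("states/", ctg), {
      sample(names(config$state_rate_multipliers), length(starts), replace = TRUE)
    })
    states[[ctg]] <- data.frame(contig = ctg, start = starts, end = ends,
                                state = lab)

    rs <- seq.int(0L, len - 1L, by = config$replication_domain_bp)
    re <- pmin(rs + config$replication_domain_bp, len)
    dir <- rep(c("right", "left"), length.out = length(rs))
    repl[[ctg]] <- data.frame(contig = ctg, start = rs, end = re,
                              direction = dir)

    unit <- config$gene_length_bp + config$gene_gap_bp
    gs <- seq.int(config$gene_gap_bp %/% 2L, len - config$gene_length_bp - 1L,
                  by = unit)
    genes[[ctg]] <- data.frame(contig = ctg, start = gs,
                               end = gs + config$gene_length_bp,
                               strand = rep(c("+", "-"), length.out = length(gs)),
                               name = paste0(ctg, "_gene", seq_along(gs)))

    n_tf <- max(1L, round(config$n_tf_sites * as.numeric(len) /
                            sum(as.numeric(lens))))
    tp <- with_substream(config$seed, paste0("tf/", ctg), {
      sort(sample.int(len - 2000L, n_tf) + 1000L)
    })
    tfs[[ctg]] <- data.frame(contig = ctg, pos = as.integer(tp))
  }
  bind <- function(l) do.call(rbind, c(unname(l), list(make.row.names = FALSE)))
  out <- list(dyads = bind(dyads), states = bind(states),
              replication = bind(repl), genes = bind(genes),
              tf_sites = bind(tfs))
  for (tr in c("states", "replication", "genes")) {
    bad <- out[[tr]]$end > lens[out[[tr]]$contig]
    if (any(bad)) stop("generated ", tr, " track exceeds contig bounds")
  }
  out
}

# Per-position signed distance to the nearest dyad of a sorted dyad vector
.nearest_dyad_offset <- function(pos, dyads) {
  idx <- findInterval(pos, dyads)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(dyads))
  d_lo <- pos - dyads[lo]
  d_hi <- pos - dyads[hi]
  use_hi <- abs(d_hi) < abs(d_lo)
  d_lo[use_hi] <- d_hi[use_hi]
  d_lo
}

# Per-position value from a half-open interval track (single contig, sorted,
# non-overlapping); positions outside all intervals get `fill`.
.interval_lookup <- function(pos, starts, ends, values, fill) {
  idx <- findInterval(pos, starts)
  ok <- idx >= 1L & pos < ends[pmax(idx, 1L)]
  out <- rep(fill, length(pos))
  out[ok] <- values[idx[ok]]
  out
}

#' Plant G-centred events with known latent structure
#'
#' Samples `n_events` distinct (contig, position, strand) sites, restricted
#' to positions whose strand-specific base is G, from the per-position
#' intensity
#' \deqn{\lambda(p) = m_{state}(p) \cdot w_{ctx}(p) \cdot
#'   [1 + A_t \cos(2\pi d(p)/P_t)] \cdot
#'   [1 + A_r \cos(2\pi d(p)/P_r + \phi)] \cdot b_{repl}(p) \cdot b_{tx}(p)}
#' where \eqn{d(p)} is the signed offset to the nearest dyad (the rotational
#' factor applies only within the nucleosome half-width) and the strand-bias
#' factors apply to leading-template / transcribed-strand guanines. Sampling
#' consists of independent multinomial draws from the intensity, so a site
#' can recur; derived call sets deduplicate keys.
#'
#' @param config an [synthetic_config()] object.
#' @param reference output of [make_reference()].
#' @param tracks output of [make_annotation_fixtures()].
#' @return data frame of events with recorded latent truth: `contig`, `pos`
#'   (0-based), `strand` (strand carrying the G), `class` (`G>T`/`G>C`/`G>A`),
#'   `ref`/`alt` (top-strand alleles), `context` (top-strand trinucleotide),
#'   `dyad_offset`, `nucleosomal`, `state`, `repl_strand`, `tx_strand`,
#'   `sample_id`.
#' @export
plant_events <- function(config, reference, tracks, sample_id = "S1") {
  seqs <- as_reference(reference)
  w <- config$context_weights[trinucleotides()]
  w[is.na(w)] <- 0
  parts <- list()
  for (ctg in names(seqs)) {
    codes <- encode_bases(seqs[[ctg]])
    n <- length(codes)
    ctx <- context_ids(codes)
    pos <- seq_len(n) - 1L  # 0-based

    dy <- tracks$dyads$pos[tracks$dyads$contig == ctg]
    d <- .nearest_dyad_offset(pos, dy)
    f_t <- 1 + config$translational_amplitude *
      cos(2 * pi * d / config$translational_period)
    f_r <- rep(1, n)
    core <- abs(d) <= config$nucleosome_halfwidth
    f_r[core] <- 1 + config$rotational_amplitude *
      cos(2 * pi * d[core] / config$rotational_period + config$rotational_phase)

    st <- tracks$states[tracks$states$contig == ctg, ]
    m_state <- .interval_lookup(pos, st$start, st$end,
                                unname(config$state_rate_multipliers[st$state]), 1)

    rp <- tracks$replication[tracks$replication$contig == ctg, ]
    dir <- .interval_lookup(pos, rp$start, rp$end,
                            match(rp$direction, c("left", "right")), NA_integer_)
    # rightward fork: top strand is the lagging template, bottom is leading;
    # leftward fork flips. The bias multiplies leading-template guanines.
    b <- config$leading_lagging_bias
    repl_plus <- rep(1, n); repl_plus[!is.na(dir) & dir == 1L] <- b
    repl_minus <- rep(1, n); repl_minus[!is.na(dir) & dir == 2L] <- b

    gn <- tracks$genes[tracks$genes$contig == ctg, ]
    gstr <- .interval_lookup(pos, gn$start, gn$end,
                             match(gn$strand, c("+", "-")), NA_integer_)
    tb <- config$transcribed_bias
    # G on the strand opposite the gene = transcribed (template) strand
    tx_plus <- rep(1, n); tx_plus[!is.na(gstr) & gstr == 2L] <- tb
    tx_minus <- rep(1, n); tx_minus[!is.na(gstr) & gstr == 1L] <- tb

    base_int <- m_state * f_t * f_r
    w65 <- c(unname(w), 0)  # slot 65 for unknown contexts
    ctx65 <- ctx; ctx65[is.na(ctx65)] <- 65L
    ctxw_plus <- w65[ctx65]
    ctxw_minus <- w65[c(.revcomp_ctx_lut, 65L)[ctx65]]
    is_g <- !is.na(codes) & codes == 2L
    is_c <- !is.na(codes) & codes == 1L
    lam_plus <- as.numeric(is_g) * ctxw_plus * base_int *
      repl_plus * tx_plus
    lam_minus <- as.numeric(is_c) * ctxw_minus * base_int *
      repl_minus * tx_minus

    parts[[ctg]] <- list(pos = pos, lam_plus = lam_plus,
                         lam_minus = lam_minus, d = d, st = st,
                         dir = dir, gstr = gstr, ctx = ctx)
  }

  lam_all <- unlist(lapply(parts, function(p) c(p$lam_plus, p$lam_minus)),
                    use.names = FALSE)
  if (all(lam_all == 0)) stop("all-zero event intensity; nothing to sample")
  # multinomial sampling from the intensity (events are independent draws,
  # so a site can recur; caller-level derivations deduplicate keys)
  cum <- cumsum(lam_all)
  take <- with_substream(config$seed, "events", {
    findInterval(stats::runif(config$n_events) * cum[length(cum)], cum) + 1L
  })
  # guard the measure-zero case of a draw landing exactly on a boundary of a
  # zero-intensity slot
  while (any(lam_all[take] == 0)) take[lam_all[take] == 0] <-
    take[lam_all[take] == 0] + 1L

  # map flat indices back to (contig, pos, strand)
  sizes <- vapply(parts, function(p) length(p$pos), integer(1))
  block_start <- cumsum(c(0L, 2L * sizes))[seq_along(sizes)]
  blk <- findInterval(take - 1L, block_start)
  ctgs <- names(parts)[blk]
  within_blk <- take - block_start[blk]  # 1 .. 2*size
  strand <- ifelse(within_blk <= sizes[blk], "+", "-")
  posidx <- ifelse(within_blk <= sizes[blk], within_blk,
                   within_blk - sizes[blk])

  cls <- with_substream(config$seed, "classes", {
    sample(names(config$snv_class_probs), config$n_events, replace = TRUE,
           prob = config$snv_class_probs)
  })

  pos0 <- integer(config$n_events)
  dyad_offset <- integer(config$n_events)
  state <- character(config$n_events)
  dirv <- integer(config$n_events)
  gstrv <- integer(config$n_events)
  ctxid <- integer(config$n_events)
  for (ctg in unique(ctgs)) {
    sel <- ctgs == ctg
    p <- parts[[ctg]]
    ii <- posidx[sel]
    pos0[sel] <- p$pos[ii]
    dyad_offset[sel] <- p$d[ii]
    state[sel] <- .interval_lookup(p$pos[ii], p$st$start, p$st$end,
                                   p$st$state, NA_character_)
    dirv[sel] <- ifelse(is.na(p$dir[ii]), 0L, p$dir[ii])
    gstrv[sel] <- ifelse(is.na(p$gstr[ii]), 0L, p$gstr[ii])
    ctxid[sel] <- p$ctx[ii]
  }

  alt_on_g <- c("G>T" = "T", "G>C" = "C", "G>A" = "A")[cls]
  ref_top <- ifelse(strand == "+", "G", "C")
  alt_top <- ifelse(strand == "+", alt_on_g, comp_base(alt_on_g))
  repl_strand <- ifelse(dirv == 0L, "unassigned",
    ifelse((dirv == 2L) == (strand == "+"), "lagging", "leading"))
  tx_strand <- ifelse(gstrv == 0L, "intergenic",
    ifelse((gstrv == 1L) == (strand == "+"), "non_transcribed", "transcribed"))

  res <- data.frame(contig = ctgs, pos = pos0, strand = strand, class = cls,
                    ref = ref_top, alt = alt_top,
                    context = trinucleotides()[ctxid],
                    dyad_offset = dyad_offset,
                    nucleosomal = abs(dyad_offset) <= config$nucleosome_halfwidth,
                    state = state, repl_strand = repl_strand,
                    tx_strand = tx_strand, sample_id = sample_id,
                    stringsAsFactors = FALSE)
  res[order(res$contig, res$pos, res$strand), , drop = FALSE]
}

#' Derive per-caller somatic call sets from planted truth
#'
#' Each of the simulated callers independently drops truth variants with
#' probability `caller_fn_rate` and adds `round(caller_fp_rate * n_truth)`
#' spurious calls at G/C sites disjoint from the truth set (and unique within
#' each caller).
#'
#' @param truth event data frame from [plant_events()].
#' @param config an [synthetic_config()] object.
#' @param reference output of [make_reference()].
#' @param callers character vector of caller names (default three SNV
#'   callers).
#' @return named list caller -> call data frame (`contig`, `pos`, `ref`,
#'   `alt`, `class`, `sample_id`).
#' @export
make_call_sets <- function(truth, config, reference,
                           callers = c("strelka2", "varscan2", "somaticsniper")) {
  if (nrow(truth) == 0) stop("truth must be non-empty")
  seqs <- as_reference(reference)
  lens <- reference_lengths(reference)
  truth_key <- paste(truth$contig, truth$pos, truth$ref, truth$alt)
  truth <- truth[!duplicated(truth_key), , drop = FALSE]
  truth_key <- unique(truth_key)
  n_fp <- round(config$caller_fp_rate * nrow(truth))
  out <- list()
  for (cl in callers) {
    kept <- with_substream(config$seed, paste0("caller/", cl, "/fn"), {
      truth[stats::runif(nrow(truth)) >= config$caller_fn_rate, , drop = FALSE]
    })
    calls <- kept[, c("contig", "pos", "ref", "alt", "class", "sample_id")]
    if (n_fp > 0) {
      fp <- with_substream(config$seed, paste0("caller/", cl, "/fp"), {
        acc <- list(); got <- 0L; guard <- 0L
        while (got < n_fp && guard < 50L) {
          guard <- guard + 1L
          ctg <- sample(names(lens), n_fp * 2L, replace = TRUE,
                        prob = lens / sum(lens))
          p0 <- floor(stats::runif(n_fp * 2L, 2, lens[ctg] - 2))
          b <- substr(unlist(seqs[ctg], use.names = FALSE), p0 + 1L, p0 + 1L)
          ok <- b %in% c("G", "C") &
            !(paste(ctg, p0, b, ifelse(b == "G", "T", "A")) %in% truth_key)
          cand <- data.frame(contig = ctg[ok], pos = as.integer(p0[ok]),
                             ref = b[ok],
                             alt = ifelse(b[ok] == "G", "T", "A"),
                             class = "G>T",
                             sample_id = truth$sample_id[1],
                             stringsAsFactors = FALSE)
          acc[[length(acc) + 1L]] <- cand
          got <- got + nrow(cand)
        }
        fp <- do.call(rbind, acc)
        fp <- fp[!duplicated(paste(fp$contig, fp$pos)), , drop = FALSE]
        utils::head(fp, n_fp)
      })
      calls <- rbind(calls, fp)
    }
    calls <- calls[order(calls$contig, calls$pos), , drop = FALSE]
    rownames(calls) <- NULL
    out[[cl]] <- calls
  }
  out
}

#' Build lesion-capture alignment records for planted lesions
#'
#' Emits one full-length (`read_length` M) alignment per lesion: flag 0 reads
#' whose leftmost column is the lesion for plus-strand guanines, and flag 16
#' reads whose rightmost column is the lesion for minus-strand guanines —
#' the convention [reads_to_lesions()] inverts. Optionally appends
#' contaminant records (soft-clipped CIGARs, unmapped flag 4, non-canonical
#' contigs) that the extractor must reject.
#'
#' @param lesion_truth data frame with `contig`, `pos` (0-based), `strand`.
#' @param reference output of [make_reference()].
#' @param config an [synthetic_config()] object (for `read_length`).
#' @param n_contaminants number of contaminant records (cycled over the three
#'   contaminant types).
#' @return data frame of SAM fields (`qname`, `flag`, `rname`, `pos` 1-based,
#'   `mapq`, `cigar`, `seq`) with attribute `skipped` counting lesions too
#'   close to a contig end for a full-length alignment.
#' @export
make_sam_fixture <- function(lesion_truth, reference, config,
                             n_contaminants = 0L) {
  seqs <- as_reference(reference)
  lens <- reference_lengths(reference)
  L <- config$read_length
  skipped <- 0L
  recs <- list()
  for (i in seq_len(nrow(lesion_truth))) {
    ctg <- lesion_truth$contig[i]
    p0 <- lesion_truth$pos[i]
    if (lesion_truth$strand[i] == "+") {
      start0 <- p0
      flag <- 0L
    } else {
      start0 <- p0 - L + 1L
      flag <- 16L
    }
    if (start0 < 0L || start0 + L > lens[[ctg]]) { skipped <- skipped + 1L; next }
    sq <- substr(seqs[[ctg]], start0 + 1L, start0 + L)
    if (flag == 16L) sq <- revcomp(sq)
    recs[[length(recs) + 1L]] <- data.frame(
      qname = sprintf("lesion_%06d", i), flag = flag, rname = ctg,
      pos = start0 + 1L, mapq = 60L, cigar = paste0(L, "M"), seq = sq,
      stringsAsFactors = FALSE)
  }
  if (n_contaminants > 0L) {
    ctg1 <- names(lens)[1]
    types <- rep_len(c("clip", "unmapped", "contig"), n_contaminants)
    for (k in seq_len(n_contaminants)) {
      rec <- switch(types[k],
        clip = data.frame(qname = sprintf("contam_clip_%04d", k), flag = 0L,
                          rname = ctg1, pos = 1000L + 7L * k, mapq = 60L,
                          cigar = paste0(L - 1L, "M1S"),
                          seq = strrep("A", L), stringsAsFactors = FALSE),
        unmapped = data.frame(qname = sprintf("contam_unmap_%04d", k),
                              flag = 4L, rname = "*", pos = 0L, mapq = 0L,
                              cigar = "*", seq = strrep("A", L),
                              stringsAsFactors = FALSE),
        contig = data.frame(qname = sprintf("contam_ctg_%04d", k), flag = 0L,
                            rname = "chrUn_synth", pos = 500L + 3L * k,
                            mapq = 60L, cigar = paste0(L, "M"),
                            seq = strrep("A", L), stringsAsFactors = FALSE))
      recs[[length(recs) + 1L]] <- rec
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(qname = character(), flag = integer(), rname = character(),
               pos = integer(), mapq = integer(), cigar = character(),
               seq = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
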