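# Anchor-relative profiling: trinucleotide-normalised observed/expected
# log2 profiles around nucleosome dyads (or TF midpoints), Savitzky-Golay
# smoothing, least-squares periodogram periodicity estimation, sinusoid
# fitting, and rotational phase classification.
#
# The expected count at offset j is Sum_c f_c * n_c(j), where f_c is the
# genome-wide per-context event frequency (events in context c divided by
# genomic occurrences of c) and n_c(j) counts occurrences of top-strand
# trinucleotide c at offset j across all anchor windows. Observed counts at
# offset j are events falling at that offset of any anchor window (windows
# may overlap; each event counts once per window it falls into).

#' Genome-wide top-strand trinucleotide occurrence counts
#' @return named 64-vector (AAA ... TTT).
#' @export
genome_context_counts <- function(reference) {
  seqs <- as_reference(reference)
  tot <- numeric(64)
  for (ctg in names(seqs)) {
    ctx <- context_ids(encode_bases(seqs[[ctg]]))
    tot <- tot + tabulate(ctx, 64L)
  }
  stats::setNames(tot, trinucleotides())
}

#' Genome-wide per-context event frequencies
#'
#' @param events data frame with `contig`, `pos`; the top-strand context is
#'   recomputed from the reference (all 64 contexts kept distinct, no
#'   pyrimidine collapse).
#' @return list: `genome_counts`, `event_counts` (64-vectors), `f`
#'   (event_counts / genome_counts, 0 where the genome count is 0 and no
#'   events occur; error on the impossible nonzero-events case).
#' @export
event_context_frequency <- function(events, reference) {
  genome_counts <- genome_context_counts(reference)
  seqs <- as_reference(reference)
  ev <- numeric(64)
  for (ctg in unique(events$contig)) {
    pos <- events$pos[events$contig == ctg]
    ctx <- context_ids(encode_bases(seqs[[ctg]]))
    ids <- ctx[pos + 1L]
    ev <- ev + tabulate(ids[!is.na(ids)], 64L)
  }
  if (any(ev > 0 & genome_counts == 0))
    stop("events observed in a context absent from the genome")
  f <- ifelse(genome_counts > 0, ev / genome_counts, 0)
  list(genome_counts = genome_counts,
       event_counts = stats::setNames(ev, trinucleotides()),
       f = stats::setNames(f, trinucleotides()))
}

#' Trinucleotide occurrences at each offset across anchor windows
#'
#' @param anchors data frame with `contig`, `pos` (0-based single
#'   positions).
#' @param reference reference sequences.
#' @param halfwidth window half-width W; offsets run -W..W.
#' @return 64 x (2W+1) matrix of context counts; columns clipped at contig
#'   edges count fewer than the number of anchors. Attribute
#'   `skipped_anchors` counts anchors on unknown contigs.
#' @export
window_context_table <- function(anchors, reference, halfwidth = 500L) {
  seqs <- as_reference(reference)
  lens <- reference_lengths(reference)
  W <- as.integer(halfwidth)
  offsets <- -W:W
  mat <- matrix(0, nrow = 64L, ncol = 2L * W + 1L,
                dimnames = list(trinucleotides(), offsets))
  skipped <- sum(!anchors$contig %in% names(seqs))
  for (ctg in intersect(unique(anchors$contig), names(seqs))) {
    apos <- anchors$pos[anchors$contig == ctg]
    ctx <- context_ids(encode_bases(seqs[[ctg]]))
    n <- lens[[ctg]]
    for (k in seq_along(offsets)) {
      p <- apos + offsets[k]
      p <- p[p >= 0L & p < n]
      ids <- ctx[p + 1L]
      mat[, k] <- mat[, k] + tabulate(ids[!is.na(ids)], 64L)
    }
  }
  attr(mat, "skipped_anchors") <- skipped
  mat
}

#' Observed/expected log2 profile around anchors
#'
#' Computes, per offset j in -W..W: observed event counts O_j over all
#' anchor windows, expected counts E_j = Sum_c f_c n_c(j) from the
#' genome-wide context frequencies, L_j = log2(O_j / E_j) (NA-flagged where
#' O_j or E_j is 0), and a Savitzky-Golay smoothed curve.
#'
#' @param events data frame with `contig`, `pos`.
#' @param anchors data frame with `contig`, `pos` (dyads or TF midpoints).
#' @param reference reference sequences.
#' @param halfwidth window half-width (default 500, i.e. a 1000-bp window).
#' @param freq optional precomputed [event_context_frequency()] result.
#' @param smooth_window,smooth_order Savitzky-Golay parameters (odd window).
#' @param pseudocount added to every O_j (with proportional mass on E_j)
#'   when > 0; default 0 (sparse offsets stay NA-flagged).
#' @return object of class `oxmut_profile`: `offsets`, `observed`,
#'   `expected`, `log2ratio`, `smoothed`, `context_counts`, `freq`,
#'   `n_pairs`.
#' @export
obs_exp_log2 <- function(events, anchors, reference, halfwidth = 500L,
                         freq = NULL, smooth_window = 201L,
                         smooth_order = 3L, pseudocount = 0) {
  if (nrow(anchors) == 0) stop("zero anchors")
  W <- as.integer(halfwidth)
  if (is.null(freq)) freq <- event_context_frequency(events, reference)
  nC <- window_context_table(anchors, reference, W)
  offsets <- -W:W
  obs <- numeric(2L * W + 1L)
  for (ctg in unique(anchors$contig)) {
    apos <- sort(anchors$pos[anchors$contig == ctg])
    epos <- events$pos[events$contig == ctg]
    if (length(epos) == 0 || length(apos) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = epos + 1L, width = 1L),
      IRanges::IRanges(start = apos - W + 1L, end = apos + W + 1L))
    d <- epos[S4Vectors::queryHits(hits)] - apos[S4Vectors::subjectHits(hits)]
    obs <- obs + tabulate(d + W + 1L, 2L * W + 1L)
  }
  expd <- as.vector(freq$f %*% nC)
  if (pseudocount > 0) {
    # add pseudocount to every observed bin and proportional mass to the
    # expected bins so the totals stay matched
    obs <- obs + pseudocount
    expd <- expd + pseudocount * expd / mean(expd[expd > 0])
  }
  l2 <- ifelse(obs > 0 & expd > 0, log2(obs / expd), NA_real_)
  sm <- tryCatch({
    x <- l2
    if (anyNA(x)) {
      idx <- which(!is.na(x))
      if (length(idx) >= 2)
        x <- stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
    }
    savgol_smooth(x, smooth_window, smooth_order)
  }, error = function(e) rep(NA_real_, length(l2)))
  structure(list(offsets = offsets, observed = obs, expected = expd,
                 log2ratio = l2, smoothed = sm, context_counts = nC,
                 freq = freq, n_pairs = sum(obs)),
            class = "oxmut_profile")
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing: each point is replaced by the
#' value at its position of the polynomial of order `polyorder` fitted to
#' the window centred there; endpoints use the polynomial fitted to the
#' nearest full window.
#'
#' @param x numeric vector (no NAs).
#' @param window_bp odd window length (> polyorder).
#' @param polyorder polynomial order.
#' @export
savgol_smooth <- function(x, window_bp = 201L, polyorder = 3L) {
  window_bp <- as.integer(window_bp)
  if (window_bp %% 2L == 0L) stop("smoothing window must be odd")
  if (window_bp <= polyorder) stop("window must exceed polynomial order")
  if (length(x) < window_bp) stop("window exceeds profile length")
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window_bp))
}

# least-squares periodogram power of mean-subtracted y at offsets j for one
# period: fraction of variance explained by cos/sin at that period
.ls_power <- function(y, j, period) {
  w <- 2 * pi / period
  cj <- cos(w * j); sj <- sin(w * j)
  X <- cbind(1, cj, sj)
  fit <- stats::lm.fit(X, y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Periodicity estimation by least-squares periodogram
#'
#' Scans a period grid over `band`, fitting a sinusoid (plus intercept) to
#' the mean-subtracted unsmoothed log2 profile at the non-missing offsets
#' (optionally restricted to `|offset| <= max_offset`), and returns the
#' period maximising explained variance. The regression formulation handles
#' missing offsets naturally (unevenly-sampled data).
#'
#' @param profile an `oxmut_profile`, or a numeric vector with offsets in
#'   `offsets`.
#' @param band numeric length-2 period search band (bp), e.g. `c(8, 15)`
#'   for the rotational band or `c(150, 250)` for the translational band.
#' @param max_offset restrict to offsets with absolute value at most this
#'   (e.g. 73 for the nucleosome core); NULL = full window.
#' @param resolution period grid step (bp); defaults to 0.02 for bands below
#'   20 bp and 0.5 above.
#' @param offsets offsets vector when `profile` is a plain numeric vector.
#' @return list of class `oxmut_period`: `period`, `power` (R^2 at the
#'   peak), `band`, `amplitude`, `phase`, `p_value`, `significant`.
#' @export
estimate_period <- function(profile, band, max_offset = NULL,
                            resolution = NULL, offsets = NULL) {
  if (inherits(profile, "oxmut_profile")) {
    y <- profile$log2ratio; j <- profile$offsets
  } else {
    y <- as.numeric(profile)
    j <- if (!is.null(offsets)) offsets else seq_along(y) - 1L
  }
  keep <- !is.na(y)
  if (!is.null(max_offset)) keep <- keep & abs(j) <= max_offset
  y <- y[keep]; j <- j[keep]
  if (length(y) == 0) stop("all-missing profile")
  span <- diff(range(j)) + 1
  if (span < 3 * band[1])
    stop("restricted offset range holds fewer than 3 cycles of the band")
  if (is.null(resolution)) resolution <- if (band[2] <= 20) 0.02 else 0.5
  if (stats::var(y) < 1e-24) {
    return(structure(list(period = NA_real_, power = 0, band = band,
                          amplitude = 0, phase = NA_real_, p_value = 1,
                          significant = FALSE), class = "oxmut_period"))
  }
  grid <- seq(band[1], band[2], by = resolution)
  pow <- vapply(grid, function(P) .ls_power(y, j, P), numeric(1))
  best <- which.max(pow)
  fit <- fit_sinusoid(y, period = grid[best], offsets = j)
  structure(list(period = grid[best], power = pow[best], band = band,
                 amplitude = fit$amplitude, phase = fit$phase,
                 p_value = fit$p_value,
                 significant = is.finite(fit$p_value) && fit$p_value < 0.01),
            class = "oxmut_period")
}

#' Least-squares sinusoid fit `a + b cos(2 pi j / P + phi)`
#'
#' With `period` fixed the fit is linear (cos/sin regression); with
#' `period = NULL` the period is initialised from [estimate_period()] over
#' `band` and refined by golden-section search on the residual sum of
#' squares.
#'
#' @param profile `oxmut_profile` or numeric vector.
#' @param period fixed period (bp) or NULL for free.
#' @param band,max_offset,offsets as in [estimate_period()].
#' @return list of class `oxmut_sinusoid`: `offset_term` (a), `amplitude`
#'   (b >= 0), `period`, `phase` (radians in `[0, 2pi)`), `p_value`
#'   (F-test of the 2-df sinusoid term), `significant`, `residual`,
#'   `fitted_fun` (function of offset).
#' @export
fit_sinusoid <- function(profile, period = NULL, band = NULL,
                         max_offset = NULL, offsets = NULL) {
  if (inherits(profile, "oxmut_profile")) {
    y <- profile$log2ratio; j <- profile$offsets
  } else {
    y <- as.numeric(profile)
    j <- if (!is.null(offsets)) offsets else seq_along(y) - 1L
  }
  keep <- !is.na(y)
  if (!is.null(max_offset)) keep <- keep & abs(j) <= max_offset
  y <- y[keep]; j <- j[keep]
  if (length(y) < 4) stop("too few points for a sinusoid fit")
  rss_at <- function(P) {
    w <- 2 * pi / P
    X <- cbind(1, cos(w * j), sin(w * j))
    sum(stats::lm.fit(X, y)$residuals^2)
  }
  if (is.null(period)) {
    if (is.null(band)) stop("either period or band must be given")
    est <- estimate_period(y, band, offsets = j)
    opt <- stats::optimize(rss_at, lower = max(band[1], est$period - 0.5),
                           upper = min(band[2], est$period + 0.5))
    period <- opt$minimum
  }
  w <- 2 * pi / period
  X <- cbind(1, cos(w * j), sin(w * j))
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  amplitude <- sqrt(cf[2]^2 + cf[3]^2)
  phase <- atan2(-cf[3], cf[2]) %% (2 * pi)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  df2 <- length(y) - 3
  p_value <- if (df2 > 0 && rss > 0 && tss > rss) {
    Fstat <- ((tss - rss) / 2) / (rss / df2)
    stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  } else if (tss <= rss) 1 else 0
  structure(list(offset_term = unname(cf[1]), amplitude = unname(amplitude),
                 period = period, phase = unname(phase), p_value = p_value,
                 significant = p_value < 0.01, residual = rss,
                 fitted_fun = function(jj)
                   cf[1] + amplitude * cos(2 * pi * jj / period + phase)),
            class = "oxmut_sinusoid")
}

#' Classify offsets by rotational phase
#'
#' Offsets within a quarter period of a fitted intensity maximum are
#' labelled `inward` (histone-proximal), within a quarter period of a
#' minimum `outward` (solvent-exposed); everything else — and every offset
#' when the fitted amplitude is not significant — is `intermediate`.
#'
#' @param offsets integer offsets to label.
#' @param fit an `oxmut_sinusoid` from [fit_sinusoid()].
#' @export
classify_rotational <- function(offsets, fit, tol = 1e-9) {
  if (!isTRUE(fit$significant) || fit$amplitude <= tol)
    return(rep("intermediate", length(offsets)))
  theta <- (2 * pi * offsets / fit$period + fit$phase)
  ct <- cos(theta)
  ifelse(ct > tol, "inward", ifelse(ct < -tol, "outward", "intermediate"))
}

#' Event profile around transcription-factor site midpoints
#'
#' Each event is assigned to its nearest midpoint (ties to the leftmost) and
#' counted at the resulting offset when within the window; a Savitzky-Golay
#' smoothed curve is overlaid. Optional trinucleotide-normalised obs/exp
#' profiling (as for dyads) via `normalize = TRUE`.
#'
#' @param events data frame with `contig`, `pos`.
#' @param tf_sites data frame with `contig`, `pos` (midpoints).
#' @param halfwidth window half-width (bp).
#' @param smooth apply Savitzky-Golay smoothing to the raw counts.
#' @param reference required when `normalize = TRUE`.
#' @return list: `offsets`, `counts`, `smoothed`, and `obs_exp`
#'   (an `oxmut_profile`) when normalised.
#' @export
tf_midpoint_profile <- function(events, tf_sites, halfwidth = 500L,
                                smooth = TRUE, normalize = FALSE,
                                reference = NULL, smooth_window = 201L,
                                smooth_order = 3L) {
  if (nrow(tf_sites) == 0) stop("zero TF sites")
  W <- as.integer(halfwidth)
  offsets <- -W:W
  counts <- numeric(2L * W + 1L)
  for (ctg in unique(events$contig)) {
    sites <- sort(tf_sites$pos[tf_sites$contig == ctg])
    epos <- events$pos[events$contig == ctg]
    if (length(sites) == 0 || length(epos) == 0) next
    idx <- findInterval(epos, sites)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(sites))
    d_lo <- epos - sites[lo]; d_hi <- epos - sites[hi]
    # nearest midpoint, ties to the leftmost site
    d <- ifelse(abs(d_lo) <= abs(d_hi), d_lo, d_hi)
    d <- d[abs(d) <= W]
    counts <- counts + tabulate(d + W + 1L, 2L * W + 1L)
  }
  sm <- if (smooth && length(counts) >= smooth_window)
    savgol_smooth(counts, smooth_window, smooth_order) else NULL
  out <- list(offsets = offsets, counts = counts, smoothed = sm)
  if (normalize) {
    if (is.null(reference)) stop("normalize = TRUE requires a reference")
    out$obs_exp <- obs_exp_log2(events, tf_sites, reference, W,
                                smooth_window = smooth_window,
                                smooth_order = smooth_order)
  }
  out
}
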