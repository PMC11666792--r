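# Chromatin-state density normalisation: events/Mb per state across a
# partitioning segmentation, with broad-group comparisons by
# Bonferroni-corrected paired t-tests.

#' Default mapping of the 15-state chromatin segmentation to 4 broad groups
#'
#' Heterochromatin (repressed/low-signal), promoters, enhancers, transcribed.
#' The insulator state is left unmapped and the two repetitive states are
#' meant to be excluded at load time.
#' @export
chromhmm15_groups <- function() {
  c("1_Active_Promoter" = "promoters", "2_Weak_Promoter" = "promoters",
    "3_Poised_Promoter" = "promoters", "4_Strong_Enhancer" = "enhancers",
    "5_Strong_Enhancer" = "enhancers", "6_Weak_Enhancer" = "enhancers",
    "7_Weak_Enhancer" = "enhancers", "8_Insulator" = NA,
    "9_Txn_Transition" = "transcribed", "10_Txn_Elongation" = "transcribed",
    "11_Weak_Txn" = "transcribed", "12_Repressed" = "heterochromatin",
    "13_Heterochrom_lo" = "heterochromatin",
    "14_Repetitive_CNV" = NA, "15_Repetitive_CNV" = NA)
}

#' Load a chromatin-state segmentation
#'
#' Accepts a BED4 path or an equivalent data frame (`contig`, `start`,
#' `end`, `state`). Intervals must not overlap (segmentations partition).
#' Excluded states are dropped with their footprint reported.
#'
#' @param x path or data frame.
#' @param excluded_states state labels to drop (e.g. repetitive-sequence
#'   states).
#' @return list of class `oxmut_segmentation`: `intervals`, `footprints`
#'   (named bp per retained state), `excluded_footprint`.
#' @export
load_segmentation <- function(x, excluded_states = character()) {
  df <- if (is.character(x)) {
    b <- read_bed(x)
    data.frame(contig = b$contig, start = b$start, end = b$end,
               state = b$name, stringsAsFactors = FALSE)
  } else as.data.frame(x)
  stopifnot(all(c("contig", "start", "end", "state") %in% names(df)))
  df <- df[order(df$contig, df$start), , drop = FALSE]
  for (ctg in unique(df$contig)) {
    s <- df[df$contig == ctg, ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping segmentation intervals on ", ctg,
           "; segmentations must partition")
  }
  drop <- df$state %in% excluded_states
  excluded_footprint <- sum(df$end[drop] - df$start[drop])
  df <- df[!drop, , drop = FALSE]
  rownames(df) <- NULL
  fp <- tapply(df$end - df$start, df$state, sum)
  structure(list(intervals = df,
                 footprints = stats::setNames(as.numeric(fp), names(fp)),
                 excluded_footprint = excluded_footprint),
            class = "oxmut_segmentation")
}

#' Events/Mb per chromatin state
#'
#' Assigns each event position to its (half-open) segmentation interval and
#' reports per-state counts and densities `count / footprint_bp * 1e6`.
#' Events on unsegmented positions or contigs are reported as `unassigned`,
#' never dropped. Per-sample rows are produced when a `sample_id` column is
#' present.
#'
#' @param events data frame with `contig`, `pos` (0-based), optional
#'   `sample_id`.
#' @param segmentation an [load_segmentation()] object.
#' @return data frame: `sample_id`, `state`, `count`, `footprint_bp`,
#'   `density` (events/Mb; NA for the unassigned row and for zero-footprint
#'   states).
#' @export
state_density <- function(events, segmentation) {
  iv <- segmentation$intervals
  st <- rep(NA_character_, nrow(events))
  for (ctg in unique(events$contig)) {
    sel <- events$contig == ctg
    s <- iv[iv$contig == ctg, ]
    if (nrow(s) == 0) next
    st[sel] <- .interval_lookup(events$pos[sel], s$start, s$end, s$state,
                                NA_character_)
  }
  samp <- if ("sample_id" %in% names(events)) events$sample_id
  else rep("all", nrow(events))
  states <- names(segmentation$footprints)
  out <- list()
  for (sm in unique(samp)) {
    cnt <- table(factor(st[samp == sm], levels = states))
    dens <- as.numeric(cnt) / segmentation$footprints[states] * 1e6
    dens[segmentation$footprints[states] == 0] <- NA_real_
    out[[sm]] <- data.frame(
      sample_id = sm,
      state = c(states, "unassigned"),
      count = c(as.integer(cnt), sum(samp == sm & is.na(st))),
      footprint_bp = c(unname(segmentation$footprints[states]), NA),
      density = c(dens, NA), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(unname(out), list(make.row.names = FALSE)))
  res
}

#' Compare broad chromatin groups by paired t-tests
#'
#' Maps states to broad groups, averages per-sample densities within each
#' group, and tests the reference group against every other group with
#' two-sided paired t-tests, Bonferroni-multiplying the p-values by the
#' number of comparisons (capped at 1).
#'
#' @param density_table output of [state_density()] (>= 2 samples for
#'   tests).
#' @param grouping named vector state -> broad group (default
#'   [chromhmm15_groups()]); states mapping to NA are ignored.
#' @param reference_group group compared against all others.
#' @return list: `group_means` (sample x group), `tests` (group, t, raw and
#'   corrected p), `skipped` notice when n < 2 samples.
#' @export
compare_state_groups <- function(density_table,
                                 grouping = chromhmm15_groups(),
                                 reference_group = "heterochromatin") {
  dt <- density_table[density_table$state != "unassigned", , drop = FALSE]
  dt$group <- unname(grouping[dt$state])
  dt <- dt[!is.na(dt$group) & !is.na(dt$density), , drop = FALSE]
  gm <- stats::aggregate(density ~ sample_id + group, data = dt, FUN = mean)
  samples <- sort(unique(gm$sample_id))
  groups <- sort(unique(gm$group))
  wide <- matrix(NA_real_, length(samples), length(groups),
                 dimnames = list(samples, groups))
  wide[cbind(match(gm$sample_id, samples), match(gm$group, groups))] <-
    gm$density
  others <- setdiff(groups, reference_group)
  if (length(samples) < 2) {
    return(list(group_means = wide, tests = NULL,
                skipped = "fewer than 2 samples; tests not run"))
  }
  m <- length(others)
  tests <- do.call(rbind, lapply(others, function(g) {
    x <- wide[, reference_group]; y <- wide[, g]
    if (all(x == y)) {
      data.frame(group = g, t = 0, p_raw = 1, p_bonferroni = 1)
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
      data.frame(group = g, t = unname(tt$statistic), p_raw = tt$p.value,
                 p_bonferroni = min(1, tt$p.value * m))
    }
  }))
  list(group_means = wide, tests = tests, skipped = NULL)
}
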