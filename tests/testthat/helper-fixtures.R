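# Shared fixtures: a lazy cache for the expensive full-scale simulations
# (computed once per test run and reused across files) and small independent
# oracles.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, force(expr), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

# full study-condition simulation: reference + tracks + planted events
run_sim <- function(config) {
  ref <- make_reference(config)
  tracks <- make_annotation_fixtures(config, ref)
  events <- plant_events(config, ref, tracks)
  list(config = config, reference = ref, tracks = tracks, events = events)
}

# small fast config for unit tests
small_config <- function(...) {
  synthetic_config(seed = 11, contig_lengths = c(chrT = 60000L),
                   n_events = 500L, n_tf_sites = 30L, ...)
}

# the 64 trinucleotides in alphabetical order, built independently
trinuc_levels <- function() {
  out <- character(0)
  for (b1 in c("A", "C", "G", "T")) for (b2 in c("A", "C", "G", "T"))
    for (b3 in c("A", "C", "G", "T")) out <- c(out, paste0(b1, b2, b3))
  out
}

# Independent brute-force oracle for the observed/expected log2 profile:
# enumerates every anchor window position and every event, counting contexts
# and events by direct string operations. Deliberately written without any
# of the package's vectorised machinery.
brute_obs_exp <- function(events, anchors, reference, W) {
  seqs <- lapply(reference, toupper)
  tri <- character(0)
  for (b1 in c("A", "C", "G", "T")) for (b2 in c("A", "C", "G", "T"))
    for (b3 in c("A", "C", "G", "T")) tri <- c(tri, paste0(b1, b2, b3))
  ctx_at <- function(ctg, p0) {
    s <- seqs[[ctg]]
    if (p0 < 1 || p0 > nchar(s) - 2) return(NA_character_)
    x <- substr(s, p0, p0 + 2)
    if (grepl("[^ACGT]", x)) NA_character_ else x
  }
  # genome-wide frequencies
  genome <- setNames(numeric(64), tri)
  for (ctg in names(seqs)) {
    for (p0 in 1:(nchar(seqs[[ctg]]) - 2)) {
      cx <- substr(seqs[[ctg]], p0, p0 + 2)
      if (!grepl("[^ACGT]", cx)) genome[cx] <- genome[cx] + 1
    }
  }
  evc <- setNames(numeric(64), tri)
  for (i in seq_len(nrow(events))) {
    cx <- ctx_at(events$contig[i], events$pos[i])
    if (!is.na(cx)) evc[cx] <- evc[cx] + 1
  }
  f <- ifelse(genome > 0, evc / genome, 0)
  offs <- -W:W
  O <- E <- setNames(numeric(length(offs)), offs)
  for (a in seq_len(nrow(anchors))) {
    actg <- anchors$contig[a]; apos <- anchors$pos[a]
    for (j in offs) {
      p <- apos + j
      if (p < 0 || p >= nchar(seqs[[actg]])) next
      O[as.character(j)] <- O[as.character(j)] +
        sum(events$contig == actg & events$pos == p)
      cx <- ctx_at(actg, p)
      if (!is.na(cx)) E[as.character(j)] <- E[as.character(j)] + f[cx]
    }
  }
  L <- ifelse(O > 0 & E > 0, log2(O / E), NA_real_)
  list(O = unname(O), E = unname(E), L = unname(L), f = f)
}
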