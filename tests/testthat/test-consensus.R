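# Consensus filtering: intersection rules, indel key normalisation,
# cross-sample exclusion, and burden summaries.

mk_calls <- function(keys, sample_id = "S1") {
  if (length(keys) == 0) {
    return(data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      sample_id = character(), stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(keys, ":"))
  data.frame(contig = parts[, 1], pos = as.integer(parts[, 2]),
             ref = parts[, 3], alt = parts[, 4], sample_id = sample_id,
             stringsAsFactors = FALSE)
}

test_that("consensus keeps only variants present in every required caller", {
  v1 <- "chrS:100:G:T"; v2 <- "chrS:200:G:T"; v3 <- "chrS:300:C:A"
  callsets <- list(strelka2 = mk_calls(c(v1, v2, v3)),
                   varscan2 = mk_calls(c(v2, v3)),
                   somaticsniper = mk_calls(v3))
  cons <- consensus_intersect(callsets)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$pos, 300)
  expect_equal(cons$callers, "somaticsniper,strelka2,varscan2")
  # 2/3 callers is not enough
  cons2 <- consensus_intersect(list(strelka2 = mk_calls(c(v1, v2)),
                                    varscan2 = mk_calls(c(v1, v2)),
                                    somaticsniper = mk_calls(v2)))
  expect_false(v1 %in% paste(cons2$contig, cons2$pos, cons2$ref, cons2$alt,
                             sep = ":"))
  # caller named in the policy but absent from input
  expect_error(consensus_intersect(
    list(a = mk_calls(v1)),
    consensus_policy(snv_required_callers = c("a", "b"))))
})

test_that("indels intersect on the 2-caller policy after left-normalisation", {
  ref <- c(chrS = paste0("AACC", "TTTT", "GGAACC",
                         strrep("ACGT", 20)))
  # the same 1-bp T deletion in the TTTT run, represented at two positions
  del_a <- data.frame(contig = "chrS", pos = 3L, ref = "CT", alt = "C",
                      sample_id = "S1")   # anchored at the C before the run
  del_b <- data.frame(contig = "chrS", pos = 6L, ref = "TT", alt = "T",
                      sample_id = "S1")   # anchored inside the run
  na <- left_normalize(del_a, ref); nb <- left_normalize(del_b, ref)
  expect_equal(na$pos, nb$pos)
  expect_equal(na$ref, nb$ref)
  expect_equal(na$alt, nb$alt)
  callsets <- list(strelka2 = del_a, varscan2 = del_b,
                   somaticsniper = mk_calls(character(0)))
  cons <- consensus_intersect(callsets, reference = ref)
  expect_equal(nrow(cons), 1)
  expect_equal(sort(strsplit(cons$callers, ",")[[1]]),
               c("strelka2", "varscan2"))
})

test_that("consensus is monotone and contained in every required set", {
  set.seed(42)
  keys <- sprintf("chrS:%d:G:T", sample(1000, 60))
  for (rep in 1:10) {
    sets <- lapply(1:3, function(i) mk_calls(sample(keys, 40)))
    names(sets) <- c("a", "b", "c")
    cons <- consensus_intersect(sets, consensus_policy(
      snv_required_callers = c("a", "b", "c"),
      indel_required_callers = c("a", "b", "c")))
    ck <- paste(cons$contig, cons$pos, cons$ref, cons$alt, sep = ":")
    for (s in sets) {
      sk <- paste(s$contig, s$pos, s$ref, s$alt, sep = ":")
      expect_true(all(ck %in% sk))
    }
    # adding calls never removes a consensus variant
    sets2 <- sets
    sets2$a <- rbind(sets2$a, mk_calls(setdiff(keys, NULL)[1:10]))
    cons2 <- consensus_intersect(sets2, consensus_policy(
      snv_required_callers = c("a", "b", "c"),
      indel_required_callers = c("a", "b", "c")))
    ck2 <- paste(cons2$contig, cons2$pos, cons2$ref, cons2$alt, sep = ":")
    expect_true(all(ck %in% ck2))
  }
})

test_that("cross-sample filter removes shared variants and is idempotent", {
  shared <- "chrS:500:G:T"
  samples <- list(S1 = mk_calls(c(shared, "chrS:1:G:T"), "S1"),
                  S2 = mk_calls(c(shared, "chrS:2:G:T"), "S2"),
                  S3 = mk_calls("chrS:3:G:T", "S3"))
  filt <- remove_cross_sample(samples)
  for (s in names(filt)) {
    expect_false(shared %in% paste(filt[[s]]$contig, filt[[s]]$pos,
                                   filt[[s]]$ref, filt[[s]]$alt, sep = ":"))
  }
  expect_equal(unname(attr(filt, "removed")), c(1L, 1L, 0L))
  # idempotent
  filt2 <- remove_cross_sample(filt)
  expect_equal(lapply(filt2, function(x) x), lapply(filt, function(x) x))
  # identical call sets across 4 samples are emptied
  same <- lapply(1:4, function(i) mk_calls(c("chrS:7:G:T", "chrS:9:C:A")))
  names(same) <- paste0("S", 1:4)
  emptied <- remove_cross_sample(same)
  expect_true(all(vapply(emptied, nrow, integer(1)) == 0))
})

test_that("burden medians and fold changes follow the definitions", {
  mk_n <- function(n, s) mk_calls(sprintf("chrS:%d:G:T", seq_len(n)), s)
  samples <- list(T1 = mk_n(10, "T1"), T2 = mk_n(20, "T2"),
                  U1 = mk_n(1, "U1"), U2 = mk_n(3, "U2"))
  b <- mutation_burden(samples, list(treated = c("T1", "T2"),
                                     untreated = c("U1", "U2")))
  expect_equal(unname(b$fold_change["snv"]), 15 / 2)
  # identical groups give fold change 1
  b2 <- mutation_burden(list(A = mk_n(5, "A"), B = mk_n(5, "B")),
                        list(treated = "A", untreated = "B"))
  expect_equal(unname(b2$fold_change["snv"]), 1)
  # zero denominator is flagged
  b3 <- mutation_burden(list(A = mk_n(5, "A"), B = mk_calls(character(0), "B")),
                        list(treated = "A", untreated = "B"))
  expect_true(is.na(b3$fold_change["snv"]))
  expect_true(b3$fold_undefined[["snv"]])
})

test_that("consensus recall matches the independence prediction", {
  sim <- cached("consensus_sim", {
    cfg <- synthetic_config(seed = 21, contig_lengths = c(chrC = 1500000L),
                            n_events = 10000L, caller_fn_rate = 0.1,
                            caller_fp_rate = 0.05)
    s <- run_sim(cfg)
    s$callsets <- make_call_sets(s$events, cfg, s$reference)
    s
  })
  cons <- consensus_intersect(sim$callsets)
  truth_keys <- unique(paste(sim$events$contig, sim$events$pos,
                             sim$events$ref, sim$events$alt))
  recall <- mean(truth_keys %in% paste(cons$contig, cons$pos, cons$ref,
                                       cons$alt))
  expect_lt(abs(recall - 0.9^3), 0.02)
})

test_that("VCF round trip preserves calls and splits multi-allelics", {
  tmp <- tempfile(fileext = ".vcf")
  calls <- mk_calls(c("chrS:100:C:A", "chrS:205:G:T"))
  write_vcf(calls, tmp, contig_lengths = c(chrS = 1000L))
  back <- read_vcf(tmp, sample_id = "S1", caller = "x")
  expect_equal(back$pos, c(100L, 205L))
  expect_equal(back$class, c("SNV", "SNV"))
  # 1-based in the file
  expect_true(any(grepl("\t101\t", readLines(tmp), fixed = TRUE)))
  # multi-allelic record splits into two calls at the same position
  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chrS\t101\t.\tC\tA,T\t.\tPASS\t."), tmp)
  ma <- read_vcf(tmp)
  expect_equal(nrow(ma), 2)
  expect_equal(ma$pos, c(100L, 100L))
  expect_equal(sort(ma$alt), c("A", "T"))
  # empty body
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), tmp)
  expect_equal(nrow(read_vcf(tmp)), 0)
})
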