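# Spectrum construction and comparison: SBS96/ID83 channelisation,
# cosine/differential identities, NNLS refitting, exposure correlation,
# and flanking composition.

test_that("SBS96 channels follow the pyrimidine-centred convention", {
  # C>A with top-strand context TCA
  ref <- c(chrS = paste0("AAAA", "TCA", "AAA"))
  v <- data.frame(contig = "chrS", pos = 5L, ref = "C", alt = "A")
  expect_equal(classify_sbs96(v, ref), "T[C>A]A")
  # G>T with top-strand context TGG collapses to C[C>A]A
  ref2 <- c(chrS = paste0("AAAA", "TGG", "AAA"))
  v2 <- data.frame(contig = "chrS", pos = 5L, ref = "G", alt = "T")
  expect_equal(classify_sbs96(v2, ref2), "C[C>A]A")
  # N in context is unclassified
  ref3 <- c(chrS = paste0("AAAA", "NCA", "AAA"))
  expect_true(is.na(classify_sbs96(v, ref3)))
})

test_that("SBS96 classification is strand-symmetric for all 96 channels", {
  for (ch in sbs96_channels()) {
    p5 <- substr(ch, 1, 1); refb <- substr(ch, 3, 3)
    altb <- substr(ch, 5, 5); p3 <- substr(ch, 7, 7)
    ctx <- paste0(p5, refb, p3)
    fwd_ref <- c(chrS = paste0("AA", ctx, "AA"))
    fwd_v <- data.frame(contig = "chrS", pos = 3L, ref = refb, alt = altb)
    # the same biological event seen from the bottom strand
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(paste0("AA", ctx, "AA"))))
    rev_ref <- c(chrS = rc)
    rev_v <- data.frame(contig = "chrS", pos = 3L,
                        ref = chartr("ACGT", "TGCA", refb),
                        alt = chartr("ACGT", "TGCA", altb))
    expect_equal(classify_sbs96(fwd_v, fwd_ref),
                 classify_sbs96(rev_v, rev_ref))
    expect_equal(classify_sbs96(fwd_v, fwd_ref), ch)
  }
})

test_that("ID83 channels follow the stated homopolymer and repeat rules", {
  # delete one T from AATTTTG: run of 4 including the deleted base
  ref <- c(chrS = paste0("AATTTTG", strrep("C", 20)))
  del_t <- data.frame(contig = "chrS", pos = 1L, ref = "AT", alt = "A")
  expect_equal(classify_indel(del_t, ref), "1:Del:T:3")
  # insert C between A and G with no adjacent C: run length 0
  ins_c <- data.frame(contig = "chrS", pos = 0L, ref = "A", alt = "AC")
  ref2 <- c(chrS = paste0("AG", strrep("T", 20)))
  expect_equal(classify_indel(ins_c, ref2), "1:Ins:C:0")
  # delete "AT" occurring once, no adjacent repeat, no microhomology
  ref3 <- c(chrS = paste0("GGG", "AT", "CCGG", strrep("G", 12)))
  del_at <- data.frame(contig = "chrS", pos = 2L, ref = "GAT", alt = "G")
  expect_equal(classify_indel(del_at, ref3), "2:Del:R:0")
  # delete "AT" inside ATATAT: 3 copies -> repeat channel subscript 2
  ref4 <- c(chrS = paste0("GGG", "ATATAT", "CCGG", strrep("G", 10)))
  del_rep <- data.frame(contig = "chrS", pos = 2L, ref = "GAT", alt = "G")
  expect_equal(classify_indel(del_rep, ref4), "2:Del:R:2")
  # microhomology: delete TAGC whose prefix TAG recurs just after the block
  ref5 <- c(chrS = paste0("GGG", "TAGC", "TAGG", strrep("C", 10)))
  del_mh <- data.frame(contig = "chrS", pos = 2L, ref = "GTAGC", alt = "G")
  expect_equal(classify_indel(del_mh, ref5), "4:Del:M:3")
  # purine collapse: deleting one G inside GGG maps to the C channel
  ref6 <- c(chrS = paste0("AAT", "GGG", "TAA", strrep("C", 10)))
  del_g <- data.frame(contig = "chrS", pos = 2L, ref = "TG", alt = "T")
  expect_equal(classify_indel(del_g, ref6), "1:Del:C:2")
})

test_that("spectra count, conserve, and add", {
  sim <- cached("small_sim", run_sim(small_config()))
  ev <- sim$events
  sp <- build_spectrum(ev, sim$reference, "SBS96")
  expect_equal(sum(sp$counts), nrow(ev) - sp$unclassified)
  expect_equal(sum(sp$fractions), 1, tolerance = 1e-9)
  # G>T events dominate and land in the C>A block
  ca_block <- grepl("C>A", sp$channels, fixed = TRUE)
  expect_gt(sum(sp$fractions[ca_block]), 0.85)
  # additivity over concatenation
  a <- build_spectrum(ev[1:200, ], sim$reference, "SBS96")
  b <- build_spectrum(ev[201:nrow(ev), ], sim$reference, "SBS96")
  expect_equal(add_spectra(a, b)$counts, sp$counts)
  # permutation invariance
  shuf <- build_spectrum(ev[sample(nrow(ev)), ], sim$reference, "SBS96")
  expect_equal(shuf$counts, sp$counts)
  # empty input gives the zero spectrum
  empty <- build_spectrum(ev[0, ], sim$reference, "SBS96")
  expect_true(all(empty$counts == 0))
})

test_that("lesion spectra are channelised into the C>A block", {
  ref <- c(chrS = paste0("AAAA", "TGG", "AAA"))
  les <- data.frame(contig = "chrS", pos = 5L, strand = "+")
  sp <- build_spectrum(les, ref, "SBS96")
  expect_equal(sp$channels[sp$counts == 1], "C[C>A]A")
  # a minus-strand lesion (top-strand C) uses its context directly
  ref2 <- c(chrS = paste0("AAAA", "TCA", "AAA"))
  les2 <- data.frame(contig = "chrS", pos = 5L, strand = "-")
  sp2 <- build_spectrum(les2, ref2, "SBS96")
  expect_equal(sp2$channels[sp2$counts == 1], "T[C>A]A")
})

test_that("cosine similarity identities hold", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(cosine_similarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2),
               tolerance = 1e-5)
  # symmetric and scale-invariant
  a <- c(0.3, 0.5, 0.2); b <- c(0.1, 0.2, 0.7)
  expect_equal(cosine_similarity(a, b), cosine_similarity(b, a))
  expect_equal(cosine_similarity(10 * a, b), cosine_similarity(a, b))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
})

test_that("differential spectra are zero-sum percentage differences", {
  a <- c(x = 30, y = 50, z = 20) / 100
  b <- c(x = 10, y = 50, z = 40) / 100
  d <- differential_spectrum(a, b)
  expect_equal(unname(d), c(20, 0, -20))
  expect_equal(sum(d), 0, tolerance = 1e-9)
  expect_equal(unname(differential_spectrum(a, a)), c(0, 0, 0))
})

test_that("NNLS refitting recovers exact catalog mixtures", {
  set.seed(1)
  # two signatures with low mutual cosine
  s1 <- c(rep(1, 8), rep(0, 88)); s1 <- s1 / sum(s1)
  s2 <- c(rep(0, 88), rep(1, 8)); s2 <- s2 / sum(s2)
  cat2 <- signature_catalog(matrix(c(s1, s2), ncol = 2,
                                   dimnames = list(NULL, c("sig1", "sig2"))))
  expect_lt(cosine_similarity(s1, s2), 0.3)
  mix <- 70 * s1 + 30 * s2
  fit <- refit_exposures(mix, cat2)
  expect_equal(unname(fit$exposures), c(70, 30), tolerance = 0.5)
  expect_lt(fit$residual, 1e-9)
  # pure signature
  fit2 <- refit_exposures(100 * s1, cat2)
  expect_equal(unname(fit2$exposures["sig1"]), 100, tolerance = 1e-6)
  expect_lt(unname(fit2$exposures["sig2"]), 1e-6)
  # zero spectrum
  fit3 <- refit_exposures(rep(0, 96), cat2)
  expect_true(all(fit3$exposures == 0))
  expect_error(signature_catalog(matrix(numeric(0), nrow = 96, ncol = 0)))
})

test_that("catalog TSV round trip preserves column-normalised signatures", {
  m <- matrix(c(2, 1, 1, 0, 0, 4), ncol = 2,
              dimnames = list(c("c1", "c2", "c3"), c("sigA", "sigB")))
  tmp <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(channel = rownames(m), m), tmp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cat2 <- read_signature_catalog(tmp)
  expect_equal(colSums(cat2$matrix), c(sigA = 1, sigB = 1))
  expect_equal(unname(cat2$matrix[, "sigA"]), c(0.5, 0.25, 0.25))
})

test_that("exposure correlation applies the 20-mutation threshold", {
  a <- c(s1 = 40, s2 = 80, s3 = 160, s4 = 19, s5 = 320)
  b <- 2 * a
  out <- exposure_correlation(a, b)
  expect_equal(out$n_retained, 4)        # s4 fails the threshold on a
  expect_false("s4" %in% out$retained)
  expect_equal(out$r, 1.0, tolerance = 1e-12)
  # hand-computed Pearson on a 5-sample table (closed form, raw counts)
  x <- c(s1 = 25, s2 = 30, s3 = 45, s4 = 60, s5 = 100)
  y <- c(s1 = 30, s2 = 20, s3 = 60, s4 = 55, s5 = 90)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  out2 <- exposure_correlation(x, y, log_transform = FALSE)
  expect_equal(out2$r, num / den, tolerance = 1e-12)
  # fewer than 3 retained samples is flagged
  out3 <- exposure_correlation(c(s1 = 50, s2 = 5), c(s1 = 50, s2 = 50))
  expect_true(is.na(out3$r))
})

test_that("flanking composition reports per-offset base frequencies", {
  # deletions of T always flanked by A on both immediate sides
  ref <- c(chrS = paste0("GG", "ATA", "CCC", "ATA", strrep("G", 10)))
  dels <- data.frame(contig = "chrS", pos = c(2L, 8L),
                     ref = c("AT", "AT"), alt = c("A", "A"))
  fc <- flanking_composition(dels, ref, k = 1)
  expect_equal(unname(fc["-1", "A"]), 1.0)
  expect_equal(unname(fc["1", "A"]), 1.0)
  expect_equal(unname(rowSums(fc)), c(1, 1))
  # uniform flanks come out near-uniform
  sim <- cached("small_sim", run_sim(small_config()))
  ev <- sim$events[sim$events$strand == "+" & !is.na(sim$events$context) &
                     sim$events$pos > 10, ]
  ev <- ev[1:300, ]
  dels2 <- data.frame(contig = ev$contig, pos = ev$pos - 1L,
                      ref = paste0(substr(ev$context, 1, 1), "G"),
                      alt = substr(ev$context, 1, 1))
  fc2 <- flanking_composition(dels2, sim$reference, k = 3)
  expect_equal(unname(rowSums(fc2)), rep(1, 6), tolerance = 1e-9)
})
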