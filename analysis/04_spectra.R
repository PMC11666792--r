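#!/usr/bin/env Rscript
# Stage 4: mutation and lesion spectra.
#
# Builds SBS96 spectra for pooled treated mutations, pooled untreated
# mutations, and extracted lesions; compares them by cosine similarity
# (all channels and the C>A block) and differential spectra; and refits
# the treated spectrum onto a two-signature catalog built from the pooled
# spectra.

suppressMessages(library(oxmut))
outdir <- "scratch/simdata"
if (!dir.exists(outdir)) stop("run analysis/01_simulate.R first (and 02, 03)")
reference <- read_fasta(file.path(outdir, "reference.fa"))

truth <- utils::read.table(file.path(outdir, "truth.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
treated <- truth[grepl("^treated", truth$sample_id), ]
untreated <- truth[grepl("^untreated", truth$sample_id), ]
lesions <- read_lesions(file.path(outdir, "lesions_rep1.bed"))

sp_t <- build_spectrum(treated, reference, "SBS96")
sp_u <- build_spectrum(untreated, reference, "SBS96")
sp_l <- build_spectrum(lesions, reference, "SBS96")

ca <- grep("C>A", sp_t$channels, fixed = TRUE, value = TRUE)
cmp <- data.frame(
  pair = c("treated_vs_untreated", "treated_vs_lesions",
           "untreated_vs_lesions"),
  cosine_all = c(cosine_similarity(sp_t, sp_u),
                 cosine_similarity(sp_t, sp_l),
                 cosine_similarity(sp_u, sp_l)),
  cosine_CtoA = c(cosine_similarity(sp_t, sp_u, channels = ca),
                  cosine_similarity(sp_t, sp_l, channels = ca),
                  cosine_similarity(sp_u, sp_l, channels = ca)))
utils::write.table(cmp, "results/04_cosine.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

diff_tl <- differential_spectrum(sp_t, sp_l)
spec_tab <- data.frame(channel = sp_t$channels,
                       treated = sp_t$fractions,
                       untreated = sp_u$fractions,
                       lesions = sp_l$fractions,
                       diff_treated_lesions_pct = diff_tl)
utils::write.table(spec_tab, "results/04_spectra.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# refit the treated spectrum on a catalog of the two pooled signatures
catalog <- signature_catalog(matrix(
  c(sp_t$fractions + 1e-9, sp_u$fractions + 1e-9), ncol = 2,
  dimnames = list(sp_t$channels, c("oxidative", "background"))))
fit <- refit_exposures(sp_t, catalog)
cat("Cosine similarities:\n"); print(cmp, row.names = FALSE)
cat(sprintf("Refit of treated spectrum: oxidative = %.0f, background = %.0f (residual %.2f)\n",
            fit$exposures["oxidative"], fit$exposures["background"],
            fit$residual))
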