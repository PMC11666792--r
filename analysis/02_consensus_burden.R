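#!/usr/bin/env Rscript
# Stage 2: consensus mutation calling and per-genome burden.
#
# For every simulated genome, intersect the three per-caller call sets
# (3-caller consensus for SNVs), pool all samples, remove cross-sample
# shared variants, and summarise burdens with the treated/untreated fold
# change and a two-sided Mann-Whitney U test.

suppressMessages(library(oxmut))
outdir <- "scratch/simdata"
if (!dir.exists(outdir)) stop("run analysis/01_simulate.R first")
reference <- read_fasta(file.path(outdir, "reference.fa"))

samples <- sub("\\.strelka2\\.vcf$", "",
               basename(Sys.glob(file.path(outdir, "*.strelka2.vcf"))))
consensus <- list()
for (s in samples) {
  callsets <- lapply(c(strelka2 = "strelka2", varscan2 = "varscan2",
                       somaticsniper = "somaticsniper"), function(cl)
    read_vcf(file.path(outdir, sprintf("%s.%s.vcf", s, cl)),
             sample_id = s, caller = cl))
  consensus[[s]] <- consensus_intersect(callsets, reference = reference)
}
filtered <- remove_cross_sample(consensus)
removed <- attr(filtered, "removed")

burden <- mutation_burden(filtered,
                          list(treated = grep("^treated", samples, value = TRUE),
                               untreated = grep("^untreated", samples,
                                                value = TRUE)))
tab <- burden$per_sample
tab$cross_sample_removed <- removed[tab$sample]
utils::write.table(tab, "results/02_burden.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
for (s in names(filtered)) {
  write_vcf(filtered[[s]], file.path(outdir, paste0(s, ".consensus.vcf")))
}
cat(sprintf("SNV fold change (treated/untreated medians): %.2f (Mann-Whitney p = %.3g)\n",
            burden$fold_change[["snv"]], burden$mann_whitney_p[["snv"]]))
print(burden$medians, row.names = FALSE)
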