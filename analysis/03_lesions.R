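#!/usr/bin/env Rscript
# Stage 3: extract single-nucleotide 8-oxoG lesion positions from the
# lesion-capture SAM replicates, applying the full-length-alignment, flag,
# contig, and guanine filters, and write BED lesion tracks.

suppressMessages(library(oxmut))
outdir <- "scratch/simdata"
if (!dir.exists(outdir)) stop("run analysis/01_simulate.R first")
reference <- read_fasta(file.path(outdir, "reference.fa"))

rows <- list()
for (rep_k in 1:2) {
  sam <- file.path(outdir, sprintf("lesions_rep%d.sam", rep_k))
  reads <- parse_sam_records(sam)
  lesions <- reads_to_lesions(reads, reference)
  write_lesions(lesions, file.path(outdir, sprintf("lesions_rep%d.bed", rep_k)))
  rej <- attr(lesions, "rejected")
  rows[[rep_k]] <- data.frame(replicate = rep_k, input_reads = nrow(reads),
                              lesions = nrow(lesions), t(rej))
}
tab <- do.call(rbind, rows)
utils::write.table(tab, "results/03_lesion_extraction.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
print(tab, row.names = FALSE)
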