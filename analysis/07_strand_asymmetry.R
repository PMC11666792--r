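#!/usr/bin/env Rscript
# Stage 7: replication and transcription strand asymmetry.
#
# Assigns every treated mutation (per sample, per G-based substitution
# class) to the leading/lagging replication template and to the
# transcribed/non-transcribed gene strand, normalises by strand-specific
# guanine content (events/Mb of G), and tests asymmetry by two-sided
# paired t-test across the four genomes. Lesions run through the same
# machinery as a single class.

suppressMessages(library(oxmut))
outdir <- "scratch/simdata"
if (!dir.exists(outdir)) stop("run analysis/01_simulate.R first (and 03)")
reference <- read_fasta(file.path(outdir, "reference.fa"))

truth <- utils::read.table(file.path(outdir, "truth.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
treated <- truth[grepl("^treated", truth$sample_id), ]
repl_bed <- read_bed(file.path(outdir, "replication.bed"))
repl <- data.frame(contig = repl_bed$contig, start = repl_bed$start,
                   end = repl_bed$end, direction = repl_bed$name)
genes_bed <- read_bed(file.path(outdir, "genes.bed"))
genes <- data.frame(contig = genes_bed$contig, start = genes_bed$start,
                    end = genes_bed$end, strand = genes_bed$strand)

res_r <- strand_asymmetry(treated, reference, repl, "replication")
res_t <- strand_asymmetry(treated, reference, genes, "transcription")
out <- rbind(cbind(mode = "replication", res_r),
             cbind(mode = "transcription", res_t))

lesions <- read_lesions(file.path(outdir, "lesions_rep1.bed"))
les_r <- strand_asymmetry(lesions, reference, repl, "replication")
out <- rbind(out, cbind(mode = "replication", les_r))

utils::write.table(out, "results/07_asymmetry.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Strand asymmetry (log2 ratio of numerator/denominator rates):\n")
print(out[, c("mode", "class", "strand_a", "strand_b", "count_a", "count_b",
              "log2_ratio", "method", "p_value")], row.names = FALSE)
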