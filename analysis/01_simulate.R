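#!/usr/bin/env Rscript
# Stage 1: build the synthetic oxidative-mutagenesis study.
#
# Emulates the experimental design: four "treated" genomes carrying a heavy
# G-centred mutation load with planted chromatin structure (heterochromatin
# enrichment, 10.3 bp rotational and 192 bp translational periodicity around
# nucleosome dyads, a mild leading-strand bias), four "untreated" genomes
# with a 20x lighter load and no planted structure, per-caller call sets
# with independent errors, and a lesion-capture SAM file. Raw fixtures go to
# scratch/simdata (regenerable); a summary table goes to results/.

suppressMessages(library(oxmut))

outdir <- "scratch/simdata"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

mult <- setNames(rep(1, 15), names(chromhmm15_groups()))
mult[c("12_Repressed", "13_Heterochrom_lo")] <- 2

base <- synthetic_config(
  seed = 20240101,
  contig_lengths = c(chrS1 = 1e6, chrS2 = 1e6),
  rotational_amplitude = 0.4,
  translational_amplitude = 0.25,
  leading_lagging_bias = 1.2,
  state_rate_multipliers = mult,
  n_events = 12000L)

reference <- make_reference(base)
tracks <- make_annotation_fixtures(base, reference)
write_fasta(reference, file.path(outdir, "reference.fa"))
write_bed(data.frame(contig = tracks$dyads$contig, start = tracks$dyads$pos,
                     end = tracks$dyads$pos + 1L), file.path(outdir, "dyads.bed"))
write_bed(data.frame(contig = tracks$states$contig, start = tracks$states$start,
                     end = tracks$states$end, name = tracks$states$state),
          file.path(outdir, "states.bed"))
write_bed(data.frame(contig = tracks$replication$contig,
                     start = tracks$replication$start,
                     end = tracks$replication$end,
                     name = tracks$replication$direction),
          file.path(outdir, "replication.bed"))
write_bed(data.frame(contig = tracks$genes$contig, start = tracks$genes$start,
                     end = tracks$genes$end, name = tracks$genes$name,
                     score = 0L, strand = tracks$genes$strand),
          file.path(outdir, "genes.bed"))
write_bed(data.frame(contig = tracks$tf_sites$contig,
                     start = tracks$tf_sites$pos,
                     end = tracks$tf_sites$pos + 1L),
          file.path(outdir, "tf_sites.bed"))

summary_rows <- list()
all_truth <- list()
for (grp in c("treated", "untreated")) {
  for (k in 1:4) {
    cfg <- base
    cfg$seed <- base$seed + k + ifelse(grp == "treated", 0L, 100L)
    if (grp == "untreated") {
      cfg$n_events <- 600L
      cfg$rotational_amplitude <- 0
      cfg$translational_amplitude <- 0
      cfg$leading_lagging_bias <- 1
      cfg$state_rate_multipliers[] <- 1
    }
    sample_id <- sprintf("%s_%d", grp, k)
    truth <- plant_events(cfg, reference, tracks, sample_id = sample_id)
    all_truth[[sample_id]] <- truth
    callsets <- make_call_sets(truth, cfg, reference)
    for (cl in names(callsets)) {
      write_vcf(callsets[[cl]],
                file.path(outdir, sprintf("%s.%s.vcf", sample_id, cl)),
                contig_lengths = cfg$contig_lengths)
    }
    summary_rows[[sample_id]] <- data.frame(
      sample = sample_id, group = grp, planted_events = nrow(truth),
      unique_sites = length(unique(paste(truth$contig, truth$pos))))
  }
}
truth_all <- do.call(rbind, c(unname(all_truth), list(make.row.names = FALSE)))
utils::write.table(truth_all, file.path(outdir, "truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

# lesion-capture reads: two technical replicates drawn from the treated truth
les_cfg <- base; les_cfg$seed <- base$seed + 999L; les_cfg$n_events <- 8000L
for (rep_k in 1:2) {
  les_cfg$seed <- les_cfg$seed + rep_k
  lesions <- plant_events(les_cfg, reference, tracks,
                          sample_id = paste0("lesion_rep", rep_k))
  lesions <- unique(lesions[lesions$pos > 200 &
                              lesions$pos < 1e6 - 200,
                            c("contig", "pos", "strand")])
  sam <- make_sam_fixture(lesions, reference, les_cfg, n_contaminants = 50)
  write_sam(sam, file.path(outdir, sprintf("lesions_rep%d.sam", rep_k)),
            les_cfg$contig_lengths)
}

summary <- do.call(rbind, c(unname(summary_rows), list(make.row.names = FALSE)))
utils::write.table(summary, "results/01_simulation_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Simulated", nrow(summary), "genomes +2 lesion replicates into", outdir, "\n")
print(summary, row.names = FALSE)
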