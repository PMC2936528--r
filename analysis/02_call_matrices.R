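#!/usr/bin/env Rscript
# Call per-CpG methylation from the simulated clone FASTA written by
# 01_simulate_clones.R: orient reads, assign strands, apply the >= 95%
# conversion filter, classify dcm status, and write call-matrix TSVs.

suppressMessages(library(methpatterns))

indir <- "results/simulations"
outdir <- "results/calls"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

for (mn in c("dnmt3a", "dnmt3b")) {
  for (tag in c("alone", "with3L")) {
    d <- file.path(indir, mn, tag)
    refs <- list.files(d, pattern = "\\.fasta$", full.names = TRUE)
    refs <- refs[!grepl("_clones\\.fasta$", refs)]
    for (rf in refs) {
      rseq <- read_fasta(rf)
      region <- reference_region(names(rseq)[1], rseq[[1]])
      clones <- read_fasta(sub("\\.fasta$", "_clones.fasta", rf))
      calls <- call_clones(clones, region, threshold = 0.95)
      out <- file.path(outdir, sprintf("%s_%s_%s.tsv", mn, region$name, tag))
      write_call_matrix(calls, out)
      message(sprintf(
        "%s %s %s: %d reads, %d pass filter (%.1f%%), dcm+ %d / dcm- %d",
        mn, region$name, tag, nrow(calls), sum(calls$pass_filter),
        100 * mean(calls$pass_filter),
        sum(calls$dcm_class == "dcm+", na.rm = TRUE),
        sum(calls$dcm_class == "dcm-", na.rm = TRUE)))
    }
  }
}
message("call matrices under ", outdir)
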