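#!/usr/bin/env Rscript
# Hotspot/coldspot word exceptionality under the M1 (first-order Markov)
# background, and CpG-island metrics, for the bundled regions: the predicted
# DNMT3B coldspot pattern NGCGCN and hotspot pattern NTCGGN are scanned and
# scored as z = (observed - expected) / sd.

suppressMessages(library(methpatterns))

outdir <- "results/words"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
regs <- bundled_regions()

# island metrics per region
im <- do.call(rbind, lapply(names(regs), function(rn) {
  x <- island_metrics(regs[[rn]]$sequence)
  data.frame(region = rn, gc = x$gc, obs_exp_cpg_ratio = x$ratio,
             island = x$island)
}))
utils::write.table(im, file.path(outdir, "island_metrics.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(paste(capture.output(print(im, row.names = FALSE)), collapse = "\n"))

# pooled word scans over all bundled region sequences
seqs <- vapply(regs, `[[`, character(1), "sequence")
cnt <- count_words(seqs, 6)
for (pat in c("NGCGCN", "NTCGGN")) {
  sw <- scan_words(seqs, pat, counts = cnt)
  utils::write.table(sw, file.path(outdir, sprintf("scan_%s.tsv", pat)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  agg <- sw[sw$word == pat, ]
  message(sprintf("%s: aggregate observed %d vs expected %.1f (score %.2f)",
                  pat, agg$observed, agg$expected, agg$score))
}

# null calibration of the scan on sequences drawn from the fitted chain
fitted <- simulate_m1(6, 3000,
                      P = matrix(c(.25, .3, .25, .2, .3, .25, .2, .25,
                                   .2, .3, .25, .25, .25, .2, .3, .25),
                                 4, 4, byrow = TRUE), seed = 99)
swn <- scan_words(fitted, "NTCGGN")
message(sprintf("null scan: %.0f%% of words at |z| > 1.96",
                100 * mean(abs(swn$score[swn$word != "NTCGGN"]) > 1.96,
                           na.rm = TRUE)))
message("word tables under ", outdir)
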