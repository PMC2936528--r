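#!/usr/bin/env Rscript
# Per-site efficiency patterns and flanking-sequence preference extraction:
# site ranking, extreme-site fold ranges, strand symmetry, hot/cold decile
# selection pooled over the two test regions, flank orientation, and
# positional chi-square enrichment with logo information content.

suppressMessages(library(methpatterns))

outdir <- "results/patterns"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
regs <- bundled_regions()[c("pBR_synthetic", "Hygro_synthetic")]
bg <- flank_background(regs, 2)

for (mn in c("dnmt3a", "dnmt3b")) {
  calls <- lapply(names(regs), function(rn)
    read_call_matrix(file.path("results/calls",
                               sprintf("%s_%s_alone.tsv", mn, rn))))

  # per-region site tables, fold ranges, strand symmetry
  for (i in seq_along(regs)) {
    tab <- rank_sites(site_efficiencies(calls[[i]]))
    utils::write.table(tab, file.path(outdir, sprintf("%s_%s_sites.tsv",
                                                      mn, names(regs)[i])),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fr <- fold_range(tab)
    sym <- strand_symmetry(site_efficiencies(calls[[i]], strand = "top"),
                           site_efficiencies(calls[[i]], strand = "bottom"))
    message(sprintf(
      "%s %s: overall %.1f%%, extreme-site fold range %.1f (~%d-fold), strand r = %.2f",
      mn, names(regs)[i], 100 * attr(tab, "overall"), fr$fold, fr$fold_int,
      sym$r))
  }

  # hot/cold deciles pooled over regions and strands, oriented, tested
  hc <- hotcold_flanks(calls, unname(regs))
  for (w in c("hot", "cold")) {
    enr <- position_enrichment(hc[[w]], bg)
    utils::write.table(enr, file.path(outdir, sprintf("%s_%s_enrichment.tsv",
                                                      mn, w)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    top <- enr[enr$direction == "enriched", ]
    top <- top[order(top$p), ][1:3, ]
    message(sprintf("%s %s flanks (n=%d): top enriched cells %s", mn, w,
                    nrow(hc[[w]]),
                    paste(sprintf("%+d/%s p=%.2g", top$offset, top$base,
                                  top$p), collapse = ", ")))
  }
}
message("pattern tables under ", outdir)
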