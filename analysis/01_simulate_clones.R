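#!/usr/bin/env Rscript
# Simulate bisulfite clone libraries for the two episome-like test regions
# under DNMT3A-like and DNMT3B-like flanking-preference models, with and
# without DNMT3L-style saturation.  Writes reference/clone FASTA plus truth
# tables under results/simulations/.

suppressMessages(library(methpatterns))

seed <- 20260927L
outdir <- "results/simulations"
regs <- bundled_regions()[c("pBR_synthetic", "Hygro_synthetic")]

models <- list(
  dnmt3a = build_preference_model("3A-like", 1.5),
  dnmt3b = build_preference_model("3B-like", 1.6)
)

for (mn in names(models)) {
  for (rn in names(regs)) {
    for (k3l in c(1, 4)) {
      par <- simulation_params(n_molecules = 200, conversion_rate = 0.991,
                               maintenance_efficiency = 0.9,
                               dnmt3l_exponent = k3l,
                               seed = seed + k3l + match(rn, names(regs)) * 10L +
                                 match(mn, names(models)) * 100L)
      sim <- simulate_molecules(regs[[rn]], models[[mn]], par)
      tag <- if (k3l == 1) "alone" else "with3L"
      write_simulation(sim, regs[[rn]], file.path(outdir, mn, tag))
      message(sprintf("%s / %s / %s: %d clone reads", mn, rn, tag,
                      length(sim$reads)))
    }
  }
}
message("done; clone FASTA and truth tables under ", outdir)
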