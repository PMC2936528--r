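test_that("site efficiencies count methylated over informative calls", {
  reg <- toy_region()
  sim <- simulate_molecules(reg, build_preference_model("null", 0),
                            simulation_params(n_molecules = 10,
                                              conversion_rate = 1, seed = 1))
  calls <- call_clones(sim$reads, reg)
  tab <- site_efficiencies(calls, n_min = 1)
  expect_identical(tab$site, reg$cpg_sites)
  expect_equal(tab$efficiency, tab$m / tab$n)
  expect_equal(attr(tab, "overall"), sum(tab$m) / sum(tab$n))
  # arithmetic on a hand table
  expect_equal(site_table(3, 20)$efficiency, 0.15)
  expect_equal(site_table(10, 10)$efficiency, 1.0)
  # empty stratum errors and names the stratum
  expect_error(site_efficiencies(calls, dcm_class = "dcm+"), "empty stratum")
})

test_that("ranking uses descending efficiency with average ties", {
  t1 <- rank_sites(site_table(c(3, 1, 2), 10))
  expect_equal(t1$rank, c(1, 3, 2))
  t2 <- rank_sites(site_table(c(2, 2, 2, 2), 10))
  expect_equal(t2$rank, rep(2.5, 4))
  t3 <- rank_sites(site_table(c(3, 3, 1), 10))
  expect_equal(t3$rank, c(1.5, 1.5, 3))
  expect_equal(sum(t3$rank), 3 * 4 / 2)       # N(N+1)/2 under average ties
})

test_that("rank correlation is squared Pearson on ranks with signed r", {
  a <- site_table(c(8, 6, 4, 2), 10)
  expect_equal(rank_correlation(a, a)$r_squared, 1.0)
  rev <- site_table(c(2, 4, 6, 8), 10)
  rc <- rank_correlation(a, rev)
  expect_equal(rc$r, -1)
  expect_equal(rc$r_squared, 1.0)
  # ranks A=(1,2,3,4) vs B=(2,1,3,4): hand Pearson gives r=0.8
  b <- site_table(c(6, 8, 4, 2), 10)
  rc2 <- rank_correlation(a, b)
  expect_equal(rc2$r, 0.8)
  expect_equal(rc2$r_squared, 0.64)
  expect_warning(out <- rank_correlation(site_table(c(1, 2), 10),
                                         site_table(c(2, 1), 10)), "fewer than 3")
  expect_true(is.na(out$r_squared))
})

test_that("fold range reproduces the published extreme-site ratios", {
  # printed efficiency pairs: 28.5% vs 2.6% and 29.3% vs 0.86%
  fr1 <- fold_range(c(0.285, 0.026))
  expect_equal(fr1$fold, 10.96, tolerance = 1e-3)
  expect_identical(fr1$fold_int, 11)
  fr2 <- fold_range(c(0.293, 0.0086))
  expect_equal(fr2$fold, 34.07, tolerance = 1e-3)
  expect_identical(fr2$fold_int, 34)
  expect_equal(fold_range(c(0.2, 0.2, 0.2))$fold, 1.0)
  expect_true(is.na(fold_range(c(0, 0))$fold))
  # Haldane pseudocount keeps zero-count sites finite
  tabz <- site_table(c(10, 0), c(20, 20))
  expect_equal(fold_range(tabz, n_min = 1)$fold, 0.5 / (0.5 / 21))
})

test_that("fold stimulation detects the saturation trend", {
  n <- 10000L
  e <- c(0.01, 0.05, 0.10, 0.20, 0.30, 0.50)
  alone <- site_table(round(e * n), n)
  stim <- site_table(round((1 - (1 - e)^5) * n), n)
  fs <- fold_stimulation(alone, stim, n_min = 1)
  expect_equal(fs$trend_rho, -1)                 # strictly monotone fold
  expect_lt(fs$fold_range_after, fs$fold_range_before)
  expect_equal(fs$rank_r_squared, 1.0)           # ranks preserved
  # identical tables: fold 1 everywhere, trend undefined
  fs0 <- fold_stimulation(alone, alone, n_min = 1)
  expect_true(all(fs0$table$fold == 1))
  expect_true(is.na(fs0$trend_rho))
  expect_error(fold_stimulation(alone, site_table(1:3, 10)), "do not match")
})

test_that("stimulated simulations show the negative fold-vs-baseline trend", {
  reg <- bundled_regions()$pBR_synthetic
  m <- build_preference_model("3A-like", 1.5)
  base <- simulation_params(n_molecules = 300, seed = 21)
  stim <- simulation_params(n_molecules = 300, dnmt3l_exponent = 4, seed = 22)
  ta <- site_efficiencies(call_clones(simulate_molecules(reg, m, base)$reads, reg))
  ts <- site_efficiencies(call_clones(simulate_molecules(reg, m, stim)$reads, reg))
  fs <- fold_stimulation(ta, ts)
  expect_lt(fs$trend_rho, 0)
  expect_lt(fs$trend_p, 0.01)
  expect_lt(fs$fold_range_after, fs$fold_range_before)
})

test_that("extreme selection sizes, tie-breaks and disjointness", {
  t48 <- rank_sites(site_table(seq_len(48), 100, positions = seq_len(48)))
  ext <- select_extremes(t48, 0.10)
  expect_length(ext$hot, 5)                      # ceiling(4.8)
  expect_length(ext$cold, 5)
  expect_length(intersect(ext$hot, ext$cold), 0)
  t10 <- rank_sites(site_table(seq_len(10), 50, positions = seq_len(10)))
  e10 <- select_extremes(t10, 0.10)
  expect_length(e10$hot, 1); expect_length(e10$cold, 1)
  # N=5 at fraction 0.5: 3 hot, 2 cold, deterministic and disjoint
  t5 <- rank_sites(site_table(c(2, 2, 2, 2, 2), 10, positions = 1:5))
  e5 <- select_extremes(t5, 0.5)
  expect_identical(e5$hot, c(1L, 2L, 3L))        # position tie-break
  expect_identical(e5$cold, c(4L, 5L))
  expect_length(intersect(e5$hot, e5$cold), 0)
  expect_error(select_extremes(t5, 0), "fraction")
  expect_error(select_extremes(t5, 0.6), "fraction")
})

test_that("flank extraction slices 5'->3' context on either strand", {
  reg <- reference_region("t", "ATACGTCA")       # CpG at 0-based 3? no: CG at 3
  expect_identical(extract_flanks(reg, 1, "top", 2), "TACGTC")
  expect_identical(extract_flanks(reg, 1, "bottom", 2), "GACGTA")
  # palindromic window reads the same on both strands
  regp <- reference_region("p", "ATTACGTAAT")
  expect_identical(extract_flanks(regp, 1, "top", 2),
                   extract_flanks(regp, 1, "bottom", 2))
  # insufficient context: NA with warning
  rege <- reference_region("e", "CGTTTTTTTT")
  expect_warning(fl <- extract_flanks(rege, 1, "top", 2), "flank context")
  expect_true(is.na(fl))
})

test_that("flank orientation unifies reverse-complemented minorities", {
  fl <- c(rep("TACGTC", 9), "GACGTA")
  out <- orient_flanks(fl)
  expect_identical(unique(out$flank), "TACGTC")
  expect_identical(out$orientation, c(rep("direct", 9), "rc"))
  # all identical flanks stay direct
  same <- orient_flanks(rep("AACGTT", 5))
  expect_true(all(same$orientation == "direct"))
  # palindromes stay direct under the tie rule
  pal <- orient_flanks(rep("TTACGTAA", 4))
  expect_true(all(pal$orientation == "direct"))
  expect_true(attr(out, "converged"))
})

test_that("positional chi-square matches the hand-computed example", {
  # 20 flanks, 15 with T at offset -2, background q_T = 0.25:
  # X2 = (15-5)^2/5 + (5-15)^2/15 = 26.667
  fl <- c(rep("TACGTC", 15), rep("GACGTC", 5))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  enr <- position_enrichment(fl, bg)
  cell <- enr[enr$offset == -2 & enr$base == "T", ]
  expect_equal(cell$observed, 15)
  expect_equal(cell$expected, 5)
  expect_equal(cell$chisq, 100 / 5 + 100 / 15, tolerance = 1e-9)
  expect_equal(cell$p, pchisq(100 / 5 + 100 / 15, 1, lower.tail = FALSE))
  expect_lt(abs(log(cell$p / 2.4e-7)), log(1.5))
  expect_identical(cell$direction, "enriched")
  # exact binomial tail oracle: same order of magnitude in this deep tail
  p_exact <- sum(dbinom(0:20, 20, 0.25)[dbinom(0:20, 20, 0.25) <=
                                          dbinom(15, 20, 0.25) * (1 + 1e-9)])
  expect_lt(abs(log10(cell$p) - log10(p_exact)), 1.5)
})

test_that("chi-square matches the exact binomial in the calibrated regime", {
  # wherever both p-values are above 0.01 (and both expected cells >= 5),
  # the 1-df chi-square and the exact two-sided binomial agree within a
  # factor of 3 over the full N <= 30 grid
  worst <- 0
  for (N in 5:30) for (q in seq(0.05, 0.95, by = 0.05)) {
    if (N * q < 5 || N * (1 - q) < 5) next
    d <- dbinom(0:N, N, q)
    for (O in 0:N) {
      E <- N * q
      X2 <- (O - E)^2 / E + ((N - O) - (N - E))^2 / (N - E)
      pchi <- pchisq(X2, 1, lower.tail = FALSE)
      pex <- sum(d[d <= d[O + 1] * (1 + 1e-9)])
      if (min(pchi, pex) < 0.01) next
      worst <- max(worst, max(pchi, pex) / min(pchi, pex))
    }
  }
  expect_lt(worst, 3)
})

test_that("enrichment handles uniform observation and conservation limits", {
  # observed frequencies exactly at background: X2 = 0, p = 1 everywhere
  fl <- c("AACGTA", "CACGTC", "GACGTG", "TACGTT")
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  enr <- position_enrichment(fl, bg)
  cells <- enr[enr$offset %in% c(-2, 2), ]
  expect_true(all(abs(cells$chisq) < 1e-12))
  expect_true(all(cells$p == 1))
  # perfectly conserved offset reaches 2 bits; IC stays within [0, 2]
  enr2 <- position_enrichment(c(rep("TACGTC", 8)), bg)
  expect_true(all(abs(enr2$ic - 2) < 1e-12))
  expect_true(all(enr$ic >= 0 & enr$ic <= 2))
  expect_equal(enr$ic[enr$offset == -2][1], 0)   # uniform offset: 0 bits
  expect_error(position_enrichment(character(0), bg), "empty")
  expect_error(position_enrichment(fl, c(A = 0.5, C = 0.5, G = 0, T = 0)),
               "background")
})

test_that("IC and letter heights decompose the logo", {
  fl <- c(rep("TACGTC", 6), rep("AACGTC", 2))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  enr <- position_enrichment(fl, bg)
  off <- enr[enr$offset == -2, ]
  f <- off$observed / 8
  H <- -sum(ifelse(f > 0, f * log2(f), 0))
  expect_equal(unique(off$ic), 2 - H)
  expect_equal(off$letter_height, f * (2 - H))
})

test_that("strand symmetry report behaves at the degenerate limits", {
  a <- site_table(c(1, 5, 9), 10)
  expect_equal(strand_symmetry(a, a)$r, 1.0)
  expect_warning(out <- strand_symmetry(site_table(c(2, 2, 2), 10),
                                        site_table(c(1, 2, 3), 10)),
                 "degenerate")
  expect_true(is.na(out$r))
})

test_that("one-tailed stimulation test matches the closed-form t", {
  # groups with exact means 0.05 / 0.15 and sd 0.05, n = 30 each
  mk <- function(mean, sd, n, seed) {
    x <- withr::with_seed(seed, rnorm(n))
    as.numeric(scale(x)) * sd + mean
  }
  g1 <- mk(0.05, 0.05, 30, 1); g2 <- mk(0.15, 0.05, 30, 2)
  out <- group_stimulation_test(g1, g2)
  t_hand <- (0.15 - 0.05) / (0.05 * sqrt(2 / 30))
  expect_equal(out$statistic, t_hand, tolerance = 1e-9)
  expect_equal(out$p_value, pt(t_hand, 58, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(out$p_value, 0.001)
  expect_identical(out$stars, "***")
  expect_equal(out$fold, 3)

  # identical groups: t = 0, p = 0.5, not significant
  out0 <- group_stimulation_test(g1, g1)
  expect_equal(out0$p_value, 0.5)
  expect_identical(out0$stars, "ns")

  # star boundaries follow the published convention
  g3 <- mk(0.078, 0.05, 30, 3)
  out3 <- group_stimulation_test(g1, g3)
  expect_true(out3$p_value > 0.01 && out3$p_value <= 0.05)
  expect_identical(out3$stars, "*")
  expect_error(group_stimulation_test(1, c(1, 2)), ">= 2 molecules")
})

test_that("per-site estimates concentrate around the simulated truth", {
  reg <- bundled_regions()$Hygro_synthetic
  m <- build_preference_model("3B-like", 1.5)
  p <- simulation_params(n_molecules = 500, conversion_rate = 1,
                         maintenance_efficiency = 0, seed = 31)
  sim <- simulate_molecules(reg, m, p)
  calls <- call_clones(sim$reads, reg)
  tab <- site_efficiencies(calls, strand = "top")
  truth <- sim$truth$p_top$p
  se <- sqrt(truth * (1 - truth) / tab$n)
  expect_gte(mean(abs(tab$efficiency - truth) <= 3 * se), 0.95)
})
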