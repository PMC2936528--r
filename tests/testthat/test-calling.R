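test_that("strand assignment follows conversion evidence", {
  reg <- toy_region()
  chars <- strsplit(reg$sequence, "")[[1]]
  # top-strand clone: every non-CpG C -> T
  top_read <- chars
  top_read[c(11, 15, 26)] <- "T"     # 1-based non-CpG Cs (0-based 10, 14, 25)
  expect_identical(assign_strand(paste(top_read, collapse = ""), reg), "top")
  # bottom-strand clone in top coordinates: every non-CpG G -> A
  bot_read <- chars
  bot_read[17] <- "A"                # the only eligible bottom C (top G at 16)
  expect_identical(assign_strand(paste(bot_read, collapse = ""), reg), "bottom")
  # unconverted read: tie, NA with warning
  expect_warning(s <- assign_strand(reg$sequence, reg), "tie")
  expect_true(is.na(s))
  expect_error(assign_strand("ACGT", reg), "length")
})

test_that("orient_read flips reverse-complemented clones into top coordinates", {
  reg <- toy_region()
  sim <- simulate_molecules(reg, build_preference_model("null", 0),
                            simulation_params(n_molecules = 3, seed = 2))
  rd <- sim$reads[[1]]
  o1 <- orient_read(rd, reg)
  o2 <- orient_read(revcomp(rd), reg)
  expect_false(o1$flipped)
  expect_true(o2$flipped)
  expect_identical(o1$seq, o2$seq)
})

test_that("call_molecule reads the toy case as enumerated by hand", {
  reg <- toy_region()        # CpGs at 5 and 20; non-CpG Cs at 10, 14, 25
  chars <- strsplit(reg$sequence, "")[[1]]
  rd <- chars
  rd[c(11, 15, 26)] <- "T"   # all eligible Cs converted
  rd[21] <- "T"              # CpG at 20 unmethylated; CpG at 5 retained
  cm <- call_molecule(paste(rd, collapse = ""), reg, "top")
  expect_identical(unname(cm$calls), c(1L, 0L))
  expect_equal(cm$conversion_efficiency, 1.0)

  # read identical to the reference: everything methylated, conversion 0
  cm2 <- call_molecule(reg$sequence, reg, "top")
  expect_identical(unname(cm2$calls), c(1L, 1L))
  expect_equal(cm2$conversion_efficiency, 0.0)

  # non-C/T base at a CpG site is a missing call
  rd[6] <- "G"
  cm3 <- call_molecule(paste(rd, collapse = ""), reg, "top")
  expect_identical(unname(cm3$calls), c(NA_integer_, 0L))
})

test_that("conversion efficiency boundary cases and the inclusive filter", {
  # 20 eligible cytosines, 19 converted -> 0.95, passes the default filter
  reg <- reference_region("c20", paste0(paste(rep("CA", 20), collapse = ""), "TT"))
  chars <- strsplit(reg$sequence, "")[[1]]
  rd <- chars; rd[seq(1, 37, by = 2)] <- "T"   # 19 of 20 Cs converted
  eff <- conversion_efficiency(paste(rd, collapse = ""), reg, "top")
  expect_equal(eff, 0.95)

  calls <- data.frame(conversion_efficiency = c(1.0, 0.96, 0.95, 0.90))
  expect_identical(sum(filter_molecules(calls, 0.95)$pass_filter), 3L)
  expect_identical(sum(filter_molecules(calls, 0)$pass_filter), 4L)
  expect_identical(sum(filter_molecules(calls, 1)$pass_filter), 1L)

  # no eligible cytosines: NA with a warning
  rega <- reference_region("nocs", "AATTAATTGGAA")
  expect_warning(e <- conversion_efficiency("AATTAATTGGAA", rega, "top"),
                 "no eligible")
  expect_true(is.na(e))
})

test_that("dcm classification counts strand-appropriate retained marks", {
  dreg <- dcm_region()       # dcm internal Cs: top 7,18,29; one CpG at 39
  chars <- strsplit(dreg$sequence, "")[[1]]
  conv <- function(x, keep) {
    rd <- chars
    ctops <- which(rd == "C")                  # all top-strand Cs, 1-based
    rd[setdiff(ctops, keep)] <- "T"
    paste(rd, collapse = "")
  }
  # all three dcm Cs retained -> dcm+
  expect_identical(classify_dcm(conv(chars, c(8, 19, 30)), dreg, "top"), "dcm+")
  # one of three retained -> dcm- at the default threshold
  expect_identical(classify_dcm(conv(chars, 8), dreg, "top"), "dcm-")
  # a region without CCWGG on that strand -> NA
  reg0 <- toy_region()
  expect_true(is.na(classify_dcm(reg0$sequence, reg0, "top")))
  # dcm retention does not touch conversion efficiency (context excluded)
  expect_equal(conversion_efficiency(conv(chars, c(8, 19, 30)), dreg, "top"), 1.0)
})

test_that("calls reproduce simulated truth exactly at perfect conversion", {
  reg <- bundled_regions()$SNRPN_synthetic
  m <- build_preference_model("3B-like", 1.5)
  p <- simulation_params(n_molecules = 40, conversion_rate = 1,
                         inappropriate_conversion = 0, seed = 5)
  sim <- simulate_molecules(reg, m, p)
  calls <- call_clones(sim$reads, reg)
  expect_true(all(calls$conversion_efficiency == 1))
  expect_true(all(calls$pass_filter))
  top <- as.matrix(calls[calls$strand == "top", site_columns_t(calls)])
  bot <- as.matrix(calls[calls$strand == "bottom", site_columns_t(calls)])
  expect_identical(unname(top), unname(sim$truth$states_top))
  expect_identical(unname(bot), unname(sim$truth$states_bottom))
  expect_identical(calls$dcm_class[calls$strand == "top"] == "dcm+",
                   sim$truth$dcm_status)
})

test_that("strand assignment is perfect on realistic simulated clones", {
  reg <- bundled_regions()$pBR_synthetic
  m <- build_preference_model("3A-like", 1.5)
  p <- simulation_params(n_molecules = 100, conversion_rate = 0.99, seed = 13)
  sim <- simulate_molecules(reg, m, p)
  calls <- call_clones(sim$reads, reg)
  truth_strand <- vapply(strsplit(names(sim$reads), "|", fixed = TRUE),
                         `[`, character(1), 2L)
  expect_identical(calls$strand, truth_strand)

  # dcm+ and dcm- molecules pass the conversion filter at similar rates
  expect_lt(abs(mean(calls$pass_filter[calls$dcm_class == "dcm+"]) -
                mean(calls$pass_filter[calls$dcm_class == "dcm-"])), 0.1)
})
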