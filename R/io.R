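#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of uppercased sequences (empty for an
#'   empty file); empty records are rejected.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  dss <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(dss) == 0)) stop("FASTA contains empty sequences")
  stats::setNames(toupper(as.character(dss)), names(dss))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- names(seqs)
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Write / read a methylation call matrix as TSV
#'
#' The round trip is lossless for calls, strata labels and efficiencies.
#'
#' @param calls a [call_clones()] matrix.
#' @param path TSV path.
#' @return `write_call_matrix`: invisibly, the path; `read_call_matrix`:
#'   the restored `methylation_calls` object.
#' @export
write_call_matrix <- function(calls, path) {
  df <- as.data.frame(calls)
  attr(df, "region") <- NULL; attr(df, "sites") <- NULL
  header <- sprintf("# region=%s", attr(calls, "region") %||% "NA")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_call_matrix
#' @export
read_call_matrix <- function(path) {
  first <- readLines(path, n = 1)
  region <- sub("^# region=", "", first)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          stringsAsFactors = FALSE, na.strings = "NA")
  for (col in c("molecule_id", "strand", "dcm_class"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  sc <- grep("^s[0-9]+$", names(df))
  if (length(sc) == 0) stop("no site columns found in call matrix file")
  for (j in sc) df[[j]] <- as.integer(df[[j]])
  structure(df, region = region,
            sites = as.integer(sub("^s", "", names(df)[sc])),
            class = c("methylation_calls", "data.frame"))
}

#' Write the site definition table (BED-like)
#'
#' 0-based half-open CpG dinucleotide intervals.
#'
#' @param region a [reference_region()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_site_table <- function(region, path) {
  df <- data.frame(region = region$name, start = region$cpg_sites,
                   end = region$cpg_sites + 2L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the generator, simulation and analysis parameters of an
#' end-to-end run.  Serializable to YAML; every stochastic stage derives its
#' seed from the top-level seed.
#'
#' @param region_length,gc_fraction,min_cpg,min_dcm generator parameters
#'   (see [generate_reference()]).
#' @param profile,strength preference-model parameters.
#' @param n_molecules,maintenance_efficiency,conversion_rate,dcm_plus_fraction
#'   simulation parameters (see [simulation_params()]).
#' @param dnmt3l_exponent saturation exponent of the companion stimulated
#'   run (the baseline run always uses 1).
#' @param k flank half-width; `fraction` extreme-decile fraction;
#'   `conversion_threshold` filter threshold; `n_min` per-site floor.
#' @param word_pattern pattern scanned on the reference sequence.
#' @param seed top-level seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(region_length = 500L, gc_fraction = 0.55,
                            min_cpg = 40L, min_dcm = 1L,
                            profile = "3A-like", strength = 1.5,
                            n_molecules = 100L, maintenance_efficiency = 0.9,
                            conversion_rate = 0.991, dcm_plus_fraction = 0.5,
                            dnmt3l_exponent = 4, k = 2L, fraction = 0.10,
                            conversion_threshold = 0.95, n_min = 10L,
                            word_pattern = "NTCGGN", seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate (baseline and DNMT3L-stimulated) -> call -> filter -> stratify
#' -> per-site statistics -> extremes -> flanks -> enrichment ->
#' stimulation -> word scan, writing every table plus a run log to
#' `outdir`.  Rerunning with the same config reproduces all outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  say("config seed: %d", config$seed)
  region <- stage("reference", generate_reference(
    config$region_length, config$gc_fraction, config$min_cpg,
    seed = config$seed, min_dcm = config$min_dcm))
  say("region: %d bp, %d CpG sites, %d dcm sites (top)",
      region$length, length(region$cpg_sites), length(region$dcm_sites$top))
  model <- build_preference_model(config$profile, config$strength, k = config$k)

  par_alone <- simulation_params(
    n_molecules = config$n_molecules,
    maintenance_efficiency = config$maintenance_efficiency,
    dnmt3l_exponent = 1, conversion_rate = config$conversion_rate,
    dcm_plus_fraction = config$dcm_plus_fraction, seed = config$seed + 1L)
  par_3l <- simulation_params(
    n_molecules = config$n_molecules,
    maintenance_efficiency = config$maintenance_efficiency,
    dnmt3l_exponent = config$dnmt3l_exponent,
    conversion_rate = config$conversion_rate,
    dcm_plus_fraction = config$dcm_plus_fraction, seed = config$seed + 2L)

  sim_alone <- stage("simulate", simulate_molecules(region, model, par_alone))
  sim_3l <- stage("simulate", simulate_molecules(region, model, par_3l))
  write_simulation(sim_alone, region, file.path(outdir, "alone"))
  say("simulated %d + %d clone reads", length(sim_alone$reads), length(sim_3l$reads))

  calls_alone <- stage("call", call_clones(sim_alone$reads, region,
                                           config$conversion_threshold))
  calls_3l <- stage("call", call_clones(sim_3l$reads, region,
                                        config$conversion_threshold))
  say("conversion filter: %d/%d (alone), %d/%d (3L) pass",
      sum(calls_alone$pass_filter), nrow(calls_alone),
      sum(calls_3l$pass_filter), nrow(calls_3l))
  stopifnot(nrow(calls_alone) == length(sim_alone$reads))
  write_call_matrix(calls_alone, file.path(outdir, "calls_alone.tsv"))
  write_call_matrix(calls_3l, file.path(outdir, "calls_3L.tsv"))
  write_site_table(region, file.path(outdir, "sites.bed"))

  tab_alone <- stage("stats", site_efficiencies(calls_alone, n_min = config$n_min))
  tab_3l <- stage("stats", site_efficiencies(calls_3l, n_min = config$n_min))
  tab_alone <- rank_sites(tab_alone)
  utils::write.table(tab_alone, file.path(outdir, "site_efficiencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("overall efficiency: %.3f (alone), %.3f (3L)",
      attr(tab_alone, "overall"), attr(tab_3l, "overall"))

  ext <- stage("extremes", select_extremes(tab_alone, config$fraction))
  bg <- flank_background(region, config$k)
  hot_fl <- orient_flanks(collect_flanks(region, ext$hot, k = config$k))
  cold_fl <- orient_flanks(collect_flanks(region, ext$cold, k = config$k))
  enr_hot <- stage("enrichment", position_enrichment(hot_fl, bg))
  enr_cold <- stage("enrichment", position_enrichment(cold_fl, bg))
  enr_hot$set <- "hot"; enr_cold$set <- "cold"
  utils::write.table(rbind(enr_hot, enr_cold),
                     file.path(outdir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stim <- stage("stimulation", fold_stimulation(tab_alone, tab_3l, config$n_min))
  utils::write.table(stim$table, file.path(outdir, "stimulation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("fold range %.2f -> %.2f under DNMT3L; trend rho %.2f",
      stim$fold_range_before, stim$fold_range_after, stim$trend_rho)

  words <- stage("words", scan_words(region$sequence, config$word_pattern))
  utils::write.table(words, file.path(outdir, "words.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  writeLines(c(sprintf("methpatterns run, R %s", getRversion()), log),
             file.path(outdir, "run_log.txt"))
  invisible(list(region = region, calls_alone = calls_alone,
                 calls_3l = calls_3l, site_table = tab_alone,
                 extremes = ext, enrichment_hot = enr_hot,
                 enrichment_cold = enr_cold, stimulation = stim,
                 words = words))
}
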