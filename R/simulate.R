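#' Simulation parameters for synthetic bisulfite clones
#'
#' @param n_molecules number of double-stranded molecules to simulate (each
#'   contributes one top-strand and one bottom-strand clone read).
#' @param maintenance_efficiency probability that a hemimethylated CpG is
#'   converted to fully methylated by maintenance methylation (mu).
#' @param dnmt3l_exponent saturation exponent applied to true per-site
#'   probabilities before drawing (1 = no DNMT3L; see [apply_dnmt3l()]).
#' @param conversion_rate probability that an unmethylated cytosine reads as
#'   T after bisulfite treatment (the study-level value is 0.991).
#' @param inappropriate_conversion probability that a methylated cytosine
#'   nevertheless reads as T.
#' @param dcm_plus_fraction fraction of molecules carrying dcm marks on both
#'   strands (old, transfected DNA; dcm- molecules model newly replicated
#'   strands and carry none).
#' @param seed RNG seed; identical parameters imply byte-identical output.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(n_molecules = 100L,
                              maintenance_efficiency = 0.9,
                              dnmt3l_exponent = 1,
                              conversion_rate = 0.991,
                              inappropriate_conversion = 0,
                              dcm_plus_fraction = 0.5,
                              seed = 1L) {
  pr <- c(maintenance_efficiency, conversion_rate,
          inappropriate_conversion, dcm_plus_fraction)
  if (any(pr < 0 | pr > 1)) stop("all probability parameters must lie in [0, 1]")
  if (dnmt3l_exponent < 1) stop("dnmt3l_exponent must be >= 1")
  if (n_molecules < 0) stop("n_molecules must be >= 0")
  structure(list(n_molecules = as.integer(n_molecules),
                 maintenance_efficiency = maintenance_efficiency,
                 dnmt3l_exponent = dnmt3l_exponent,
                 conversion_rate = conversion_rate,
                 inappropriate_conversion = inappropriate_conversion,
                 dcm_plus_fraction = dcm_plus_fraction,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Simulate bisulfite clone reads from a preference model
#'
#' For each molecule, de novo methylation is drawn independently per strand
#' per CpG site with the model's true probability (after the optional DNMT3L
#' saturation transform); hemimethylated sites then become fully methylated
#' with probability `maintenance_efficiency`, producing the strand symmetry
#' maintenance methylation creates in vivo.  dcm status is drawn per
#' molecule; dcm+ molecules keep the internal C of every CCWGG methylated on
#' both strands.  Each strand is finally bisulfite-converted with
#' [bisulfite_read()].  Deterministic given the seed.
#'
#' @param region a [reference_region()].
#' @param model a [build_preference_model()] object.
#' @param params a [simulation_params()] object.
#' @return object of class `clone_simulation`: list with
#'   \describe{
#'     \item{reads}{named character vector, one read per molecule-strand;
#'       names follow `molecule|strand|dcm+`/`dcm-`. Bottom-strand reads are
#'       written 5'->3' on the bottom strand.}
#'     \item{truth}{list with `p_top`/`p_bottom` (per-site true probability
#'       tables from [site_probabilities()], post-DNMT3L), `states_top`/
#'       `states_bottom` (molecules x sites 0/1 matrices), `dcm_status`
#'       (logical per molecule), and `strand_of` (named strand per read).}
#'   }
#' @export
simulate_molecules <- function(region, model, params) {
  stopifnot(inherits(region, "reference_region"),
            inherits(model, "flank_preference"),
            inherits(params, "simulation_params"))
  n <- params$n_molecules
  nsite <- length(region$cpg_sites)
  truth_top <- site_probabilities(model, region, "top")
  truth_bot <- site_probabilities(model, region, "bottom")
  truth_top$p <- apply_dnmt3l(truth_top$p, params$dnmt3l_exponent)
  truth_bot$p <- apply_dnmt3l(truth_bot$p, params$dnmt3l_exponent)

  with_seed(params$seed, {
    st <- matrix(stats::runif(n * nsite) < rep(truth_top$p, each = n),
                 nrow = n, ncol = nsite)
    sb <- matrix(stats::runif(n * nsite) < rep(truth_bot$p, each = n),
                 nrow = n, ncol = nsite)
    hemi <- xor(st, sb)
    keep <- hemi & (matrix(stats::runif(n * nsite), n, nsite) <
                      params$maintenance_efficiency)
    st[keep] <- TRUE; sb[keep] <- TRUE
    dcm <- stats::runif(n) < params$dcm_plus_fraction

    reads <- character(2 * n)
    nms <- character(2 * n)
    for (i in seq_len(n)) {
      tag <- if (dcm[i]) "dcm+" else "dcm-"
      id <- sprintf("mol%04d", i)
      reads[2 * i - 1] <- bisulfite_read(region, "top", st[i, ], dcm[i], params)
      nms[2 * i - 1] <- paste(id, "top", tag, sep = "|")
      reads[2 * i] <- bisulfite_read(region, "bottom", sb[i, ], dcm[i], params)
      nms[2 * i] <- paste(id, "bottom", tag, sep = "|")
    }
    names(reads) <- nms
    structure(list(
      reads = reads,
      truth = list(p_top = truth_top, p_bottom = truth_bot,
                   states_top = st * 1L, states_bottom = sb * 1L,
                   dcm_status = dcm)
    ), class = "clone_simulation")
  })
}

#' Bisulfite-convert one simulated strand
#'
#' Unmethylated cytosines read as T with probability `conversion_rate`
#' (retained C models conversion failure); methylated cytosines (CpG state 1,
#' plus dcm internal Cs on dcm+ molecules) read as T with probability
#' `inappropriate_conversion`.  Non-cytosine bases are copied verbatim.
#' Bottom-strand reads are emitted 5'->3' on the bottom strand.
#'
#' @param region a [reference_region()].
#' @param strand `"top"` or `"bottom"`.
#' @param cpg_state 0/1 (or logical) methylation state per CpG site of that
#'   strand, in `region$cpg_sites` order.
#' @param dcm_plus logical: does this molecule carry dcm marks?
#' @param params a [simulation_params()] object.
#' @return converted read string.
#' @export
bisulfite_read <- function(region, strand = c("top", "bottom"), cpg_state,
                           dcm_plus = FALSE, params = simulation_params()) {
  strand <- match.arg(strand)
  L <- region$length
  cpg_state <- as.logical(cpg_state)
  if (length(cpg_state) != length(region$cpg_sites))
    stop("cpg_state must have one entry per CpG site")

  if (strand == "top") {
    chars <- strsplit(region$sequence, "")[[1]]
    meth_idx <- region$cpg_sites[cpg_state] + 1L      # 1-based
    dcm_idx <- if (dcm_plus) region$dcm_sites$top + 1L else integer(0)
  } else {
    chars <- strsplit(revcomp(region$sequence), "")[[1]]
    # top 0-based coordinate i maps to bottom 1-based index L - i
    meth_idx <- L - (region$cpg_sites[cpg_state] + 1L)
    dcm_idx <- if (dcm_plus) L - region$dcm_sites$bottom else integer(0)
  }
  c_idx <- which(chars == "C")
  meth <- c_idx %in% c(meth_idx, dcm_idx)
  u <- stats::runif(length(c_idx))
  convert <- ifelse(meth, u < params$inappropriate_conversion,
                    u < params$conversion_rate)
  chars[c_idx[convert]] <- "T"
  paste(chars, collapse = "")
}

#' Write simulated clones and truth tables to disk
#'
#' @param sim a [simulate_molecules()] result.
#' @param region the region it was simulated from.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, region, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    reference = file.path(dir, paste0(region$name, ".fasta")),
    clones = file.path(dir, paste0(region$name, "_clones.fasta")),
    truth = file.path(dir, paste0(region$name, "_truth.tsv")),
    states = file.path(dir, paste0(region$name, "_states.tsv"))
  )
  write_fasta(stats::setNames(region$sequence, region$name), paths["reference"])
  write_fasta(sim$reads, paths["clones"])
  truth <- rbind(sim$truth$p_top, sim$truth$p_bottom)
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  states <- data.frame(
    molecule = rep(sprintf("mol%04d", seq_len(nrow(sim$truth$states_top))), 2),
    strand = rep(c("top", "bottom"), each = nrow(sim$truth$states_top)),
    dcm = rep(ifelse(sim$truth$dcm_status, "dcm+", "dcm-"), 2),
    rbind(sim$truth$states_top, sim$truth$states_bottom), check.names = FALSE)
  names(states)[-(1:3)] <- sprintf("s%d", region$cpg_sites)
  utils::write.table(states, paths["states"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
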