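#' Orient a clone read into top-strand coordinates
#'
#' Bisulfite PCR clones may be sequenced in either orientation.  The read (or
#' its reverse complement) is chosen by identity to the reference at A/T
#' positions, which bisulfite conversion never touches.
#'
#' @param read clone read, gaplessly matching the reference length.
#' @param region a [reference_region()].
#' @return list with `seq` (read in top-strand coordinates) and `flipped`.
#' @export
orient_read <- function(read, region) {
  read <- toupper(read)
  if (nchar(read) != region$length)
    stop(sprintf("read length %d does not match reference length %d",
                 nchar(read), region$length))
  ref <- strsplit(region$sequence, "")[[1]]
  at <- ref %in% c("A", "T")
  fwd <- strsplit(read, "")[[1]]
  rev <- strsplit(revcomp(read), "")[[1]]
  if (sum(fwd[at] == ref[at]) >= sum(rev[at] == ref[at]))
    list(seq = read, flipped = FALSE)
  else list(seq = revcomp(read), flipped = TRUE)
}

#' Assign the sequenced strand of a clone read
#'
#' With the read in top-strand coordinates, a top-strand clone shows
#' reference Cs as Ts (bisulfite conversion of the top strand) while a
#' bottom-strand clone shows reference Gs as As (conversion of the bottom
#' strand viewed in top coordinates).  The strand with more conversion
#' evidence wins.
#'
#' @param read clone read in top-strand coordinates (see [orient_read()]).
#' @param region a [reference_region()].
#' @return `"top"`, `"bottom"`, or `NA` (with a warning) on a tie or when no
#'   conversion evidence exists.
#' @export
assign_strand <- function(read, region) {
  read <- toupper(read)
  if (nchar(read) != region$length)
    stop("read length does not match reference length")
  ref <- strsplit(region$sequence, "")[[1]]
  rd <- strsplit(read, "")[[1]]
  top_ev <- sum(ref == "C" & rd == "T")
  bot_ev <- sum(ref == "G" & rd == "A")
  if (top_ev == bot_ev) {
    warning("strand assignment tie (or no conversion evidence); returning NA")
    return(NA_character_)
  }
  if (top_ev > bot_ev) "top" else "bottom"
}

## Eligible cytosine positions (1-based, top coordinates) for conversion
## accounting: cytosines of the given strand excluding CpG-context and the
## dcm-methylatable internal C of CCWGG, which a dcm+ strand legitimately
## retains.
eligible_positions <- function(region, strand) {
  ref <- strsplit(region$sequence, "")[[1]]
  if (strand == "top") {
    pos <- which(ref == "C")
    excl <- c(region$cpg_sites + 1L, region$dcm_sites$top + 1L)
  } else {
    pos <- which(ref == "G")
    excl <- c(region$cpg_sites + 2L, region$dcm_sites$bottom + 1L)
  }
  setdiff(pos, excl)
}

#' Call per-CpG methylation for one clone read
#'
#' At each CpG site a retained C (top strand) or retained G (bottom strand,
#' top coordinates) is called methylated, the converted base unmethylated,
#' and any other base missing.  Conversion efficiency is the fraction of
#' eligible cytosines (non-CpG-context, non-dcm-context cytosines of that
#' strand) that were converted; dcm-site retention is tallied for
#' [classify_dcm()].
#'
#' @param read clone read in top-strand coordinates.
#' @param region a [reference_region()].
#' @param strand `"top"` or `"bottom"`.
#' @return list with `calls` (integer 1/0/NA per site, named by 0-based site
#'   position), `conversion_efficiency`, `dcm_retained`, `dcm_total`.
#' @export
call_molecule <- function(read, region, strand = c("top", "bottom")) {
  strand <- match.arg(strand)
  read <- toupper(read)
  if (nchar(read) != region$length)
    stop(sprintf("read length %d does not match reference length %d",
                 nchar(read), region$length))
  rd <- strsplit(read, "")[[1]]

  if (strand == "top") {
    site_idx <- region$cpg_sites + 1L
    meth_base <- "C"; unmeth_base <- "T"
    dcm_idx <- region$dcm_sites$top + 1L
  } else {
    site_idx <- region$cpg_sites + 2L
    meth_base <- "G"; unmeth_base <- "A"
    dcm_idx <- region$dcm_sites$bottom + 1L
  }
  obs <- rd[site_idx]
  calls <- ifelse(obs == meth_base, 1L, ifelse(obs == unmeth_base, 0L, NA_integer_))
  names(calls) <- sprintf("s%d", region$cpg_sites)

  elig <- eligible_positions(region, strand)
  obs_e <- rd[elig]
  converted <- sum(obs_e == unmeth_base)
  retained <- sum(obs_e == meth_base)
  eff <- if (converted + retained == 0) NA_real_ else converted / (converted + retained)

  dcm_obs <- rd[dcm_idx]
  list(calls = calls,
       conversion_efficiency = eff,
       dcm_retained = sum(dcm_obs == meth_base),
       dcm_total = length(dcm_idx))
}

#' Per-molecule bisulfite conversion efficiency
#'
#' @inheritParams call_molecule
#' @return fraction of eligible cytosines converted, or `NA` (with a
#'   warning) when the strand has no eligible cytosines.
#' @export
conversion_efficiency <- function(read, region, strand) {
  eff <- call_molecule(read, region, strand)$conversion_efficiency
  if (is.na(eff)) warning("no eligible cytosines on this strand; efficiency NA")
  eff
}

#' Classify a clone read as dcm+ or dcm-
#'
#' dcm+ (old, transfected) strands retain the internal C of CCWGG as
#' methylated; newly replicated strands lose the mark.  The read is dcm+
#' when the retained fraction of strand-appropriate dcm-context cytosines is
#' at least `retention_threshold`.
#'
#' @inheritParams call_molecule
#' @param retention_threshold retained fraction at or above which the read
#'   is called dcm+ (default 0.5).
#' @return `"dcm+"`, `"dcm-"`, or `NA` when the strand carries no dcm sites.
#' @export
classify_dcm <- function(read, region, strand, retention_threshold = 0.5) {
  cm <- call_molecule(read, region, strand)
  if (cm$dcm_total == 0) return(NA_character_)
  if (cm$dcm_retained / cm$dcm_total >= retention_threshold) "dcm+" else "dcm-"
}

#' Build a methylation call matrix from clone reads
#'
#' Orients each read into top-strand coordinates, assigns its strand, calls
#' per-CpG methylation, computes conversion efficiency and dcm class, and
#' applies the conversion filter.  Reads whose strand cannot be assigned are
#' kept with `strand = NA` and fail the filter.
#'
#' @param reads named character vector of clone reads (names become molecule
#'   ids; a `id|strand|dcm` FASTA-style name keeps only the id token).
#' @param region a [reference_region()].
#' @param threshold conversion-efficiency filter threshold (inclusive;
#'   default 0.95).
#' @return object of class `methylation_calls`: data frame with columns
#'   `molecule_id`, `strand`, `dcm_class`, `conversion_efficiency`,
#'   `pass_filter`, then one 1/0/NA column per CpG site (`s<position>`),
#'   with attributes `region` (name) and `sites` (0-based positions).
#' @export
call_clones <- function(reads, region, threshold = 0.95) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%04d", seq_along(reads))
  ids <- vapply(strsplit(ids, "|", fixed = TRUE), `[`, character(1), 1L)

  nsite <- length(region$cpg_sites)
  call_mat <- matrix(NA_integer_, nrow = length(reads), ncol = nsite)
  strand <- character(length(reads))
  eff <- numeric(length(reads))
  dcm <- character(length(reads))
  for (i in seq_along(reads)) {
    orp <- orient_read(reads[[i]], region)
    s <- suppressWarnings(assign_strand(orp$seq, region))
    strand[i] <- s
    if (is.na(s)) { eff[i] <- NA_real_; dcm[i] <- NA_character_; next }
    cm <- call_molecule(orp$seq, region, s)
    call_mat[i, ] <- cm$calls
    eff[i] <- cm$conversion_efficiency
    dcm[i] <- if (cm$dcm_total == 0) NA_character_ else
      if (cm$dcm_retained / cm$dcm_total >= 0.5) "dcm+" else "dcm-"
  }
  out <- data.frame(molecule_id = ids, strand = strand, dcm_class = dcm,
                    conversion_efficiency = eff,
                    pass_filter = !is.na(eff) & eff >= threshold,
                    stringsAsFactors = FALSE)
  call_df <- as.data.frame(call_mat)
  names(call_df) <- sprintf("s%d", region$cpg_sites)
  out <- cbind(out, call_df)
  structure(out, region = region$name, sites = region$cpg_sites,
            class = c("methylation_calls", "data.frame"))
}

#' Apply (or re-apply) the conversion-efficiency filter
#'
#' @param calls a [call_clones()] matrix.
#' @param threshold inclusive pass threshold ("no less than 95% conversion"
#'   reads as >= 0.95).
#' @return the matrix with `pass_filter` recomputed.
#' @export
filter_molecules <- function(calls, threshold = 0.95) {
  calls$pass_filter <- !is.na(calls$conversion_efficiency) &
    calls$conversion_efficiency >= threshold
  calls
}

## Column indices of per-site call columns.
site_columns <- function(calls) grep("^s[0-9]+$", names(calls))

#' Per-molecule overall methylation efficiency
#'
#' The unit of analysis for group-level stimulation tests: the fraction of
#' informative CpG calls that are methylated, per passing molecule.
#'
#' @param calls a [call_clones()] matrix.
#' @param pass_only use only molecules passing the conversion filter.
#' @return named numeric vector (molecule ids), NA for molecules with no
#'   informative calls.
#' @export
molecule_efficiencies <- function(calls, pass_only = TRUE) {
  if (pass_only) calls <- calls[calls$pass_filter, , drop = FALSE]
  m <- as.matrix(calls[, site_columns(calls), drop = FALSE])
  stats::setNames(rowMeans(m, na.rm = TRUE), calls$molecule_id)
}
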