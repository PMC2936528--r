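#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings over A/C/G/T.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a reference region with indexed CpG and dcm sites
#'
#' A region is a named DNA sequence with 0-based coordinates for the C of
#' every CG dinucleotide on the top strand (CG is its own reverse complement,
#' so one index serves both strands) and for the dcm-methylatable internal C
#' of every CCWGG (W = A or T) occurrence on each strand.  CCWGG is
#' self-complementary as a pattern set, so each top-strand occurrence at
#' 0-based start s carries a top-strand internal C at s+1 and a bottom-strand
#' internal C opposite top coordinate s+3.
#'
#' @param name region identifier.
#' @param sequence DNA string over A/C/G/T (case-insensitive).
#' @return an object of class `reference_region`: list with `name`,
#'   `sequence`, `length`, `cpg_sites` (0-based top-strand C positions) and
#'   `dcm_sites` (list with `top` and `bottom` 0-based internal-C positions,
#'   both in top-strand coordinates).
#' @export
reference_region <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("reference sequence contains characters outside A/C/G/T")
  cpg <- find_all(sequence, "CG")
  dcm_start <- sort(c(find_all(sequence, "CCAGG"), find_all(sequence, "CCTGG")))
  structure(list(
    name = name,
    sequence = sequence,
    length = nchar(sequence),
    cpg_sites = cpg,
    dcm_sites = list(top = dcm_start + 1L, bottom = dcm_start + 3L)
  ), class = "reference_region")
}

## All 0-based start positions of fixed pattern `pat` in `s` (overlapping).
find_all <- function(s, pat) {
  hits <- integer(0)
  from <- 1L
  repeat {
    m <- regexpr(pat, substring(s, from), fixed = TRUE)
    if (m == -1L) break
    hits <- c(hits, from + as.integer(m) - 2L)  # 0-based
    from <- from + as.integer(m)                # step one past the match start
  }
  hits
}

#' @export
print.reference_region <- function(x, ...) {
  cat(sprintf("<reference_region> %s: %d bp, %d CpG sites, %d/%d dcm sites (top/bottom)\n",
              x$name, x$length, length(x$cpg_sites),
              length(x$dcm_sites$top), length(x$dcm_sites$bottom)))
  invisible(x)
}

#' Generate a random episome-like reference region
#'
#' Bases are drawn i.i.d. with the requested GC fraction; generation is
#' retried until the region carries at least `min_cpg` CpG sites (and
#' optionally `min_dcm` dcm sites per strand), failing explicitly if the
#' constraint is unattainable within `max_tries` draws.
#'
#' @param length region length in bp (>= 20).
#' @param gc_fraction target GC fraction, strictly inside (0, 1).
#' @param min_cpg minimum number of CG dinucleotides required.
#' @param seed RNG seed (generation is deterministic given the seed).
#' @param min_dcm minimum number of CCWGG occurrences required (default 0).
#' @param max_tries bounded number of redraws before failing.
#' @param name region name.
#' @return a [reference_region()].
#' @export
generate_reference <- function(length, gc_fraction, min_cpg = 0L, seed = 1L,
                               min_dcm = 0L, max_tries = 100L,
                               name = sprintf("synthetic_%dbp", length)) {
  stopifnot(is.numeric(length), length(length) == 1L)
  if (length < 20) stop("region length must be >= 20 bp")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be strictly inside (0, 1)")
  probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
             G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      seq <- paste(sample(BASES, length, replace = TRUE, prob = probs),
                   collapse = "")
      reg <- reference_region(name, seq)
      if (length(reg$cpg_sites) >= min_cpg &&
          length(reg$dcm_sites$top) >= min_dcm)
        return(reg)
    }
    stop(sprintf(
      "could not generate a %d bp region with >= %d CpG and >= %d dcm sites in %d tries",
      length, min_cpg, min_dcm, max_tries))
  })
}

#' Load the bundled synthetic stand-in regions
#'
#' The study's episomal test-region sequences are not deposited; the package
#' bundles synthetic stand-ins (constructed, labelled `*_synthetic`) that
#' match the published coarse properties: a ~500 bp pBR322-like region with
#' 48 CpG sites, a ~500 bp Hygro-like region with 47 CpG sites, a ~300 bp
#' SNRPN-like region with 23 CpG sites and a ~500 bp TIMELESS-like region
#' with 12 CpG sites.
#'
#' @return named list of [reference_region()] objects.
#' @export
bundled_regions <- function() {
  path <- system.file("extdata", "regions_synthetic.fasta",
                      package = "methpatterns")
  seqs <- read_fasta(path)
  out <- lapply(names(seqs), function(nm) reference_region(nm, seqs[[nm]]))
  names(out) <- names(seqs)
  out
}
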