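#' Build a flanking-sequence preference model
#'
#' The per-site methylation probability is a logistic function of a baseline
#' log-odds plus additive contributions from the bases observed at offsets
#' around the target CpG (offset 0, the CpG itself, is excluded).  The
#' `"3A-like"` profile plants DNMT3A-style selectivity at offsets -2/+2
#' (T at -2 and C at +2 favoured, A at -2 and G at +2 disfavoured); the -2
#' position dominates and the +2 effects are planted at half weight, since
#' DNMT3A discriminates primarily through -2 and only to a lesser degree
#' through +2.  The `"3B-like"` profile plants DNMT3B-style selectivity at
#' -1/+1 (T at -1 and G at +1 favoured, C at +1 disfavoured); `"null"` has
#' no flank effects.
#'
#' @param profile one of `"3A-like"`, `"3B-like"`, `"null"`.
#' @param strength effect size on the log-odds scale (>= 0).
#' @param baseline baseline log-odds; the default gives a ~15% per-site
#'   methylation probability under the null profile.
#' @param k flank half-width; effects are defined at offsets -k..-1, +1..+k.
#' @return object of class `flank_preference`: list with `baseline`,
#'   `effects` (offsets x bases matrix of log-odds), `enzyme_label`, `k`.
#' @export
build_preference_model <- function(profile = c("3A-like", "3B-like", "null"),
                                   strength = 1, baseline = stats::qlogis(0.15),
                                   k = 2L) {
  profile <- match.arg(profile)
  stopifnot(strength >= 0, k >= 1)
  offsets <- c(-(k:1), 1:k)
  eff <- matrix(0, nrow = length(offsets), ncol = 4,
                dimnames = list(as.character(offsets), BASES))
  if (profile == "3A-like") {
    if (k < 2) stop("3A-like profile needs k >= 2 (effects at -2/+2)")
    eff["-2", "T"] <- +strength
    eff["-2", "A"] <- -strength
    eff["2",  "C"] <- +strength / 2
    eff["2",  "G"] <- -strength / 2
  } else if (profile == "3B-like") {
    eff["1",  "G"] <- +strength
    eff["1",  "C"] <- -strength
    eff["-1", "T"] <- +strength
  }
  structure(list(baseline = baseline, effects = eff,
                 enzyme_label = profile, k = as.integer(k)),
            class = "flank_preference")
}

#' @export
print.flank_preference <- function(x, ...) {
  cat(sprintf("<flank_preference> %s, baseline %.3f (p0 = %.3f), k = %d\n",
              x$enzyme_label, x$baseline, stats::plogis(x$baseline), x$k))
  nz <- which(x$effects != 0, arr.ind = TRUE)
  if (nrow(nz)) {
    for (i in seq_len(nrow(nz)))
      cat(sprintf("  offset %s, base %s: %+0.2f\n",
                  rownames(x$effects)[nz[i, 1]], colnames(x$effects)[nz[i, 2]],
                  x$effects[nz[i, 1], nz[i, 2]]))
  } else cat("  no flank effects\n")
  invisible(x)
}

#' True methylation probability at one CpG site
#'
#' Evaluates the logistic model on the flank context read 5'->3' on the
#' requested strand.  Sites too close to the region edge to have k bases of
#' context on each side fall back to the baseline probability and are
#' flagged via the `"edge"` attribute.
#'
#' @param model a [build_preference_model()] object.
#' @param region a [reference_region()].
#' @param site 1-based index into `region$cpg_sites`.
#' @param strand `"top"` or `"bottom"`.
#' @return probability in (0, 1), with attribute `edge` = TRUE if the site
#'   lacked full flank context.
#' @export
site_probability <- function(model, region, site, strand = "top") {
  stopifnot(inherits(model, "flank_preference"),
            inherits(region, "reference_region"))
  if (site < 1 || site > length(region$cpg_sites))
    stop(sprintf("site index %s out of range (region has %d CpG sites)",
                 site, length(region$cpg_sites)))
  fl <- suppressWarnings(extract_flanks(region, site, strand, model$k))
  if (is.na(fl))
    return(structure(stats::plogis(model$baseline), edge = TRUE))
  lo <- model$baseline + flank_logodds(model, fl)
  structure(stats::plogis(lo), edge = FALSE)
}

## Sum of flank effects for one oriented flank string of length 2k+2.
flank_logodds <- function(model, flank) {
  k <- model$k
  chars <- strsplit(flank, "")[[1]]
  offs <- rownames(model$effects)
  up <- chars[1:k]                    # offsets -k..-1
  dn <- chars[(k + 3):(2 * k + 2)]    # offsets +1..+k
  sum(model$effects[cbind(match(as.character(-(k:1)), offs), match(up, BASES))]) +
    sum(model$effects[cbind(match(as.character(1:k), offs), match(dn, BASES))])
}

#' Per-site true probabilities for a whole region
#'
#' @inheritParams site_probability
#' @return data frame with `site` (1-based index), `position` (0-based
#'   top-strand C coordinate), `strand`, `p` and `edge`.
#' @export
site_probabilities <- function(model, region, strand = "top") {
  n <- length(region$cpg_sites)
  p <- numeric(n); edge <- logical(n)
  for (i in seq_len(n)) {
    pi <- site_probability(model, region, i, strand)
    p[i] <- pi; edge[i] <- attr(pi, "edge")
  }
  data.frame(site = seq_len(n), position = region$cpg_sites,
             strand = strand, p = p, edge = edge)
}

#' DNMT3L saturation transform
#'
#' Models DNMT3L stimulation as k independent opportunities for a site to be
#' methylated: p' = 1 - (1 - p)^k.  The transform preserves order, leaves the
#' fixed points 0 and 1 untouched, and the fold stimulation p'/p strictly
#' decreases with p for k > 1 -- poorly methylated sites gain the most,
#' flattening the pattern spread.
#'
#' @param p probability vector in [0, 1].
#' @param k saturation exponent (>= 1; k = 1 is the identity).
#' @return transformed probability vector.
#' @export
apply_dnmt3l <- function(p, k) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("probabilities must lie in [0, 1]")
  if (length(k) != 1L || k < 1) stop("dnmt3l exponent k must be >= 1")
  if (k == 1) return(p)
  1 - (1 - p)^k
}
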