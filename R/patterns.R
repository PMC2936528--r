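#' Per-site methylation efficiency table
#'
#' Counts methylated and informative calls per CpG site over a stratum of
#' molecules (optionally restricted by strand, dcm class and the conversion
#' filter).  Sites with fewer than `n_min` informative calls are flagged;
#' ranking and extreme-decile selection exclude them.
#'
#' @param calls a [call_clones()] matrix.
#' @param strand optional `"top"`/`"bottom"` restriction.
#' @param dcm_class optional `"dcm+"`/`"dcm-"` restriction.
#' @param pass_only use only molecules passing the conversion filter.
#' @param n_min minimum informative calls for a site to be rankable.
#' @return data frame with `site` (0-based position), `m` (methylated), `n`
#'   (informative), `efficiency`, `low_n`; attribute `overall` holds the
#'   stratum-level efficiency sum(m)/sum(n).
#' @export
site_efficiencies <- function(calls, strand = NULL, dcm_class = NULL,
                              pass_only = TRUE, n_min = 10L) {
  sel <- rep(TRUE, nrow(calls))
  if (pass_only) sel <- sel & calls$pass_filter
  if (!is.null(strand)) sel <- sel & !is.na(calls$strand) & calls$strand == strand
  if (!is.null(dcm_class)) sel <- sel & !is.na(calls$dcm_class) & calls$dcm_class == dcm_class
  if (!any(sel))
    stop(sprintf("empty stratum (strand=%s, dcm_class=%s, pass_only=%s)",
                 strand %||% "any", dcm_class %||% "any", pass_only))
  mat <- as.matrix(calls[sel, site_columns(calls), drop = FALSE])
  m <- colSums(mat == 1L, na.rm = TRUE)
  n <- colSums(!is.na(mat))
  pos <- as.integer(sub("^s", "", colnames(mat)))
  out <- data.frame(site = pos, m = m, n = n,
                    efficiency = ifelse(n > 0, m / n, NA_real_),
                    low_n = n < n_min, row.names = NULL)
  attr(out, "overall") <- sum(m) / sum(n)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank sites by methylation efficiency
#'
#' Rank 1 is the most methylated site; ties receive average ranks, so ranks
#' always sum to N(N+1)/2.
#'
#' @param table a [site_efficiencies()] table.
#' @return the table with a `rank` column (NA for low-n sites).
#' @export
rank_sites <- function(table) {
  ok <- !table$low_n & !is.na(table$efficiency)
  table$rank <- NA_real_
  table$rank[ok] <- rank(-table$efficiency[ok], ties.method = "average")
  table
}

#' Squared rank correlation between two site tables
#'
#' The square of the Pearson correlation computed on rank vectors (i.e. the
#' squared Spearman correlation), as used to compare replicate samples and
#' +/- DNMT3L conditions.  The signed r is reported alongside since r^2
#' hides direction.
#'
#' @param a,b [site_efficiencies()] tables over the same sites (ranked or
#'   not; ranks are computed if absent).
#' @return list with `r` (signed) and `r_squared`, or NAs (with a warning)
#'   given fewer than 3 shared rankable sites or zero rank variance.
#' @export
rank_correlation <- function(a, b) {
  if (is.null(a$rank)) a <- rank_sites(a)
  if (is.null(b$rank)) b <- rank_sites(b)
  mg <- merge(a[, c("site", "rank")], b[, c("site", "rank")], by = "site")
  mg <- mg[stats::complete.cases(mg), ]
  if (nrow(mg) < 3) {
    warning("fewer than 3 shared rankable sites; rank correlation NA")
    return(list(r = NA_real_, r_squared = NA_real_))
  }
  if (stats::sd(mg$rank.x) == 0 || stats::sd(mg$rank.y) == 0) {
    warning("zero rank variance; rank correlation NA")
    return(list(r = NA_real_, r_squared = NA_real_))
  }
  r <- stats::cor(mg$rank.x, mg$rank.y)
  list(r = r, r_squared = r^2)
}

## Efficiencies with the Haldane pseudocount applied to zero-count sites
## only; used for ratio computations, never for reported efficiencies.
haldane_eff <- function(m, n) ifelse(m == 0, 0.5 / (n + 1), m / n)

#' Fold range between the most and least methylated sites
#'
#' The ratio of the highest to the lowest per-site efficiency.  Zero-count
#' sites enter via the Haldane pseudocount (m + 0.5)/(n + 1) so the ratio is
#' finite; reported efficiencies themselves are never pseudocounted.  Both
#' the unrounded fold and its nearest integer are returned (published fold
#' differences are printed as integers).
#'
#' @param x either a [site_efficiencies()] table or a bare numeric vector of
#'   efficiencies (e.g. a printed pair like c(0.285, 0.026)).
#' @param n_min minimum informative calls for a site to enter (table input).
#' @return list with `fold`, `fold_int`, `max`, `min`; NAs for an all-zero
#'   table.
#' @export
fold_range <- function(x, n_min = 10L) {
  if (is.data.frame(x)) {
    x <- x[!is.na(x$efficiency) & x$n >= n_min, , drop = FALSE]
    if (nrow(x) < 2) stop("need >= 2 sites with n >= n_min")
    e <- haldane_eff(x$m, x$n)
    if (all(x$m == 0)) return(list(fold = NA_real_, fold_int = NA_real_,
                                   max = NA_real_, min = NA_real_))
  } else {
    e <- as.numeric(x)
    if (length(e) < 2) stop("need >= 2 efficiencies")
    if (all(e == 0)) return(list(fold = NA_real_, fold_int = NA_real_,
                                 max = NA_real_, min = NA_real_))
  }
  fold <- max(e) / min(e)
  list(fold = fold, fold_int = round(fold), max = max(e), min = min(e))
}

#' Per-site fold stimulation by DNMT3L
#'
#' Pairs a baseline table with a stimulated table over the same sites and
#' computes the per-site fold f = e_3L / e_alone (Haldane-pseudocounted for
#' zero counts), the Spearman trend between baseline efficiency and fold
#' (negative when the least methylated sites gain the most), rank agreement,
#' and the fold range before and after stimulation.
#'
#' @param alone,stimulated [site_efficiencies()] tables over identical sites.
#' @param n_min minimum informative calls per site.
#' @return list with `table` (site, e_alone, e_stim, fold), `trend_rho`,
#'   `trend_p`, `rank_r_squared`, `fold_range_before`, `fold_range_after`.
#' @export
fold_stimulation <- function(alone, stimulated, n_min = 10L) {
  if (!identical(alone$site, stimulated$site))
    stop("site sets of the two tables do not match")
  keep <- alone$n >= n_min & stimulated$n >= n_min
  a <- alone[keep, , drop = FALSE]; s <- stimulated[keep, , drop = FALSE]
  ea <- haldane_eff(a$m, a$n); es <- haldane_eff(s$m, s$n)
  f <- es / ea
  tab <- data.frame(site = a$site, e_alone = a$efficiency,
                    e_stim = s$efficiency, fold = f)
  if (stats::sd(f) == 0 || stats::sd(ea) == 0) {
    rho <- NA_real_; pv <- NA_real_
  } else {
    ct <- suppressWarnings(stats::cor.test(ea, f, method = "spearman"))
    rho <- unname(ct$estimate); pv <- ct$p.value
  }
  list(table = tab,
       trend_rho = rho, trend_p = pv,
       rank_r_squared = rank_correlation(rank_sites(a), rank_sites(s))$r_squared,
       fold_range_before = fold_range(a, n_min)$fold,
       fold_range_after = fold_range(s, n_min)$fold)
}

#' Select the hot and cold extreme deciles of a ranked table
#'
#' Picks the top and bottom `ceiling(fraction * N)` rankable sites.  Ties at
#' the cut are broken by efficiency and then by ascending position, so the
#' selection is deterministic; when the two sets would overlap (tiny N with
#' a large fraction) the cold set shrinks to keep them disjoint.
#'
#' @param table a ranked [site_efficiencies()] table.
#' @param fraction selected fraction per tail, in (0, 0.5].
#' @return list with `hot` and `cold`: integer vectors of 0-based site
#'   positions.
#' @export
select_extremes <- function(table, fraction = 0.10) {
  if (fraction <= 0 || fraction > 0.5)
    stop("fraction must lie in (0, 0.5]")
  tab <- table[!table$low_n & !is.na(table$efficiency), , drop = FALSE]
  N <- nrow(tab)
  if (N < 2) stop("need at least 2 rankable sites")
  k <- ceiling(fraction * N)
  hot_ord <- tab[order(-tab$efficiency, tab$site), ]
  hot <- hot_ord$site[seq_len(k)]
  k_cold <- min(k, N - k)
  cold_ord <- tab[order(tab$efficiency, tab$site), ]
  cold_ord <- cold_ord[!cold_ord$site %in% hot, , drop = FALSE]
  cold <- cold_ord$site[seq_len(k_cold)]
  list(hot = sort(hot), cold = sort(cold))
}

#' Extract the flanking context of one CpG site
#'
#' Returns the 5'->3' context of length 2k+2 on the requested strand (k
#' bases, the central CG, k bases); the bottom-strand flank is the reverse
#' complement of the top-strand window.  Sites with fewer than k bases of
#' context return NA with a warning.
#'
#' @param region a [reference_region()].
#' @param site 1-based index into `region$cpg_sites`.
#' @param strand `"top"` or `"bottom"`.
#' @param k flank half-width.
#' @return flank string, or NA for an edge site.
#' @export
extract_flanks <- function(region, site, strand = c("top", "bottom"), k = 2L) {
  strand <- match.arg(strand)
  if (site < 1 || site > length(region$cpg_sites))
    stop("site index out of range")
  p <- region$cpg_sites[site]                 # 0-based C position
  if (p - k < 0 || p + 1 + k > region$length - 1) {
    warning(sprintf("site %d lacks %d bp of flank context; excluded", site, k))
    return(NA_character_)
  }
  win <- substring(region$sequence, p + 1 - k, p + 2 + k)
  if (strand == "top") win else revcomp(win)
}

#' Collect flanks for a set of sites, pooled over strands
#'
#' Per-strand extraction pooled across strands: a site selected on both
#' strands contributes two flanks (reverse complements of each other), as
#' when both strands of a region are analyzed.
#'
#' @param region a [reference_region()].
#' @param positions 0-based site positions (as returned by
#'   [select_extremes()]).
#' @param strands strands to extract from.
#' @param k flank half-width.
#' @return data frame of class `flank_set`: `flank`, `site`, `strand`,
#'   `orientation` (all `"direct"` until [orient_flanks()]).
#' @export
collect_flanks <- function(region, positions, strands = c("top", "bottom"),
                           k = 2L) {
  idx <- match(positions, region$cpg_sites)
  if (anyNA(idx)) stop("some positions are not CpG sites of this region")
  rows <- list()
  for (s in strands) for (i in idx) {
    fl <- suppressWarnings(extract_flanks(region, i, s, k))
    if (!is.na(fl))
      rows[[length(rows) + 1]] <- data.frame(
        flank = fl, site = region$cpg_sites[i], strand = s,
        orientation = "direct", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("flank_set", "data.frame")
  out
}

## Position frequency matrix with +0.5 pseudocounts, in log space.
flank_pfm <- function(flanks) {
  mat <- do.call(rbind, strsplit(flanks, ""))
  counts <- apply(mat, 2, function(col) table(factor(col, levels = BASES)))
  log((counts + 0.5) / rep(colSums(counts + 0.5), each = 4))
}

pfm_score <- function(flank, lpfm) {
  chars <- strsplit(flank, "")[[1]]
  sum(lpfm[cbind(match(chars, BASES), seq_along(chars))])
}

#' Orient flanks into a common direction
#'
#' Flanks can legitimately be read in direct or reverse-complement
#' orientation (the central CG is palindromic), so a shared motif may sit in
#' either reading.  The assignment is deterministic and two-phase.
#' Progressive seeding first: the position frequency matrix (PFM, +0.5
#' pseudocounts) is seeded with the first flank in its given reading and
#' each subsequent flank joins in whichever orientation scores the higher
#' log-likelihood against the running matrix (ties keep the given reading).
#' Batch refinement then iterates to a fixed point: rebuild the PFM from all
#' current readings and flip any flank whose reverse complement scores
#' strictly higher.  The seeding phase matters because a flank set closed
#' under reverse complement (every site contributing both strand readings)
#' makes the batch phase's scores exactly palindromic -- all ties, no
#' movement -- whereas an anchored seed breaks the symmetry; callers should
#' therefore order flanks by extremity so the anchor is the most extreme
#' site's own-strand reading (see [hotcold_flanks()]).  Palindromic flanks
#' always stay direct.
#'
#' @param flanks a [collect_flanks()] data frame (or character vector),
#'   ordered with the anchoring flank first.
#' @param max_iter refinement bound; non-convergence returns the current
#'   state with a warning and attribute `converged = FALSE`.
#' @return the flank set with `flank` strings re-oriented and `orientation`
#'   updated (`"direct"` or `"rc"` relative to the input).
#' @export
orient_flanks <- function(flanks, max_iter = 25L) {
  if (is.character(flanks))
    flanks <- data.frame(flank = flanks, site = NA_integer_,
                         strand = NA_character_, orientation = "direct",
                         stringsAsFactors = FALSE)
  cur <- flanks$flank
  n <- length(cur)
  flipped <- rep(FALSE, n)

  # progressive seeding against the running pseudocount matrix
  if (n > 1) {
    len <- nchar(cur[1])
    acc <- matrix(0.5, nrow = 4, ncol = len, dimnames = list(BASES, NULL))
    add_to <- function(acc, f) {
      ch <- strsplit(f, "")[[1]]
      acc[cbind(match(ch, BASES), seq_len(len))] <-
        acc[cbind(match(ch, BASES), seq_len(len))] + 1
      acc
    }
    acc <- add_to(acc, cur[1])
    for (i in 2:n) {
      lpfm <- log(acc / rep(colSums(acc), each = 4))
      if (pfm_score(revcomp(cur[i]), lpfm) > pfm_score(cur[i], lpfm)) {
        cur[i] <- revcomp(cur[i]); flipped[i] <- TRUE
      }
      acc <- add_to(acc, cur[i])
    }
  }

  # batch fixed-point refinement
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lpfm <- flank_pfm(cur)
    want_flip <- vapply(cur, function(f)
      pfm_score(revcomp(f), lpfm) > pfm_score(f, lpfm), logical(1),
      USE.NAMES = FALSE)
    if (!any(want_flip)) { converged <- TRUE; break }
    cur[want_flip] <- revcomp(cur[want_flip])
    flipped <- xor(flipped, want_flip)
  }
  if (!converged) warning("flank orientation did not converge; returning current state")
  flanks$flank <- cur
  flanks$orientation <- ifelse(flipped, "rc", "direct")
  attr(flanks, "converged") <- converged
  flanks
}

#' Extreme-decile flank sets from a call matrix
#'
#' The full hot/cold extraction pipeline: per-strand site efficiency tables,
#' per-strand ranking and extreme selection, flank extraction in each
#' strand's own 5'->3' reading, pooling across strands, and orientation
#' assignment with the most extreme site's flank as the anchor (hot flanks
#' are ordered by descending efficiency, cold by ascending, so the first
#' flank of each set is the most extreme site in its own strand's frame).
#'
#' Several regions can be pooled (as when the hot/cold analysis combines
#' multiple ~500 bp test regions) by passing lists of call matrices and
#' their matching regions.
#'
#' @param calls a [call_clones()] matrix, or a list of them (one per region).
#' @param region the matching [reference_region()], or a list of them.
#' @param fraction extreme fraction per tail (default the top/bottom 10%).
#' @param k flank half-width.
#' @param n_min minimum informative calls per site.
#' @return list with `hot` and `cold` oriented flank sets (columns gain
#'   `region` and `efficiency`), and `tables` (per-region per-strand ranked
#'   efficiency tables).
#' @export
hotcold_flanks <- function(calls, region, fraction = 0.10, k = 2L,
                           n_min = 10L) {
  if (inherits(calls, "methylation_calls")) calls <- list(calls)
  if (inherits(region, "reference_region")) region <- list(region)
  stopifnot(length(calls) == length(region))
  tabs <- list(); hot_rows <- list(); cold_rows <- list()
  for (i in seq_along(region)) {
    reg <- region[[i]]
    for (s in c("top", "bottom")) {
      tt <- rank_sites(site_efficiencies(calls[[i]], strand = s,
                                         n_min = n_min))
      tabs[[paste(reg$name, s, sep = ".")]] <- tt
      ext <- select_extremes(tt, fraction)
      for (which in c("hot", "cold")) {
        fl <- collect_flanks(reg, ext[[which]], strands = s, k = k)
        fl$efficiency <- tt$efficiency[match(fl$site, tt$site)]
        fl$region <- reg$name
        if (which == "hot") hot_rows[[length(hot_rows) + 1]] <- fl
        else cold_rows[[length(cold_rows) + 1]] <- fl
      }
    }
  }
  finish <- function(rows, hot) {
    out <- do.call(rbind, rows)
    ord <- if (hot) order(-out$efficiency, out$site)
           else order(out$efficiency, out$site)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    orient_flanks(out)
  }
  list(hot = finish(hot_rows, TRUE), cold = finish(cold_rows, FALSE),
       tables = tabs)
}

#' Background base composition of the flanking windows
#'
#' Pooled base frequencies over the +/-k flank positions (excluding the
#' central CG) of all full-context CpG sites of the region(s), on both
#' strands.  This is the "average composition of the sequence being
#' considered", conditioned on CpG context.
#'
#' @param regions a [reference_region()] or list of them.
#' @param k flank half-width.
#' @return named frequency vector over A/C/G/T summing to 1.
#' @export
flank_background <- function(regions, k = 2L) {
  if (inherits(regions, "reference_region")) regions <- list(regions)
  counts <- stats::setNames(numeric(4), BASES)
  for (reg in regions) {
    fs <- collect_flanks(reg, reg$cpg_sites, k = k)
    chars <- unlist(strsplit(fs$flank, ""))
    keep <- rep(c(rep(TRUE, k), FALSE, FALSE, rep(TRUE, k)),
                length.out = length(chars))
    tb <- table(factor(chars[keep], levels = BASES))
    counts <- counts + as.numeric(tb)
  }
  counts / sum(counts)
}

#' Positional chi-square enrichment of flank residues
#'
#' For every (offset, base) cell, tests the observed base count among the
#' flanks against the expectation from the background composition with a
#' 1-df base-versus-rest chi-square (no continuity correction); enrichment
#' versus depletion is the sign of O - E.  Raw p-values are reported per
#' cell with a Bonferroni column across the 4 x 2k cells.  Per offset, the
#' sequence-logo information content IC = 2 - H(bits) of the observed base
#' frequencies is attached (2 bits = perfect conservation, 0 = uniform),
#' with letter heights frequency x IC.
#'
#' @param flanks a flank set (data frame with `flank`, or character vector);
#'   all flanks must share one length 2k+2.
#' @param background named A/C/G/T frequency vector summing to 1 (see
#'   [flank_background()]); must be positive for every observed base.
#' @return data frame with `offset`, `base`, `observed`, `expected`,
#'   `chisq`, `p`, `p_bonferroni`, `direction`, `ic`, `letter_height`.
#' @export
position_enrichment <- function(flanks, background) {
  if (is.data.frame(flanks)) flanks <- flanks$flank
  if (length(flanks) == 0) stop("empty flank set")
  if (length(unique(nchar(flanks))) != 1) stop("flanks must share one length")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  if (length(flanks) < 5)
    warning("fewer than 5 flanks; enrichment p-values are unstable")
  len <- nchar(flanks[1])
  k <- (len - 2) / 2
  mat <- do.call(rbind, strsplit(flanks, ""))
  offsets <- c(-(k:1), 1:k)
  cols <- c(1:k, (k + 3):len)
  N <- length(flanks)
  rows <- list()
  for (j in seq_along(cols)) {
    obs <- table(factor(mat[, cols[j]], levels = BASES))
    freq <- as.numeric(obs) / N
    H <- -sum(ifelse(freq > 0, freq * log2(freq), 0))
    ic <- 2 - H
    for (b in BASES) {
      q <- background[[b]]
      O <- as.numeric(obs[[b]])
      if (q <= 0 && O > 0)
        stop(sprintf("background frequency of %s is zero but base observed", b))
      E <- N * q
      X2 <- (O - E)^2 / E + ((N - O) - (N - E))^2 / (N - E)
      rows[[length(rows) + 1]] <- data.frame(
        offset = offsets[j], base = b, observed = O, expected = E,
        chisq = X2, p = stats::pchisq(X2, df = 1, lower.tail = FALSE),
        direction = if (O >= E) "enriched" else "depleted",
        ic = ic, letter_height = freq[match(b, BASES)] * ic,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out[, c("offset", "base", "observed", "expected", "chisq", "p",
          "p_bonferroni", "direction", "ic", "letter_height")]
}

#' Strand symmetry of per-site efficiencies
#'
#' Maintenance methylation converts hemimethylated CpGs to fully methylated,
#' so efficient maintenance makes top- and bottom-strand patterns mirror
#' each other.  Reports per-site pairs and their Pearson correlation.
#'
#' @param top_table,bottom_table [site_efficiencies()] tables for the two
#'   strands over the same sites.
#' @return list with `r`, `p`, and `table` (site, e_top, e_bottom).
#' @export
strand_symmetry <- function(top_table, bottom_table) {
  mg <- merge(top_table[, c("site", "efficiency")],
              bottom_table[, c("site", "efficiency")], by = "site",
              suffixes = c("_top", "_bottom"))
  mg <- mg[stats::complete.cases(mg), ]
  if (nrow(mg) < 3 || stats::sd(mg$efficiency_top) == 0 ||
      stats::sd(mg$efficiency_bottom) == 0) {
    warning("degenerate input; strand symmetry correlation NA")
    return(list(r = NA_real_, p = NA_real_, table = mg))
  }
  ct <- stats::cor.test(mg$efficiency_top, mg$efficiency_bottom)
  list(r = unname(ct$estimate), p = ct$p.value,
       table = stats::setNames(mg, c("site", "e_top", "e_bottom")))
}

#' One-tailed group test for DNMT3L stimulation
#'
#' Two-sample one-tailed Student t-test (alternative: stimulated > alone) on
#' per-molecule overall methylation efficiencies, with the conventional star
#' category ('***' p < 0.001, '**' 0.001-0.01, '*' 0.01-0.05, 'ns').
#'
#' @param eff_alone,eff_stimulated numeric vectors of per-molecule overall
#'   efficiencies (see [molecule_efficiencies()]).
#' @return list with `statistic`, `df`, `p_value`, `stars`, `mean_alone`,
#'   `mean_stimulated`, `fold`.
#' @export
group_stimulation_test <- function(eff_alone, eff_stimulated) {
  eff_alone <- eff_alone[!is.na(eff_alone)]
  eff_stimulated <- eff_stimulated[!is.na(eff_stimulated)]
  if (length(eff_alone) < 2 || length(eff_stimulated) < 2)
    stop("need >= 2 molecules per group")
  ma <- mean(eff_alone); ms <- mean(eff_stimulated)
  if (stats::sd(eff_alone) == 0 && stats::sd(eff_stimulated) == 0) {
    if (ma == ms) {
      t <- 0; df <- length(eff_alone) + length(eff_stimulated) - 2; p <- 0.5
    } else {
      warning("degenerate variance in both groups; test NA")
      return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                  stars = NA_character_, mean_alone = ma,
                  mean_stimulated = ms, fold = ms / ma))
    }
  } else {
    tt <- stats::t.test(eff_stimulated, eff_alone, alternative = "greater",
                        var.equal = TRUE)
    t <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  stars <- if (p < 0.001) "***" else if (p <= 0.01) "**" else
    if (p <= 0.05) "*" else "ns"
  list(statistic = t, df = df, p_value = p, stars = stars,
       mean_alone = ma, mean_stimulated = ms, fold = ms / ma)
}
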