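#' Overlapping word counts of a sequence set
#'
#' Counts every word of lengths 1..h over A/C/G/T in a set of sequences,
#' pooled across sequences; windows never span sequence boundaries and
#' windows containing non-ACGT characters are skipped (with a warning).
#'
#' @param sequences character vector of DNA sequences.
#' @param h maximum word length (>= 1).
#' @return object of class `word_counts`: list with `h`, `counts` (list of
#'   named count vectors per length), `total_length`, `n_positions` (valid
#'   window totals per length).
#' @export
count_words <- function(sequences, h) {
  if (h < 1) stop("word length h must be >= 1")
  sequences <- toupper(sequences)
  if (any(grepl("[^ACGT]", sequences)))
    warning("non-ACGT characters present; windows containing them are skipped")
  dss <- Biostrings::DNAStringSet(sequences)
  counts <- lapply(seq_len(h), function(j) {
    colSums(Biostrings::oligonucleotideFrequency(dss, width = j))
  })
  structure(list(h = h, counts = counts,
                 total_length = sum(nchar(sequences)),
                 n_positions = vapply(counts, sum, numeric(1))),
            class = "word_counts")
}

## Count lookup for one word.
nw <- function(counts, w) {
  j <- nchar(w)
  if (j > counts$h) stop("word longer than counted length")
  unname(counts$counts[[j]][w])
}

#' Expected word count under the M1 (first-order Markov) model
#'
#' The plug-in estimator from the observed mono- and di-nucleotide counts:
#' E(w1..wh) = prod_i N2(w_i w_{i+1}) / prod_{i=2}^{h-1} N1(w_i).  For h = 2
#' the model reproduces the dinucleotide counts exactly.
#'
#' @param word word over A/C/G/T, length 2..h.
#' @param counts a [count_words()] object.
#' @return expected count, or NA (with a warning) when an interior letter
#'   never occurs.
#' @export
m1_expected <- function(word, counts) {
  word <- toupper(word)
  hh <- nchar(word)
  if (hh < 2) stop("M1 expectation needs word length >= 2")
  chars <- strsplit(word, "")[[1]]
  pairs <- paste0(chars[-hh], chars[-1])
  num <- prod(vapply(pairs, function(p) nw(counts, p), numeric(1)))
  if (hh == 2) return(num)
  interior <- chars[2:(hh - 1)]
  den <- vapply(interior, function(b) nw(counts, b), numeric(1))
  if (any(den == 0)) {
    if (num == 0) return(0)
    warning(sprintf("interior letter of '%s' absent from the data; expected count NA", word))
    return(NA_real_)
  }
  num / prod(den)
}

## --- first-order Markov chain machinery ----------------------------------

## Transition matrix and stationary distribution from dinucleotide counts.
fit_m1 <- function(counts) {
  n2 <- counts$counts[[2]]
  P <- matrix(n2[paste0(rep(BASES, each = 4), rep(BASES, 4))],
              nrow = 4, byrow = TRUE, dimnames = list(BASES, BASES))
  rs <- rowSums(P)
  if (any(rs == 0)) stop("some bases never occur; cannot fit M1 chain")
  P <- P / rs
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  pi <- Re(ev$vectors[, i]); pi <- pi / sum(pi)
  list(P = P, pi = stats::setNames(pi, BASES))
}

word_idx <- function(w) match(strsplit(w, "")[[1]], BASES)

## Stationary probability of a word, and its conditional part (product of
## transition steps given the first letter).
word_q <- function(idx, P) {
  if (length(idx) < 2) return(1)
  prod(P[cbind(idx[-length(idx)], idx[-1])])
}
word_p <- function(idx, pi, P) pi[idx[1]] * word_q(idx, P)

## Per-position covariance rate between occurrence counts of words u and v
## in a stationary first-order chain: sum over all lags of
## cov(I_i(u), I_{i+d}(v)), with the geometric tail summed through
## M = sum_{t>=1} (P^t - 1 pi') = Z - I, Z = (I - P + 1 pi')^{-1}.
cov_rate <- function(u, v, pi, P, M) {
  lu <- length(u); lv <- length(v)
  pu <- word_p(u, pi, P); pv <- word_p(v, pi, P)
  total <- pu * word_q(v, P) * M[u[lu], v[1]] +
           pv * word_q(u, P) * M[v[lv], u[1]]
  for (d in (-(lv - 1)):(lu - 1)) {
    # v starts at offset d relative to u; guaranteed overlap/adjacency
    lo <- min(0, d); hi <- max(lu - 1, d + lv - 1)
    merged <- rep(NA_integer_, hi - lo + 1)
    upos <- (0:(lu - 1)) - lo + 1
    vpos <- (d + 0:(lv - 1)) - lo + 1
    ok <- TRUE
    merged[upos] <- u
    for (j in seq_along(vpos)) {
      if (!is.na(merged[vpos[j]]) && merged[vpos[j]] != v[j]) { ok <- FALSE; break }
      merged[vpos[j]] <- v[j]
    }
    joint <- if (ok) word_p(merged, pi, P) else 0
    total <- total + (joint - pu * pv)
  }
  unname(total)
}

## Asymptotic variance of N(w) - Ehat(w) under M1, by the delta method on
## the joint Gaussian limit of the word, pair and interior-letter counts.
m1_variance <- function(word, counts) {
  fm <- fit_m1(counts)
  P <- fm$P; pi <- fm$pi
  Pi <- matrix(pi, 4, 4, byrow = TRUE)
  M <- solve(diag(4) - P + Pi) - diag(4)
  chars <- strsplit(word, "")[[1]]
  hh <- length(chars)
  pairs <- paste0(chars[-hh], chars[-1])
  interior <- if (hh > 2) chars[2:(hh - 1)] else character(0)
  Ehat <- m1_expected(word, counts)
  if (is.na(Ehat) || Ehat <= 0) return(NA_real_)

  # linearization: N(w) - sum_v (Ehat b_v / N2(v)) dN2(v)
  #                      + sum_u (Ehat c_u / N1(u)) dN1(u)
  coefs <- c(stats::setNames(1, word))
  for (v in unique(pairs)) {
    bv <- sum(pairs == v)
    coefs[v] <- (coefs[v] %|na|% 0) - Ehat * bv / nw(counts, v)
  }
  for (u in unique(interior)) {
    cu <- sum(interior == u)
    coefs[u] <- (coefs[u] %|na|% 0) + Ehat * cu / nw(counts, u)
  }
  words <- names(coefs)
  idxs <- lapply(words, word_idx)
  m <- length(words)
  V <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in i:m) {
    V[i, j] <- V[j, i] <- cov_rate(idxs[[i]], idxs[[j]], pi, P, M)
  }
  as.numeric(counts$total_length *
               (coefs %*% V %*% coefs))
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Word-count exceptionality score under the M1 model
#'
#' The standardized deviation z = (N_obs - E) / sd of a word's observed
#' count from its first-order Markov expectation, with the standard
#' deviation from the asymptotic Gaussian variance of the plug-in estimator
#' (derived by the delta method; every 2-letter word scores exactly 0
#' because M1 reproduces dinucleotide counts).  Positive scores flag
#' over-representation.
#'
#' @param word word over A/C/G/T (length 2..h).
#' @param counts a [count_words()] object with `h >= nchar(word)`.
#' @return one-row data frame: `word`, `observed`, `expected`, `sd`,
#'   `score`, `p`, `log10_p`.
#' @export
exceptionality_score <- function(word, counts) {
  word <- toupper(word)
  obs <- nw(counts, word)
  Ehat <- m1_expected(word, counts)
  if (is.na(Ehat) || Ehat == 0) {
    return(data.frame(word = word, observed = obs, expected = Ehat,
                      sd = NA_real_, score = NA_real_, p = NA_real_,
                      log10_p = NA_real_, stringsAsFactors = FALSE))
  }
  if (nchar(word) == 2) {
    z <- 0; sd <- 0
  } else {
    v <- m1_variance(word, counts)
    if (is.na(v) || v <= 0)
      return(data.frame(word = word, observed = obs, expected = Ehat,
                        sd = NA_real_, score = NA_real_, p = NA_real_,
                        log10_p = NA_real_, stringsAsFactors = FALSE))
    sd <- sqrt(v)
    z <- (obs - Ehat) / sd
  }
  p <- score_to_pvalue(z)
  data.frame(word = word, observed = obs, expected = Ehat, sd = sd,
             score = z, p = p, log10_p = log10(p), stringsAsFactors = FALSE)
}

#' Two-sided normal p-value of an exceptionality score
#'
#' p = 2 * Phi(-|z|); a score of 5 corresponds to ~1e-6 and a score of 10 to
#' ~1e-23 on the order-of-magnitude scale returned by [pvalue_order()].
#'
#' @param z finite score (vectorized).
#' @return two-sided p-value in (0, 1].
#' @export
score_to_pvalue <- function(z) 2 * stats::pnorm(-abs(z))

#' @rdname score_to_pvalue
#' @export
pvalue_order <- function(z) round(log10(score_to_pvalue(z)))

#' Scan a degenerate word pattern for exceptionality
#'
#' Expands a pattern over A/C/G/T/N (N = any base) into its concrete words,
#' scores each with [exceptionality_score()], and appends an aggregate row
#' (summed observed versus summed expected; its score uses the summed
#' per-word variances and ignores between-word covariance, so treat it as a
#' descriptive summary).
#'
#' @param sequences character vector of DNA sequences (or a precomputed
#'   [count_words()] object via `counts`).
#' @param pattern fixed-length pattern like `"NTCGGN"` or `"NGCGCN"`.
#' @param counts optional precomputed counts (must cover the pattern length).
#' @return data frame of per-word rows plus one `aggregate` row.
#' @export
scan_words <- function(sequences, pattern, counts = NULL) {
  pattern <- toupper(pattern)
  if (grepl("[^ACGTN]", pattern)) stop("pattern must be over A/C/G/T/N")
  hh <- nchar(pattern)
  if (hh < 2) stop("pattern must have length >= 2")
  if (is.null(counts)) counts <- count_words(sequences, hh)
  if (counts$h < hh) stop("counts do not cover the pattern length")
  words <- expand_pattern(pattern)
  rows <- do.call(rbind, lapply(words, exceptionality_score, counts = counts))
  agg_obs <- sum(rows$observed)
  agg_exp <- sum(rows$expected, na.rm = TRUE)
  agg_var <- sum(rows$sd^2, na.rm = TRUE)
  agg_z <- if (agg_var > 0) (agg_obs - agg_exp) / sqrt(agg_var) else NA_real_
  agg <- data.frame(word = pattern, observed = agg_obs, expected = agg_exp,
                    sd = sqrt(agg_var), score = agg_z,
                    p = score_to_pvalue(agg_z),
                    log10_p = log10(score_to_pvalue(agg_z)),
                    stringsAsFactors = FALSE)
  out <- rbind(rows, agg)
  rownames(out) <- NULL
  out
}

#' @rdname scan_words
#' @export
expand_pattern <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  opts <- lapply(chars, function(ch) if (ch == "N") BASES else ch)
  grid <- expand.grid(rev(opts), stringsAsFactors = FALSE)
  apply(grid[, rev(seq_along(opts)), drop = FALSE], 1, paste, collapse = "")
}

#' Simulate sequences from a first-order Markov chain
#'
#' Used for null calibration: sequences drawn from the chain fitted to real
#' data should show no exceptional words beyond chance.
#'
#' @param n_seq number of sequences.
#' @param length length of each sequence.
#' @param P 4x4 transition matrix (rows/cols A,C,G,T).
#' @param pi initial distribution; defaults to the stationary distribution
#'   of `P`.
#' @param seed RNG seed.
#' @param as_matrix return an integer matrix (1..4) instead of strings.
#' @return character vector of sequences, or an `n_seq x length` integer
#'   matrix when `as_matrix = TRUE`.
#' @export
simulate_m1 <- function(n_seq, length, P, pi = NULL, seed = 1L,
                        as_matrix = FALSE) {
  stopifnot(nrow(P) == 4, ncol(P) == 4)
  if (is.null(pi)) {
    ev <- eigen(t(P)); i <- which.min(abs(ev$values - 1))
    pi <- Re(ev$vectors[, i]); pi <- pi / sum(pi)
  }
  cumP <- t(apply(P, 1, cumsum))
  with_seed(seed, {
    X <- matrix(0L, n_seq, length)
    X[, 1] <- sample.int(4, n_seq, replace = TRUE, prob = pi)
    for (t in 2:length) {
      u <- stats::runif(n_seq)
      X[, t] <- 1L + rowSums(u > cumP[X[, t - 1], , drop = FALSE])
    }
    X[X > 4L] <- 4L
    if (as_matrix) return(X)
    apply(X, 1, function(row) paste(BASES[row], collapse = ""))
  })
}

#' CpG-island metrics of a sequence
#'
#' GC fraction and the observed/expected CpG ratio
#' rho = N(CG) * L / (N(C) * N(G)), with the operational island verdict
#' GC > 0.55 and rho > 0.8.
#'
#' @param sequence DNA string (length >= 2).
#' @return list with `gc`, `ratio`, `island`.
#' @export
island_metrics <- function(sequence) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 2) stop("sequence must have length >= 2")
  chars <- strsplit(sequence, "")[[1]]
  nC <- sum(chars == "C"); nG <- sum(chars == "G")
  gc <- (nC + nG) / L
  if (nC == 0 || nG == 0) {
    return(list(gc = gc, ratio = NA_real_, island = FALSE))
  }
  nCG <- length(find_all(sequence, "CG"))
  ratio <- nCG * L / (nC * nG)
  list(gc = gc, ratio = ratio, island = gc > 0.55 && ratio > 0.8)
}
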