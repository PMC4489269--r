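# integer window scores for one encoded sequence against an integer score
# matrix (w x letters); returns a vector over the L - w + 1 windows
score_windows_int <- function(s_int, ints) {
  w <- nrow(ints)
  m <- length(s_int) - w + 1L
  if (m < 1L) return(numeric(0))
  sc <- numeric(m)
  for (j in seq_len(w)) sc <- sc + ints[j, s_int[j:(j + m - 1L)]]
  sc
}

#' Exact null distribution of integerized PWM scores
#'
#' Computes, by position-wise convolution over the motif's integer score
#' matrix, the exact probability mass function of the total integer score of
#' a width-`w` word drawn from the background, and its right cumulative
#' tail. `p-value(s) = P(score >= s)` under that null; the smallest score
#' has p-value 1.
#'
#' @param lom A `LogOddsMatrix` from [motif_to_logodds()].
#' @param background A `Background`; defaults to the one inside `lom`.
#' @return An object of class `ScoreDistribution`: list with `pmf` and
#'   `tail` (numeric vectors over integer scores `0..max`), and `max_score`.
#' @export
score_pvalue_table <- function(lom, background = NULL) {
  if (is.null(background)) background <- lom$background
  bg <- background$frequencies
  core <- lom$motif$alphabet$core
  ints <- lom$ints[, core, drop = FALSE]
  w <- nrow(ints)
  smax <- sum(apply(ints, 1, max))
  pmf <- numeric(smax + 1L)
  pmf[1L] <- 1
  upto <- 0L
  for (i in seq_len(w)) {
    new <- numeric(smax + 1L)
    for (a in seq_along(core)) {
      s_a <- ints[i, a]
      idx <- seq_len(upto + 1L)
      new[idx + s_a] <- new[idx + s_a] + pmf[idx] * bg[a]
    }
    pmf <- new
    upto <- upto + max(ints[i, ])
  }
  tail <- rev(cumsum(rev(pmf)))
  tail <- pmin(tail, 1)
  out <- list(pmf = pmf, tail = tail, max_score = smax)
  class(out) <- "ScoreDistribution"
  out
}

#' @export
print.ScoreDistribution <- function(x, ...) {
  cat(sprintf("<ScoreDistribution: integer scores 0..%d, min p %.3g>\n",
              x$max_score, x$tail[x$max_score + 1L]))
  invisible(x)
}

# p-values for integer scores (clamped into the table's range)
score_pvalue <- function(sdist, int_scores) {
  s <- pmin(pmax(round(int_scores), 0), sdist$max_score)
  sdist$tail[s + 1L]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment `q(i) = min_{j >= i} p_(j) * m / j` clipped at 1,
#' mapped back to input order; `m` may exceed the number of reported
#' p-values when further tests were performed but not reported.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param m Total number of tests (default `length(p)`).
#' @return Numeric vector of q-values in input order.
#' @export
bh_qvalues <- function(p, m = length(p)) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p <= 0 | p > 1 | is.na(p))) stop("p-values must lie in (0, 1]")
  if (m < length(p)) stop("m must be at least the number of p-values")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Scan sequences for individual motif occurrences with exact p-values
#'
#' Every window of every sequence (both strands for nucleotide alphabets) is
#' scored against each motif's integerized log-odds matrix; the exact null
#' score distribution converts scores to p-values, and windows at or below
#' `p_threshold` are reported as hits. Minus-strand hits are given in
#' forward-strand coordinates with the matched text reverse-complemented.
#' q-values are Benjamini-Hochberg over all scored windows (not only the
#' emitted hits), per motif.
#'
#' @param motifs A `MotifFile`, a list of `Motif`s, or one `Motif`.
#' @param seqs A `SequenceSet` of the same alphabet.
#' @param background A `Background`; uniform if `NULL`.
#' @param p_threshold Report windows with `p <= p_threshold` (default 1e-4).
#' @param both_strands Scan the reverse strand too (nucleotides only).
#' @param pseudocount Total pseudocount applied to motif rows containing
#'   zeros before taking log-odds.
#' @param quantization_bins Integer score quanta for the p-value table.
#' @param skip_masked Drop windows with more than 50% wildcard letters.
#' @return A data.frame of class `MotifHits` with columns `motif_id`,
#'   `motif_alt_id`, `sequence_name`, `start`, `stop` (1-based inclusive,
#'   forward strand), `strand`, `score` (bits), `p_value`, `q_value`,
#'   `matched_sequence`; attribute `n_tests` records the number of scored
#'   windows per motif.
#' @export
scan_motifs <- function(motifs, seqs, background = NULL, p_threshold = 1e-4,
                        both_strands = TRUE, pseudocount = 0.01,
                        quantization_bins = 1000L, skip_masked = FALSE) {
  motifs <- as_motif_list(motifs)
  if (is.null(background)) background <- uniform_background(seqs$alphabet)
  nuc <- is_nucleotide(seqs$alphabet)
  both_strands <- both_strands && nuc
  res <- list()
  n_tests <- stats::setNames(numeric(length(motifs)),
                             vapply(motifs, function(m) m$name, character(1)))
  enc <- lapply(seqs$records$residues, encode_seq, alphabet = seqs$alphabet)
  wc_idx <- match(seqs$alphabet$wildcard, seqs$alphabet$letters)
  for (m in motifs) {
    if (!identical(m$alphabet$name, seqs$alphabet$name)) {
      stop("motif ", m$name, " (", m$alphabet$name, ") cannot scan ",
           seqs$alphabet$name, " sequences")
    }
    m_pos <- positive_motif(m, background, pseudocount)
    lom_f <- motif_to_logodds(m_pos, background, quantization_bins)
    sd_f <- score_pvalue_table(lom_f)
    if (both_strands) {
      lom_r <- motif_to_logodds(revcomp_motif(m_pos), background, quantization_bins)
      sd_r <- score_pvalue_table(lom_r)
    }
    w <- motif_width(m)
    hits <- list()
    total_windows <- 0
    for (si in seq_along(enc)) {
      s_int <- enc[[si]]
      if (length(s_int) < w) next
      keep <- NULL
      if (skip_masked) {
        is_wc <- as.numeric(s_int == wc_idx)
        frac <- stats::filter(is_wc, rep(1 / w, w), sides = 1)
        frac <- frac[seq(w, length(s_int))]
        keep <- frac <= 0.5
      }
      for (strand in c("+", if (both_strands) "-")) {
        lom <- if (strand == "+") lom_f else lom_r
        sdist <- if (strand == "+") sd_f else sd_r
        sc_int <- score_windows_int(s_int, lom$ints)
        if (!is.null(keep)) {
          idx_all <- which(keep)
        } else idx_all <- seq_along(sc_int)
        total_windows <- total_windows + length(idx_all)
        pv <- score_pvalue(sdist, sc_int[idx_all])
        sel <- which(pv <= p_threshold)
        if (!length(sel)) next
        starts <- idx_all[sel]
        txt <- substring(seqs$records$residues[si], starts, starts + w - 1L)
        if (strand == "-") txt <- revcomp(txt, seqs$alphabet)
        hits[[length(hits) + 1L]] <- data.frame(
          motif_id = m$name, motif_alt_id = m$alt_name,
          sequence_name = seqs$records$id[si],
          start = starts, stop = starts + w - 1L, strand = strand,
          # bit score recovered from the affine integer map
          score = w * lom$offset + lom$scale * sc_int[idx_all[sel]],
          p_value = pv[sel], q_value = NA_real_,
          matched_sequence = txt, stringsAsFactors = FALSE)
      }
    }
    n_tests[m$name] <- total_windows
    if (length(hits)) {
      h <- do.call(rbind, hits)
      h$q_value <- bh_qvalues(h$p_value, m = total_windows)
      res[[length(res) + 1L]] <- h
    }
  }
  out <- if (length(res)) do.call(rbind, res) else data.frame(
    motif_id = character(0), motif_alt_id = character(0),
    sequence_name = character(0), start = integer(0), stop = integer(0),
    strand = character(0), score = numeric(0), p_value = numeric(0),
    q_value = numeric(0), matched_sequence = character(0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_tests") <- n_tests
  class(out) <- c("MotifHits", "data.frame")
  out
}

# coerce list / MotifFile / single Motif into a plain list of Motifs
as_motif_list <- function(motifs) {
  if (inherits(motifs, "MotifFile")) return(motifs$motifs)
  if (inherits(motifs, "Motif")) return(list(motifs))
  stopifnot(is.list(motifs), all(vapply(motifs, inherits, TRUE, "Motif")))
  motifs
}

# ensure strictly positive motif probabilities before log-odds
positive_motif <- function(m, background, pseudocount = 0.01) {
  if (all(m$probs > 0)) return(m)
  counts <- m$probs * m$nsites
  bg <- background$frequencies
  probs <- sweep(counts, 2, pseudocount * bg, "+") / (m$nsites + pseudocount)
  probs <- probs / rowSums(probs)
  motif(probs, m$alphabet, name = m$name, alt_name = m$alt_name,
        nsites = m$nsites, evalue = m$evalue)
}
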