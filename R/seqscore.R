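#' Per-motif best-hit p-values for one sequence
#'
#' For each motif, the minimum window p-value over all positions (and both
#' strands, for nucleotides) is corrected for the number of windows scanned
#' via the minimum-of-uniforms tail `p_seq = 1 - (1 - p_min)^n`, clipped to
#' (0, 1]. A motif wider than the sequence contributes p = 1 and is recorded
#' in the `warnings` attribute.
#'
#' @param motifs Motifs (`MotifFile`, list, or single `Motif`).
#' @param seq_residues Character scalar: the sequence.
#' @param alphabet The sequences' `Alphabet`.
#' @param background A `Background`; uniform if `NULL`.
#' @param both_strands Scan both strands (nucleotides only).
#' @param quantization_bins Integer quanta for the p-value tables.
#' @return Named numeric vector of per-motif sequence-level p-values, with
#'   attributes `p_min`, `n_windows` and `warnings`.
#' @export
best_hit_pvalues <- function(motifs, seq_residues, alphabet, background = NULL,
                             both_strands = TRUE, quantization_bins = 1000L) {
  motifs <- as_motif_list(motifs)
  if (is.null(background)) background <- uniform_background(alphabet)
  tabs <- motif_scan_tables(motifs, background, alphabet, both_strands,
                            quantization_bins)
  res <- best_hit_pvalues_enc(tabs, encode_seq(seq_residues, alphabet))
  res
}

# precompute log-odds + p-value tables once per motif (shared by rank_sequences)
motif_scan_tables <- function(motifs, background, alphabet, both_strands,
                              quantization_bins = 1000L, pseudocount = 0.01) {
  both_strands <- both_strands && is_nucleotide(alphabet)
  lapply(motifs, function(m) {
    if (!identical(m$alphabet$name, alphabet$name)) {
      stop("motif ", m$name, " (", m$alphabet$name, ") does not match the ",
           alphabet$name, " sequences")
    }
    mp <- positive_motif(m, background, pseudocount)
    lom_f <- motif_to_logodds(mp, background, quantization_bins)
    ent <- list(name = m$name, w = motif_width(m), lom_f = lom_f,
                sd_f = score_pvalue_table(lom_f), both = both_strands)
    if (both_strands) {
      lom_r <- motif_to_logodds(revcomp_motif(mp), background, quantization_bins)
      ent$lom_r <- lom_r
      ent$sd_r <- score_pvalue_table(lom_r)
    }
    ent
  })
}

best_hit_pvalues_enc <- function(tabs, s_int) {
  p_seq <- p_min <- n_win <- stats::setNames(
    numeric(length(tabs)), vapply(tabs, function(t) t$name, character(1)))
  best <- vector("list", length(tabs))
  warn <- character(0)
  for (k in seq_along(tabs)) {
    t <- tabs[[k]]
    if (t$w > length(s_int)) {
      p_seq[k] <- 1; p_min[k] <- 1; n_win[k] <- 0
      warn <- c(warn, paste0("motif ", t$name, " wider than sequence"))
      best[[k]] <- list(start = NA_integer_, strand = "+", p = 1)
      next
    }
    pf <- score_pvalue(t$sd_f, score_windows_int(s_int, t$lom_f$ints))
    n <- length(pf)
    bi <- which.min(pf); bp <- pf[bi]; bs <- "+"
    if (t$both) {
      pr <- score_pvalue(t$sd_r, score_windows_int(s_int, t$lom_r$ints))
      n <- n + length(pr)
      if (min(pr) < bp) { bi <- which.min(pr); bp <- min(pr); bs <- "-" }
    }
    p_min[k] <- bp
    n_win[k] <- n
    p_seq[k] <- min(1, max(-expm1(n * log1p(-bp)), .Machine$double.xmin))
    best[[k]] <- list(start = bi, strand = bs, p = bp)
  }
  structure(p_seq, p_min = p_min, n_windows = n_win, warnings = warn,
            best = best)
}

#' Combine independent p-values by the product-of-uniforms tail
#'
#' With `x` the product of the `n` p-values, the exact tail of a product of
#' independent uniforms is `x * sum_{k=0}^{n-1} (-ln x)^k / k!`, evaluated
#' in log space and clipped to (0, 1].
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Combined p-value.
#' @export
combine_pvalues <- function(p) {
  if (length(p) == 0L) stop("cannot combine an empty p-value list")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  n <- length(p)
  lnx <- sum(log(p))
  if (lnx == 0) return(1)
  k <- 0:(n - 1)
  log_terms <- lnx + k * log(-lnx) - lgamma(k + 1)
  mx <- max(log_terms)
  comb <- exp(mx + log(sum(exp(log_terms - mx))))
  min(1, max(comb, .Machine$double.xmin))
}

#' Rank sequences by how well they match a set of motifs
#'
#' Each sequence gets, per motif, a window-count-corrected best-hit p-value
#' (see [best_hit_pvalues()]); the per-motif p-values are combined with
#' [combine_pvalues()] and turned into an E-value by multiplying by the
#' number of sequences scanned. Sequences are returned in ascending E-value
#' order, ties broken by identifier.
#'
#' @param motifs Motifs (`MotifFile`, list, or single `Motif`).
#' @param seqs A `SequenceSet`.
#' @param background A `Background`; uniform if `NULL`.
#' @param both_strands Scan both strands (nucleotides only).
#' @return A data.frame with columns `sequence_name`, `combined_p`,
#'   `e_value`, and one `p_<motif>` column per motif.
#' @export
rank_sequences <- function(motifs, seqs, background = NULL, both_strands = TRUE) {
  motifs <- as_motif_list(motifs)
  if (is.null(background)) background <- uniform_background(seqs$alphabet)
  tabs <- motif_scan_tables(motifs, background, seqs$alphabet, both_strands)
  N <- length(seqs)
  rows <- lapply(seq_len(N), function(i) {
    ps <- best_hit_pvalues_enc(tabs, encode_seq(seqs$records$residues[i],
                                                seqs$alphabet))
    comb <- combine_pvalues(as.numeric(ps))
    c(list(sequence_name = seqs$records$id[i], combined_p = comb,
           e_value = comb * N), as.list(stats::setNames(as.numeric(ps),
                                                        paste0("p_", names(ps)))))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  out <- out[order(out$e_value, out$sequence_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select non-overlapping diagram blocks from scan hits
#'
#' Greedy best-p-value-first selection of non-overlapping hits below
#' `p_threshold` for one sequence, with display heights proportional to
#' `-log10(p)` and truncated at the height of a p-value of `floor`
#' (so stronger sites do not grow without bound).
#'
#' @param hits A `MotifHits` data.frame restricted to one sequence.
#' @param p_threshold Keep hits with `p_value < p_threshold` (default 1e-4).
#' @param floor Height cap p-value (default 1e-10).
#' @return The selected rows, ordered by `start`, with a `height` column;
#'   attribute `diagram` holds a text rendering like `10-[+1]-35-[-2]-5`.
#' @export
diagram_blocks <- function(hits, p_threshold = 1e-4, floor = 1e-10) {
  if (nrow(hits) && length(unique(hits$sequence_name)) > 1L) {
    stop("diagram_blocks expects hits from a single sequence")
  }
  cand <- hits[hits$p_value < p_threshold, , drop = FALSE]
  cand <- cand[order(cand$p_value, cand$start), , drop = FALSE]
  sel <- logical(nrow(cand))
  occ <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$stop[i]
    if (!nrow(occ) || all(e < occ[, 1] | s > occ[, 2])) {
      sel[i] <- TRUE
      occ <- rbind(occ, c(s, e))
    }
  }
  out <- cand[sel, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  out$height <- pmin(-log10(out$p_value), -log10(floor))
  rownames(out) <- NULL
  motif_ids <- unique(hits$motif_id)
  diagram <- if (nrow(out)) {
    parts <- character(0)
    pos <- 1L
    for (i in seq_len(nrow(out))) {
      gap <- out$start[i] - pos
      if (gap > 0) parts <- c(parts, as.character(gap))
      idx <- match(out$motif_id[i], motif_ids)
      parts <- c(parts, paste0("[", out$strand[i], idx, "]"))
      pos <- out$stop[i] + 1L
    }
    paste(parts, collapse = "-")
  } else ""
  attr(out, "diagram") <- diagram
  out
}
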