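#' Best motif-site position per sequence
#'
#' For each sequence, finds the window (both strands for nucleotides) with
#' the smallest exact p-value and records its site-center offset relative to
#' the sequence midpoint. Sequences whose best p-value exceeds `p_threshold`
#' contribute `NA`. Ties are resolved toward the leftmost start, then the
#' forward strand. All sequences must have the same length, as positional
#' enrichment is only meaningful on aligned, equal-length regions (e.g.
#' fixed-width windows around ChIP-seq peak summits).
#'
#' @param motif A `Motif`.
#' @param seqs A `SequenceSet`, all sequences of one length.
#' @param background A `Background`; uniform if `NULL`.
#' @param p_threshold Site-level p-value cutoff for counting a sequence as
#'   containing a site (default 1e-3).
#' @param both_strands Scan both strands (nucleotides only).
#' @return Numeric vector (length = number of sequences) of center offsets
#'   (0 = sequence midpoint; half-integers occur when width and length have
#'   opposite parity), `NA` where no window passes the threshold.
#' @export
best_site_positions <- function(motif, seqs, background = NULL,
                                p_threshold = 1e-3, both_strands = TRUE) {
  lens <- seq_lengths(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences must all have the same length for positional enrichment ",
         "(got lengths ", min(lens), "-", max(lens), ")")
  }
  L <- lens[1]
  w <- motif_width(motif)
  if (w > L) stop("motif wider than the sequences")
  if (is.null(background)) background <- uniform_background(seqs$alphabet)
  tabs <- motif_scan_tables(list(motif), background, seqs$alphabet, both_strands)
  t <- tabs[[1]]
  c_mid <- (L - w + 2) / 2   # central admissible start
  vapply(seqs$records$residues, function(res) {
    s_int <- encode_seq(res, seqs$alphabet)
    pf <- score_pvalue(t$sd_f, score_windows_int(s_int, t$lom_f$ints))
    p_all <- pf
    strands <- rep("+", length(pf))
    if (t$both) {
      pr <- score_pvalue(t$sd_r, score_windows_int(s_int, t$lom_r$ints))
      p_all <- c(p_all, pr)
      strands <- c(strands, rep("-", length(pr)))
    }
    starts <- c(seq_along(pf), if (t$both) seq_along(pf))
    ord <- order(p_all, starts, strands)
    best <- ord[1]
    if (p_all[best] > p_threshold) return(NA_real_)
    starts[best] - c_mid
  }, numeric(1), USE.NAMES = FALSE)
}

#' Binomial test of central enrichment of site positions
#'
#' Given best-site center offsets (from [best_site_positions()]), tests every
#' centered window of admissible start positions, expanding symmetrically
#' from the midpoint, for an excess of sites: with `n` sequences carrying a
#' site and `k` of them inside a window covering a fraction `pi` of the
#' `L - w + 1` admissible positions, the p-value is the binomial right tail
#' `P(Bin(n, pi) >= k)`. The reported window minimizes p; the adjusted
#' p-value applies a Bonferroni factor for the number of windows tested.
#'
#' @param offsets Numeric center offsets (`NA` = sequence without a site).
#' @param L Sequence length.
#' @param w Motif width.
#' @param max_window Largest window size (number of start positions) to
#'   test; defaults to all admissible positions.
#' @return An object of class `CentralityResult`: list with `L`, `w`,
#'   `n_sites` (= `k`, sites in best window), `n_seqs_with_site` (= `n`),
#'   `best_halfwidth`, `window_size`, `pi`, `p_value`, `adjusted_p`,
#'   `n_windows_tested`, `histogram` (table of offsets).
#' @export
central_enrichment <- function(offsets, L, w, max_window = NULL) {
  m <- L - w + 1L
  if (is.null(max_window)) max_window <- m
  offs <- offsets[!is.na(offsets)]
  n <- length(offs)
  # candidate half-widths: the distinct |start - center| values
  c_mid <- (m + 1) / 2
  dists <- sort(unique(abs(seq_len(m) - c_mid)))
  sizes <- vapply(dists, function(h) sum(abs(seq_len(m) - c_mid) <= h + 1e-9),
                  numeric(1))
  keep <- sizes <= max_window
  dists <- dists[keep]; sizes <- sizes[keep]
  if (n == 0L || !length(dists)) {
    res <- list(L = L, w = w, n_sites = 0L, n_seqs_with_site = n,
                best_halfwidth = NA_real_, window_size = NA_integer_,
                pi = NA_real_, p_value = 1, adjusted_p = 1,
                n_windows_tested = length(dists),
                histogram = table(numeric(0)))
    class(res) <- "CentralityResult"
    return(res)
  }
  pis <- sizes / m
  ks <- vapply(dists, function(h) sum(abs(offs) <= h + 1e-9), numeric(1))
  pvals <- stats::pbinom(ks - 1, n, pis, lower.tail = FALSE)
  best <- order(pvals, dists)[1]
  res <- list(L = L, w = w, n_sites = as.integer(ks[best]),
              n_seqs_with_site = n,
              best_halfwidth = dists[best],
              window_size = as.integer(sizes[best]),
              pi = pis[best], p_value = pvals[best],
              adjusted_p = min(1, pvals[best] * length(dists)),
              n_windows_tested = length(dists),
              histogram = table(offs))
  class(res) <- "CentralityResult"
  res
}

#' @export
print.CentralityResult <- function(x, ...) {
  cat(sprintf(
    "<CentralityResult: %d/%d sites within +/-%s of center (pi=%.3f), p=%.3g, adjusted p=%.3g>\n",
    x$n_sites, x$n_seqs_with_site,
    format(x$best_halfwidth), if (is.na(x$pi)) 0 else x$pi,
    x$p_value, x$adjusted_p))
  invisible(x)
}

#' Rank motifs by central positional enrichment
#'
#' Runs [best_site_positions()] and [central_enrichment()] for every motif
#' in a database against one equal-length sequence set, ranking by adjusted
#' p-value ascending (ties by motif name). Only the positions of best motif
#' sites enter the test, so central enrichment is an independent line of
#' evidence for motifs discovered without positional information.
#'
#' @param motif_db Motifs (`MotifFile`, list, or single `Motif`).
#' @param seqs A `SequenceSet`, all sequences of one length.
#' @param background A `Background`; uniform if `NULL`.
#' @param p_threshold Site p-value cutoff (see [best_site_positions()]).
#' @param max_window Largest window tested (see [central_enrichment()]).
#' @param both_strands Scan both strands (nucleotides only).
#' @return A data.frame with one row per motif: `motif_id`,
#'   `best_halfwidth`, `window_size`, `sites`, `sequences`, `pi`, `p_value`,
#'   `adjusted_p`; attribute `results` holds the full `CentralityResult`s.
#' @export
rank_motifs_by_centrality <- function(motif_db, seqs, background = NULL,
                                      p_threshold = 1e-3, max_window = NULL,
                                      both_strands = TRUE) {
  motif_db <- as_motif_list(motif_db)
  if (!length(motif_db)) {
    return(data.frame(motif_id = character(0), best_halfwidth = numeric(0),
                      window_size = integer(0), sites = integer(0),
                      sequences = integer(0), pi = numeric(0),
                      p_value = numeric(0), adjusted_p = numeric(0)))
  }
  L <- unique(seq_lengths(seqs))
  if (length(L) != 1L) stop("sequences must all have the same length")
  results <- lapply(motif_db, function(m) {
    offs <- best_site_positions(m, seqs, background = background,
                                p_threshold = p_threshold,
                                both_strands = both_strands)
    central_enrichment(offs, L = L, w = motif_width(m),
                       max_window = max_window)
  })
  names(results) <- vapply(motif_db, function(m) m$name, character(1))
  tab <- data.frame(
    motif_id = names(results),
    best_halfwidth = vapply(results, function(r) as.numeric(r$best_halfwidth), 1),
    window_size = vapply(results, function(r) as.integer(r$window_size %||% NA), 1L),
    sites = vapply(results, function(r) r$n_sites, 1L),
    sequences = vapply(results, function(r) r$n_seqs_with_site, 1L),
    pi = vapply(results, function(r) as.numeric(r$pi), 1),
    p_value = vapply(results, function(r) r$p_value, 1),
    adjusted_p = vapply(results, function(r) r$adjusted_p, 1),
    stringsAsFactors = FALSE)
  ord <- order(tab$adjusted_p, tab$motif_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "results") <- results[tab$motif_id]
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
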