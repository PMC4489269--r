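#' Integrated motif analysis of equal-length peak sequences
#'
#' Runs, on one set of equal-length nucleotide sequences (e.g. fixed-width
#' windows around ChIP-seq peak summits): de novo discovery by seeded EM
#' ([discover_motifs()]) and by discriminative word enumeration
#' ([discover_words()]); central positional enrichment of the database
#' motifs and of every discovered motif ([rank_motifs_by_centrality()]);
#' and comparison of each discovered motif against the motif database
#' ([compare_to_database()]). The report links every discovered motif to
#' its best database match and its centrality result, the evidence pattern
#' that supports a direct-binding call: discovery uses no positional
#' information (sequences are passed in shuffled order), so central
#' enrichment is an independent check.
#'
#' @param seqs Equal-length nucleotide `SequenceSet`.
#' @param motif_db Database motifs (`MotifFile` or list of `Motif`s).
#' @param seed Integer seed; sub-stream seeds are derived from it per stage.
#' @param background A `Background`; estimated from the input if `NULL`.
#' @param em_width Width for the EM search (single width, default 8).
#' @param em_motifs,word_motifs Number of motifs per discovery engine.
#' @param n_starts EM seeds per width (default 5 at pipeline scale).
#' @param em_tol,em_max_iter EM convergence controls at pipeline scale.
#' @param centrality_threshold Adjusted-p cutoff quoted in the summary.
#' @return An object of class `PeakPipelineReport`: list with `discovered`
#'   (all discovered motifs), `em`, `words`, `centrality_db`,
#'   `centrality_discovered`, `comparisons` (per discovered motif), and
#'   `summary` (one row per discovered motif: `motif_id`, `source`,
#'   `consensus`, `evalue`, `best_match`, `match_p`, `central_adjusted_p`).
#' @export
run_peak_pipeline <- function(seqs, motif_db, seed = 1L, background = NULL,
                              em_width = 8L, em_motifs = 1L, word_motifs = 2L,
                              n_starts = 5L, centrality_threshold = 0.01,
                              em_tol = 1e-5, em_max_iter = 60L) {
  lens <- seq_lengths(seqs)
  if (length(unique(lens)) != 1L) {
    stop("the peak pipeline requires equal-length sequences ",
         "(positional enrichment is undefined otherwise)")
  }
  if (!is_nucleotide(seqs$alphabet)) stop("the peak pipeline is nucleotide-only")
  motif_db <- as_motif_list(motif_db)
  if (is.null(background)) background <- estimate_background(seqs, 1)
  sub_seed <- function(k) (as.integer(seed) * 131L + k) %% 2147483647L
  # discovery must not see positional structure beyond the sequences
  # themselves; feed it a shuffled sequence order
  ord <- withr::with_seed(sub_seed(1L), sample.int(length(seqs)))
  seqs_shuf <- sequence_set(seqs$records$id[ord], seqs$records$residues[ord],
                            alphabet = seqs$alphabet,
                            descriptions = seqs$records$description[ord])
  em <- discover_motifs(seqs_shuf, min_width = em_width, max_width = em_width,
                        n_motifs = em_motifs, model = site_model("zoops"),
                        background = background, seed = sub_seed(2L),
                        n_starts = n_starts, tol = em_tol,
                        max_iter = em_max_iter)
  words <- discover_words(seqs_shuf, min_k = 4L, max_k = min(8L, em_width),
                          n_motifs = word_motifs, seed = sub_seed(3L),
                          background = background)
  discovered <- c(em$motifs, words$motifs)
  for (i in seq_along(discovered)) {
    discovered[[i]]$name <- paste0("disc_", i, "_", discovered[[i]]$name)
  }
  centrality_db <- rank_motifs_by_centrality(motif_db, seqs,
                                             background = background)
  centrality_disc <- if (length(discovered)) {
    rank_motifs_by_centrality(discovered, seqs, background = background)
  } else NULL
  comparisons <- lapply(discovered, function(m) {
    compare_to_database(m, motif_db, seed = sub_seed(4L),
                        background = background)
  })
  names(comparisons) <- vapply(discovered, function(m) m$name, character(1))
  summary <- if (length(discovered)) do.call(rbind, lapply(
    seq_along(discovered), function(i) {
      m <- discovered[[i]]
      cmp <- comparisons[[i]]
      cen <- centrality_disc[centrality_disc$motif_id == m$name, , drop = FALSE]
      data.frame(
        motif_id = m$name,
        source = if (i <= length(em$motifs)) "em" else "words",
        consensus = consensus(m),
        evalue = m$evalue,
        best_match = cmp$target_id[1],
        match_p = cmp$p_value[1],
        central_adjusted_p = cen$adjusted_p[1],
        centrally_enriched = cen$adjusted_p[1] < centrality_threshold,
        stringsAsFactors = FALSE)
    })) else data.frame()
  out <- list(discovered = discovered, em = em, words = words,
              centrality_db = centrality_db,
              centrality_discovered = centrality_disc,
              comparisons = comparisons, summary = summary,
              seed = seed)
  class(out) <- "PeakPipelineReport"
  out
}

#' @export
print.PeakPipelineReport <- function(x, ...) {
  cat(sprintf("<PeakPipelineReport: %d discovered motif(s)>\n",
              length(x$discovered)))
  if (nrow(x$summary)) {
    print(x$summary[, c("motif_id", "source", "consensus", "best_match",
                        "match_p", "central_adjusted_p")])
  }
  invisible(x)
}

#' Write a pipeline report as JSON plus a plain-text summary
#'
#' @param report A `PeakPipelineReport`.
#' @param json_path Path for the machine-readable JSON report (or `NULL`).
#' @param text_path Path for the plain-text summary (or `NULL`).
#' @return The JSON text, invisibly.
#' @export
write_pipeline_report <- function(report, json_path = NULL, text_path = NULL) {
  js <- list(
    seed = report$seed,
    summary = report$summary,
    centrality_db = report$centrality_db,
    comparisons = lapply(report$comparisons, utils::head, 5L))
  txt <- jsonlite::toJSON(js, dataframe = "rows", auto_unbox = TRUE,
                          digits = NA, pretty = TRUE)
  if (!is.null(json_path)) writeLines(txt, json_path)
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    on.exit(close(con))
    writeLines(utils::capture.output(print(report)), con)
  }
  invisible(txt)
}

#' Iterative motif refinement against a sequence database
#'
#' Mirrors the scan-collect-rediscover loop used to broaden a motif learned
#' from a handful of sequences: each round scans the database with the
#' current motif, collects the sequences with a hit (p below `p_threshold`)
#' inside their first `region_length` letters, truncates them to that
#' region, and re-estimates the motif with one-occurrence-per-sequence EM at
#' fixed width. Stops early (with a warning) if a round collects fewer than
#' two sequences.
#'
#' @param seqs_db The `SequenceSet` to scan.
#' @param initial_motif Starting `Motif`.
#' @param region_length N-terminal window, in letters (>= motif width).
#' @param rounds Number of refinement rounds (0 returns the input motif).
#' @param background A `Background`; uniform if `NULL`.
#' @param p_threshold Hit threshold for collection (default 1e-4).
#' @return List with `motif` (final), `collected` (integer vector of
#'   per-round collected-set sizes), `rounds_run`.
#' @export
iterative_refinement <- function(seqs_db, initial_motif, region_length,
                                 rounds = 2L, background = NULL,
                                 p_threshold = 1e-4) {
  if (region_length < motif_width(initial_motif)) {
    stop("region_length must be at least the motif width")
  }
  if (is.null(background)) background <- uniform_background(seqs_db$alphabet)
  cur <- initial_motif
  collected <- integer(0)
  for (r in seq_len(rounds)) {
    hits <- scan_motifs(cur, seqs_db, background = background,
                        p_threshold = p_threshold,
                        both_strands = is_nucleotide(seqs_db$alphabet))
    hits <- hits[hits$start <= region_length - motif_width(cur) + 1L, ,
                 drop = FALSE]
    ids <- unique(hits$sequence_name)
    collected <- c(collected, length(ids))
    if (length(ids) < 2L) {
      warning("round ", r, " collected ", length(ids),
              " sequence(s); stopping early")
      return(list(motif = cur, collected = collected, rounds_run = r - 1L))
    }
    sel <- seqs_db$records$id %in% ids
    trunc <- substr(seqs_db$records$residues[sel], 1L,
                    pmin(region_length, nchar(seqs_db$records$residues[sel])))
    sub <- sequence_set(seqs_db$records$id[sel], trunc,
                        alphabet = seqs_db$alphabet)
    fit <- run_em(sub, cur, model = site_model("oops"),
                  background = background,
                  both_strands = is_nucleotide(seqs_db$alphabet))
    cur <- fit$motif
    cur$name <- initial_motif$name
  }
  list(motif = cur, collected = collected, rounds_run = rounds)
}
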