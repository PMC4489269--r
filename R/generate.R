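#' Specification of one planted motif for the synthetic generator
#'
#' @param motif A `Motif` to plant.
#' @param occurrence `"every"` (one site in every sequence), a probability
#'   in (0, 1) (zero-or-one site per sequence with that probability), or
#'   `"none"`.
#' @param placement `"uniform"` over admissible offsets, or `"central"` for
#'   a Gaussian centered on the sequence midpoint with standard deviation
#'   `sd` (in letters), rounded and clipped to the admissible range.
#' @param sd Standard deviation of the central placement.
#' @param mutation_rate Per-column probability that a planted letter is
#'   replaced by a draw from the background.
#' @param strand `"forward"` or `"both"` (sites planted on a random strand).
#' @return An object of class `PlantSpec`.
#' @export
plant_spec <- function(motif, occurrence = "every", placement = "uniform",
                       sd = NULL, mutation_rate = 0, strand = "forward") {
  if (is.character(occurrence)) {
    occurrence <- match.arg(occurrence, c("every", "none"))
  } else {
    stopifnot(is.numeric(occurrence), occurrence > 0, occurrence < 1)
  }
  placement <- match.arg(placement, c("uniform", "central"))
  if (placement == "central" && (is.null(sd) || sd <= 0)) {
    stop("central placement needs a positive sd")
  }
  stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  strand <- match.arg(strand, c("forward", "both"))
  structure(list(motif = motif, occurrence = occurrence, placement = placement,
                 sd = sd, mutation_rate = mutation_rate, strand = strand),
            class = "PlantSpec")
}

#' Generate background sequences with planted motif sites
#'
#' Sequences are drawn i.i.d. letter-by-letter from the background, then
#' sites are planted per [plant_spec()]: each planted column is sampled from
#' the motif's probability row and then mutated (replaced by a background
#' draw) at the specified rate, and written over the background letters on
#' the chosen strand. Overlapping plants within a sequence are re-drawn up
#' to 100 times before the call fails. Deterministic given `seed`.
#'
#' @param n Number of sequences.
#' @param L Sequence length.
#' @param background A `Background` (defines the alphabet).
#' @param plants List of `PlantSpec`s (or a single one); may be empty.
#' @param seed Integer seed.
#' @param prefix Identifier prefix.
#' @return List with `seqs` (a `SequenceSet`) and `truth` (data.frame with
#'   columns `sequence`, `plant`, `start`, `strand`, `site`, one row per
#'   planted site; `start` is the 1-based forward-strand offset).
#' @export
generate_planted_dataset <- function(n, L, background, plants = list(),
                                     seed = 1L, prefix = "seq") {
  if (inherits(plants, "PlantSpec")) plants <- list(plants)
  alph <- background$alphabet
  core <- alph$core
  bg <- background$frequencies
  for (p in plants) {
    if (motif_width(p$motif) > L) stop("planted motif wider than L")
  }
  withr::with_seed(seed, {
    residues <- vapply(seq_len(n), function(i) {
      paste(sample(core, L, replace = TRUE, prob = bg), collapse = "")
    }, character(1))
    truth <- list()
    for (i in seq_len(n)) {
      occupied <- matrix(numeric(0), ncol = 2)
      for (pi in seq_along(plants)) {
        p <- plants[[pi]]
        w <- motif_width(p$motif)
        do_plant <- if (identical(p$occurrence, "every")) TRUE
          else if (identical(p$occurrence, "none")) FALSE
          else stats::runif(1) < p$occurrence
        if (!do_plant) next
        placed <- FALSE
        for (try in seq_len(100L)) {
          start <- if (p$placement == "uniform") {
            sample.int(L - w + 1L, 1L)
          } else {
            ctr <- (L - w + 2) / 2
            s <- round(ctr + stats::rnorm(1, 0, p$sd))
            min(max(s, 1L), L - w + 1L)
          }
          if (!nrow(occupied) ||
              all(start + w - 1 < occupied[, 1] | start > occupied[, 2])) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place plant ", pi, " in sequence ", i,
               " without overlap after 100 tries")
        }
        site <- core[apply(p$motif$probs, 1, function(r) {
          sample.int(length(core), 1L, prob = r)
        })]
        if (p$mutation_rate > 0) {
          mut <- stats::runif(w) < p$mutation_rate
          if (any(mut)) {
            site[mut] <- sample(core, sum(mut), replace = TRUE, prob = bg)
          }
        }
        strand <- "+"
        if (p$strand == "both" && is_nucleotide(alph) && stats::runif(1) < 0.5) {
          strand <- "-"
        }
        written <- paste(site, collapse = "")
        if (strand == "-") written <- revcomp(written, alph)
        substr(residues[i], start, start + w - 1L) <- written
        occupied <- rbind(occupied, c(start, start + w - 1L))
        truth[[length(truth) + 1L]] <- data.frame(
          sequence = paste0(prefix, i), plant = pi, start = start,
          strand = strand, site = paste(site, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
    list(seqs = sequence_set(paste0(prefix, seq_len(n)), residues,
                             alphabet = alph),
         truth = if (length(truth)) do.call(rbind, truth) else data.frame(
           sequence = character(0), plant = integer(0), start = integer(0),
           strand = character(0), site = character(0)))
  })
}

#' Motif built from a consensus word
#'
#' Convenience constructor: probability `p_match` on the consensus letter of
#' each position, the rest spread evenly.
#'
#' @param word Core-letter string.
#' @param alphabet An `Alphabet`.
#' @param p_match Probability of the consensus letter (default 0.9).
#' @param name Motif name (defaults to the word).
#' @return A `Motif`.
#' @export
word_motif <- function(word, alphabet, p_match = 0.9, name = word) {
  ch <- strsplit(toupper(word), "", fixed = TRUE)[[1]]
  idx <- match(ch, alphabet$core)
  if (anyNA(idx)) stop("word must use core letters only")
  K <- length(alphabet$core)
  probs <- matrix((1 - p_match) / (K - 1), length(ch), K,
                  dimnames = list(NULL, alphabet$core))
  probs[cbind(seq_along(ch), idx)] <- p_match
  motif(probs, alphabet, name = name, nsites = 20)
}
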