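#' Construct a motif from a letter-probability matrix
#'
#' A motif is a fixed-width per-position letter-probability matrix over the
#' core symbols of an alphabet (no insertions or deletions are
#' representable), together with a name, an effective site count and an
#' optional E-value.
#'
#' @param probs Numeric matrix, `w` rows (motif positions) by `|alphabet|`
#'   columns (core symbols, in alphabet order or named). Each row must sum
#'   to 1 within 1e-6.
#' @param alphabet An `Alphabet`.
#' @param name Motif name.
#' @param alt_name Optional alternative name.
#' @param nsites Positive effective number of sites behind the matrix.
#' @param evalue Non-negative E-value, or `NA` when undefined.
#' @return An object of class `Motif`.
#' @export
motif <- function(probs, alphabet, name = "motif", alt_name = "",
                  nsites = 20, evalue = NA_real_) {
  probs <- as.matrix(probs)
  core <- alphabet$core
  if (ncol(probs) != length(core)) {
    stop("motif matrix has ", ncol(probs), " columns; alphabet ",
         alphabet$name, " has ", length(core), " core symbols")
  }
  if (!is.null(colnames(probs))) probs <- probs[, core, drop = FALSE]
  colnames(probs) <- core
  rownames(probs) <- NULL
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("motif row ", which(abs(rs - 1) > 1e-6)[1], " sums to ",
         format(rs[which(abs(rs - 1) > 1e-6)[1]]), ", not 1")
  }
  if (any(probs < 0)) stop("motif probabilities must be non-negative")
  if (nrow(probs) < 1L) stop("motif width must be >= 1")
  stopifnot(nsites > 0)
  out <- list(name = as.character(name), alt_name = as.character(alt_name),
              probs = probs, nsites = as.numeric(nsites),
              evalue = as.numeric(evalue), alphabet = alphabet)
  class(out) <- "Motif"
  out
}

#' @export
print.Motif <- function(x, ...) {
  cat(sprintf("<Motif %s: width %d, nsites %.1f%s, consensus %s>\n",
              x$name, nrow(x$probs), x$nsites,
              if (is.na(x$evalue)) "" else sprintf(", E=%.3g", x$evalue),
              consensus(x)))
  invisible(x)
}

motif_width <- function(m) nrow(m$probs)

#' Consensus string of a motif (most probable letter per position)
#' @param m A `Motif`.
#' @return Character scalar.
#' @export
consensus <- function(m) {
  paste(m$alphabet$core[max.col(m$probs, ties.method = "first")], collapse = "")
}

#' Convert a count matrix to a motif with background-proportional pseudocounts
#'
#' `p(i, a) = (count(i, a) + alpha * background(a)) / (nsites + alpha)` where
#' `nsites` is the common row sum. Rows whose sums deviate from the first
#' row's by more than 10% are rejected; small deviations (fractional IUPAC
#' contributions) are tolerated and `nsites` is the mean row sum.
#'
#' @param counts Non-negative numeric matrix, `w` x `|alphabet|`.
#' @param background A `Background`.
#' @param alpha Total pseudocount mass spread proportionally to the
#'   background. `alpha = 0` requires strictly positive counts.
#' @param ... Passed to [motif()] (`name`, `evalue`, ...).
#' @return A `Motif` with `nsites` equal to the (mean) row sum.
#' @export
counts_to_motif <- function(counts, background, alpha = 0.1, ...) {
  counts <- as.matrix(counts)
  alph <- background$alphabet
  if (!is.null(colnames(counts))) counts <- counts[, alph$core, drop = FALSE]
  if (any(counts < 0)) stop("counts must be non-negative")
  rs <- rowSums(counts)
  if (any(rs == 0)) stop("count row ", which(rs == 0)[1], " is all zeros")
  if (max(rs) - min(rs) > 0.1 * max(rs)) {
    stop("count rows have unequal sums (", format(min(rs)), " vs ",
         format(max(rs)), "); not a site count matrix")
  }
  if (alpha == 0 && any(counts == 0)) {
    stop("zero count at position ", which(rowSums(counts == 0) > 0)[1],
         " with alpha = 0: motif rows must stay strictly positive for log-odds")
  }
  nsites <- mean(rs)
  bg <- background$frequencies
  probs <- sweep(counts, 2, alpha * bg, "+") / (rs + alpha)
  probs <- probs / rowSums(probs)
  motif(probs, alph, nsites = nsites, ...)
}

#' Reverse complement of a nucleotide motif
#' @param m A `Motif` over a complementable alphabet.
#' @return A `Motif` with rows reversed and columns complement-permuted.
#' @export
revcomp_motif <- function(m) {
  alph <- m$alphabet
  if (!is_nucleotide(alph)) stop("cannot reverse-complement a ", alph$name, " motif")
  perm <- match(alph$complement[alph$core], alph$core)
  probs <- m$probs[rev(seq_len(nrow(m$probs))), perm, drop = FALSE]
  colnames(probs) <- alph$core
  motif(probs, alph, name = m$name, alt_name = m$alt_name,
        nsites = m$nsites, evalue = m$evalue)
}

#' Per-position and total information content of a motif, in bits
#'
#' `IC(i) = sum_a p(i,a) * log2(p(i,a) / background(a))`, the relative
#' entropy of each motif position against the background (the letter-height
#' quantity of a sequence logo).
#'
#' @param m A `Motif`.
#' @param background A `Background` (uniform if omitted).
#' @return List with `per_position` (numeric, length `w`) and `total`.
#' @export
information_content <- function(m, background = NULL) {
  if (is.null(background)) background <- uniform_background(m$alphabet)
  bg <- background$frequencies
  p <- m$probs
  term <- p * log2(sweep(p, 2, bg, "/"))
  term[p == 0] <- 0
  per_pos <- pmax(rowSums(term), 0)
  list(per_position = per_pos, total = sum(per_pos))
}

#' Convert a motif to a log-odds (bit-score) matrix with integer quantization
#'
#' Bit scores are `log2(p(i,a) / background(a))`; they are affinely mapped
#' onto `0..quantization_bins` and rounded, with `scale`/`offset` inverting
#' the map (`bits ~ offset + scale * integer`, exact to within `scale/2`).
#' The integer representation feeds the exact p-value dynamic program.
#' Ambiguity letters receive the background-weighted average of their
#' expansion's scores.
#'
#' @param m A `Motif` with strictly positive probabilities.
#' @param background A `Background`.
#' @param quantization_bins Number of integer quanta (default 1000).
#' @return An object of class `LogOddsMatrix`: list with `motif`, `bits`
#'   (`w` x core), `ints` (`w` x all letters, integer), `scale`, `offset`,
#'   `background`.
#' @export
motif_to_logodds <- function(m, background, quantization_bins = 1000L) {
  p <- m$probs
  if (any(p <= 0)) {
    bad <- which(p <= 0, arr.ind = TRUE)[1, ]
    stop("zero probability at position ", bad[1], ", letter ",
         colnames(p)[bad[2]], "; apply a pseudocount before scoring")
  }
  bg <- background$frequencies
  bits <- log2(sweep(p, 2, bg, "/"))
  lo <- min(bits); hi <- max(bits)
  if (hi - lo < 1e-12) {
    scale <- 1; offset <- lo
    ints_core <- matrix(0L, nrow(bits), ncol(bits))
  } else {
    scale <- (hi - lo) / quantization_bins
    offset <- lo
    ints_core <- matrix(as.integer(round((bits - lo) / scale)),
                        nrow(bits), ncol(bits))
  }
  E <- expansion_weights(m$alphabet, background)
  # ambiguity letters: background-weighted average of the integer scores
  ints <- matrix(0L, nrow(bits), length(m$alphabet$letters),
                 dimnames = list(NULL, m$alphabet$letters))
  ints[, m$alphabet$core] <- ints_core
  for (e in names(m$alphabet$ambig)) {
    ints[, e] <- as.integer(round(ints_core %*% E[e, ]))
  }
  out <- list(motif = m, bits = bits, ints = ints, scale = scale,
              offset = offset, background = background,
              bins = as.integer(quantization_bins))
  class(out) <- "LogOddsMatrix"
  out
}

#' @export
print.LogOddsMatrix <- function(x, ...) {
  cat(sprintf("<LogOddsMatrix for %s: width %d, scale %.4g bits/quantum>\n",
              x$motif$name, nrow(x$bits), x$scale))
  invisible(x)
}

# random Dirichlet motif, used by tests, decoy databases and the generator
#' Sample a random motif
#'
#' Each position is drawn from a symmetric Dirichlet; small concentration
#' values give sharp (high-information) positions.
#'
#' @param width Motif width.
#' @param alphabet An `Alphabet`.
#' @param concentration Dirichlet concentration per letter.
#' @param name Motif name.
#' @return A `Motif`.
#' @export
random_motif <- function(width, alphabet, concentration = 0.5, name = "random") {
  K <- length(alphabet$core)
  g <- matrix(stats::rgamma(width * K, shape = concentration), nrow = width)
  g <- pmax(g, 1e-8)
  motif(g / rowSums(g), alphabet, name = name, nsites = 20)
}
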