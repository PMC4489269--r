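#' Parse "typed" motifs: aligned sites, count matrices or probability matrices
#'
#' Auto-detects how each blank-line-separated block specifies a motif, the
#' way the classic web forms do:
#'
#' * lines of alphabet letters (IUPAC ambiguity codes allowed) are read as
#'   aligned sites of equal length; ambiguity letters contribute fractional
#'   counts split evenly over their expansion;
#' * numeric blocks are read as a count or probability matrix, deciding
#'   automatically whether rows correspond to motif positions or to alphabet
#'   letters: rows-as-positions when every row has `|alphabet|` entries and
#'   row sums agree (on a common total or on 1), rows-as-letters when there
#'   are exactly `|alphabet|` rows and the columns satisfy that instead.
#'   When both readings are consistent (e.g. a 4 x 4 matrix over DNA),
#'   rows-as-positions wins. Entries at most 1 with unit sums mark a
#'   probability matrix (effective `nsites` defaults to 20); otherwise the
#'   block is a count matrix with `nsites` the common total.
#'
#' @param text Character scalar (possibly multi-line) or vector of lines.
#' @param alphabet An `Alphabet`.
#' @param background Background used for the pseudocount when converting
#'   counts to probabilities; uniform if `NULL`.
#' @param alpha Total pseudocount for count/site blocks. The default 0 keeps
#'   the parsed matrix an exact transcription of the input (zero counts give
#'   zero probabilities); scoring functions add their own pseudocount before
#'   taking log-odds.
#' @return List of `Motif` objects, named `m1`, `m2`, ...
#' @export
parse_typed_motifs <- function(text, alphabet, background = NULL, alpha = 0) {
  if (is.null(background)) background <- uniform_background(alphabet)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  blocks <- split(lines, cumsum(lines == ""))
  blocks <- lapply(blocks, function(b) b[nzchar(b)])
  blocks <- blocks[vapply(blocks, length, 1L) > 0]
  out <- list()
  for (b in blocks) {
    out[[length(out) + 1L]] <- parse_typed_block(b, alphabet, background, alpha,
                                                 name = paste0("m", length(out) + 1L))
  }
  names(out) <- vapply(out, function(m) m$name, character(1))
  out
}

parse_typed_block <- function(block, alphabet, background, alpha, name) {
  is_numeric_block <- all(grepl("^[-0-9.eE+[:space:]]+$", block)) &&
    all(grepl("[0-9]", block))
  if (!is_numeric_block) {
    sites_to_motif(block, alphabet, background, alpha, name)
  } else {
    rows <- lapply(block, function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "[[:space:],]+")[[1]]))
      if (anyNA(v)) stop("unsupported characters in numeric motif line: ", l)
      v
    })
    numeric_to_motif(rows, alphabet, background, alpha, name)
  }
}

sites_to_motif <- function(block, alphabet, background, alpha, name) {
  block <- toupper(block)
  widths <- nchar(block)
  if (length(unique(widths)) != 1L) {
    stop("sequence sites are of inconsistent lengths (",
         paste(unique(widths), collapse = ", "), ")")
  }
  w <- widths[1]
  K <- length(alphabet$core)
  counts <- matrix(0, nrow = w, ncol = K, dimnames = list(NULL, alphabet$core))
  for (s in block) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- setdiff(ch, alphabet$letters)
    if (length(bad)) stop("unsupported character '", bad[1], "' in site: ", s)
    for (i in seq_len(w)) {
      l <- ch[i]
      if (l %in% alphabet$core) {
        counts[i, l] <- counts[i, l] + 1
      } else {
        exp_set <- alphabet$ambig[[l]]
        counts[i, exp_set] <- counts[i, exp_set] + 1 / length(exp_set)
      }
    }
  }
  typed_counts_motif(counts, background, alpha, name)
}

# zero-pseudocount conversion keeps exact relative frequencies (zeros
# allowed in a Motif; only log-odds conversion needs positivity)
typed_counts_motif <- function(counts, background, alpha, name) {
  if (alpha > 0) return(counts_to_motif(counts, background, alpha = alpha,
                                        name = name))
  rs <- rowSums(counts)
  if (any(rs == 0)) stop("motif position ", which(rs == 0)[1], " has no counts")
  motif(counts / rs, background$alphabet, name = name, nsites = mean(rs))
}

numeric_to_motif <- function(rows, alphabet, background, alpha, name) {
  K <- length(alphabet$core)
  lens <- vapply(rows, length, 1L)
  sums_agree <- function(x) {
    m <- mean(x)
    m > 0 && all(abs(x - m) <= 0.02 * max(m, 1))
  }
  as_positions_ok <- all(lens == K) && {
    mat <- do.call(rbind, rows); sums_agree(rowSums(mat))
  }
  as_letters_ok <- length(rows) == K && length(unique(lens)) == 1L && {
    mat <- do.call(rbind, rows); sums_agree(colSums(mat))
  }
  if (!as_positions_ok && !as_letters_ok) {
    stop("numeric motif block is neither a positions-by-letters nor a ",
         "letters-by-positions matrix over the ", alphabet$name, " alphabet")
  }
  # tie-break: rows-as-positions preferred when both readings are consistent
  mat <- do.call(rbind, rows)
  if (!as_positions_ok) mat <- t(mat)
  colnames(mat) <- alphabet$core
  is_prob <- all(mat <= 1 + 1e-9) && all(abs(rowSums(mat) - 1) <= 0.02)
  if (is_prob) {
    nsites <- 20
    counts <- mat * nsites
  } else {
    counts <- mat
  }
  typed_counts_motif(counts, background, alpha, name)
}
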