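#' Build a sequence set
#'
#' Container for a collection of unaligned sequences over one alphabet.
#' Residues are uppercased on ingest (repeat-masked lowercase input is
#' common) and validated against the alphabet's core plus IUPAC ambiguity
#' letters. Identifiers must be unique.
#'
#' @param ids Character vector of non-empty identifiers.
#' @param residues Character vector of sequences (same length as `ids`).
#' @param alphabet An `Alphabet`; if `NULL`, inferred with [infer_alphabet()].
#' @param descriptions Optional character vector of free-text descriptions.
#' @return An object of class `SequenceSet`: list with `alphabet` and
#'   `records` (a data.frame with columns `id`, `description`, `residues`).
#' @export
sequence_set <- function(ids, residues, alphabet = NULL, descriptions = NULL) {
  stopifnot(length(ids) == length(residues))
  if (length(ids) == 0L) stop("a SequenceSet must contain at least one sequence")
  ids <- as.character(ids)
  if (any(!nzchar(ids))) stop("sequence identifiers must be non-empty")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier: ", ids[duplicated(ids)][1])
  }
  residues <- toupper(as.character(residues))
  if (any(!nzchar(residues))) {
    stop("empty sequence for identifier: ", ids[!nzchar(residues)][1])
  }
  if (is.null(descriptions)) descriptions <- rep("", length(ids))
  if (is.null(alphabet)) alphabet <- infer_alphabet(residues)
  ok <- grepl(paste0("^[", paste(alphabet$letters, collapse = ""), "]+$"), residues)
  if (!all(ok)) {
    bad_seq <- residues[!ok][1]
    bad_chr <- setdiff(unique(strsplit(bad_seq, "", fixed = TRUE)[[1]]),
                       alphabet$letters)[1]
    stop("invalid letter '", bad_chr, "' in sequence '", ids[!ok][1],
         "' for ", alphabet$name, " alphabet")
  }
  out <- list(alphabet = alphabet,
              records = data.frame(id = ids, description = as.character(descriptions),
                                   residues = residues, stringsAsFactors = FALSE))
  class(out) <- "SequenceSet"
  out
}

#' @export
print.SequenceSet <- function(x, ...) {
  lens <- nchar(x$records$residues)
  cat(sprintf("<SequenceSet: %d %s sequence(s), lengths %d-%d>\n",
              nrow(x$records), x$alphabet$name, min(lens), max(lens)))
  invisible(x)
}

#' @export
length.SequenceSet <- function(x) nrow(x$records)

seq_lengths <- function(seqs) nchar(seqs$records$residues)

#' Infer the alphabet of a set of residues
#'
#' DNA is assumed unless a letter outside the IUPAC nucleotide set appears,
#' in which case the set is read as protein; `U` without `T` selects RNA.
#' A supplied alphabet always overrides inference at the call sites that
#' accept one.
#'
#' @param residues Character vector of uppercase sequences.
#' @return An `Alphabet`.
#' @export
infer_alphabet <- function(residues) {
  chars <- unique(strsplit(paste(toupper(residues), collapse = ""), "", fixed = TRUE)[[1]])
  dna <- make_alphabet("DNA"); rna <- make_alphabet("RNA")
  if (all(chars %in% dna$letters)) return(dna)
  if (all(chars %in% rna$letters)) return(rna)
  make_alphabet("protein")
}

#' Read sequences from a FASTA file
#'
#' Headers are split at the first whitespace into identifier and description;
#' sequence lines are concatenated and uppercased. Characters outside the
#' alphabet (core plus IUPAC ambiguity codes) are rejected with the line
#' number at which they occur, as are duplicate identifiers.
#'
#' @param path Path to a FASTA file, or a character scalar containing FASTA
#'   text (detected by a leading `>`).
#' @param alphabet Optional `Alphabet`; inferred from the residues when `NULL`.
#' @return A `SequenceSet`.
#' @export
read_fasta <- function(path, alphabet = NULL) {
  if (length(path) == 1L && grepl("^>", path)) {
    tf <- tempfile(fileext = ".fa")
    on.exit(unlink(tf), add = TRUE)
    writeLines(strsplit(path, "\n", fixed = TRUE)[[1]], tf)
    path <- tf
  }
  xss <- Biostrings::readBStringSet(path)
  if (length(xss) == 0L) stop("no sequences in FASTA input: ", path)
  headers <- names(xss)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(as.character(xss))
  if (is.null(alphabet)) alphabet <- infer_alphabet(residues)
  bad <- !grepl(paste0("^[", paste(alphabet$letters, collapse = ""), "]*$"), residues)
  if (any(bad)) {
    report_fasta_letter_error(path, alphabet)
  }
  sequence_set(ids, residues, alphabet = alphabet, descriptions = descs)
}

# locate the first offending character with its file line number
report_fasta_letter_error <- function(path, alphabet) {
  lines <- readLines(path, warn = FALSE)
  valid <- c(alphabet$letters, tolower(alphabet$letters))
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], ">")) next
    ch <- strsplit(lines[i], "", fixed = TRUE)[[1]]
    bad <- setdiff(ch, c(valid, " ", "\t"))
    if (length(bad)) {
      stop("invalid letter '", bad[1], "' at line ", i, " for ",
           alphabet$name, " alphabet")
    }
  }
  stop("invalid sequence characters for ", alphabet$name, " alphabet")
}

#' Write a sequence set to FASTA
#'
#' @param seqs A `SequenceSet`.
#' @param path Output file path.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  nm <- ifelse(nzchar(seqs$records$description),
               paste(seqs$records$id, seqs$records$description),
               seqs$records$id)
  xss <- Biostrings::BStringSet(seqs$records$residues)
  names(xss) <- nm
  Biostrings::writeXStringSet(xss, filepath = path, width = width)
  invisible(path)
}

#' Estimate a 0-order background model from sequences
#'
#' Letter frequencies with an additive pseudocount:
#' `(count + pseudocount) / (total + pseudocount * |alphabet|)`.
#' IUPAC ambiguity letters contribute fractionally, split evenly over their
#' expansion. For complementable alphabets, `use_both_strands` symmetrizes
#' counts with the complement.
#'
#' @param seqs A `SequenceSet`.
#' @param pseudocount Non-negative pseudocount added per core letter.
#' @param use_both_strands Symmetrize with the complement (nucleotides only).
#' @return An object of class `Background`: list with `alphabet` and
#'   `frequencies` (named numeric over core symbols, strictly positive,
#'   summing to 1).
#' @export
estimate_background <- function(seqs, pseudocount = 1, use_both_strands = FALSE) {
  alph <- seqs$alphabet
  core <- alph$core
  K <- length(core)
  all_res <- paste(seqs$records$residues, collapse = "")
  ch <- strsplit(all_res, "", fixed = TRUE)[[1]]
  tab <- table(factor(ch, levels = alph$letters))
  counts <- as.numeric(tab[core])
  names(counts) <- core
  for (e in names(alph$ambig)) {
    n_e <- as.numeric(tab[e])
    if (n_e > 0) {
      exp_set <- alph$ambig[[e]]
      counts[exp_set] <- counts[exp_set] + n_e / length(exp_set)
    }
  }
  if (use_both_strands && is_nucleotide(alph)) {
    comp <- alph$complement[core]
    counts <- (counts + counts[comp]) / 2
    names(counts) <- core
  }
  total <- sum(counts)
  freqs <- (counts + pseudocount) / (total + pseudocount * K)
  background(freqs, alph)
}

#' Construct a background model from explicit frequencies
#'
#' @param frequencies Named numeric vector over the alphabet's core symbols
#'   (any order); must be strictly positive and is normalized to sum to 1.
#' @param alphabet An `Alphabet`.
#' @return A `Background`.
#' @export
background <- function(frequencies, alphabet) {
  core <- alphabet$core
  if (is.null(names(frequencies))) {
    if (length(frequencies) != length(core)) stop("background length mismatch")
    names(frequencies) <- core
  }
  if (!setequal(names(frequencies), core)) {
    stop("background frequencies must cover exactly the core symbols of ",
         alphabet$name)
  }
  frequencies <- frequencies[core]
  if (any(frequencies <= 0)) {
    stop("background frequencies must be strictly positive (letter ",
         names(frequencies)[frequencies <= 0][1],
         " is zero; use a positive pseudocount)")
  }
  frequencies <- frequencies / sum(frequencies)
  out <- list(alphabet = alphabet, frequencies = frequencies)
  class(out) <- "Background"
  out
}

#' Uniform background over an alphabet's core symbols
#' @param alphabet An `Alphabet`.
#' @return A `Background` with equal frequencies.
#' @export
uniform_background <- function(alphabet) {
  K <- length(alphabet$core)
  background(stats::setNames(rep(1 / K, K), alphabet$core), alphabet)
}

#' @export
print.Background <- function(x, ...) {
  cat("<Background ", x$alphabet$name, ": ",
      paste(sprintf("%s=%.3f", names(x$frequencies), x$frequencies), collapse = " "),
      ">\n", sep = "")
  invisible(x)
}

#' Reverse-complement every sequence in a set
#' @param seqs A nucleotide `SequenceSet`.
#' @return A `SequenceSet` with each record reverse-complemented.
#' @export
revcomp_set <- function(seqs) {
  sequence_set(seqs$records$id, revcomp(seqs$records$residues, seqs$alphabet),
               alphabet = seqs$alphabet, descriptions = seqs$records$description)
}
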