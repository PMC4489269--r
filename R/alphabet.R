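#' Construct a standard biological alphabet
#'
#' Builds one of the three standard alphabets used throughout the package:
#' DNA (`ACGT`), RNA (`ACGU`) or protein (the 20 amino acids). Nucleotide
#' alphabets carry a full IUPAC complement map; all alphabets carry IUPAC
#' ambiguity codes mapping each degenerate letter to its expansion over the
#' core symbols, with a wildcard (`N` for nucleotides, `X` for protein)
#' expanding to every core symbol.
#'
#' @param kind One of `"DNA"`, `"RNA"` or `"protein"`.
#'
#' @return An object of class `Alphabet`: a list with elements `name`,
#'   `core` (ordered core symbols), `complement` (named character vector over
#'   all letters; empty for protein), `ambig` (named list mapping each
#'   ambiguity letter to its expansion), `wildcard`, and `letters` (core
#'   symbols followed by ambiguity letters, the full set accepted in
#'   sequences).
#'
#' @examples
#' dna <- make_alphabet("DNA")
#' dna$complement[["A"]]      # "T"
#' dna$ambig[["R"]]           # c("A", "G")
#' @export
make_alphabet <- function(kind) {
  if (length(kind) != 1L || !kind %in% c("DNA", "RNA", "protein")) {
    stop("unknown alphabet kind: ", paste(kind, collapse = ", "),
         " (expected one of DNA, RNA, protein)")
  }
  if (kind %in% c("DNA", "RNA")) {
    t_or_u <- if (kind == "DNA") "T" else "U"
    core <- c("A", "C", "G", t_or_u)
    ambig <- list(
      R = c("A", "G"), Y = c("C", t_or_u), S = c("C", "G"),
      W = c("A", t_or_u), K = c("G", t_or_u), M = c("A", "C"),
      B = c("C", "G", t_or_u), D = c("A", "G", t_or_u),
      H = c("A", "C", t_or_u), V = c("A", "C", "G"),
      N = c("A", "C", "G", t_or_u)
    )
    comp_core <- stats::setNames(c(t_or_u, "G", "C", "A"), core)
    comp_amb <- c(R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                  B = "V", D = "H", H = "D", V = "B", N = "N")
    complement <- c(comp_core, comp_amb)
    wildcard <- "N"
  } else {
    core <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
    ambig <- list(
      B = c("D", "N"), Z = c("E", "Q"), J = c("I", "L"),
      X = core
    )
    complement <- character(0)
    wildcard <- "X"
  }
  out <- list(
    name = kind,
    core = core,
    complement = complement,
    ambig = ambig,
    wildcard = wildcard,
    letters = c(core, names(ambig))
  )
  class(out) <- "Alphabet"
  out
}

#' @export
print.Alphabet <- function(x, ...) {
  cat(sprintf("<Alphabet %s: %s%s>\n", x$name, paste(x$core, collapse = ""),
              if (length(x$complement)) " (complementable)" else ""))
  invisible(x)
}

is_nucleotide <- function(alphabet) length(alphabet$complement) > 0L

#' Reverse-complement a character string
#'
#' Applies the alphabet's IUPAC complement map letter-wise and reverses.
#' Only defined for nucleotide alphabets.
#'
#' @param x Character vector of sequences (uppercase, alphabet letters only).
#' @param alphabet An [make_alphabet()] `Alphabet` with a complement map.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x, alphabet) {
  if (!is_nucleotide(alphabet)) stop("alphabet ", alphabet$name, " has no complement")
  vapply(x, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(rev(unname(alphabet$complement[ch])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Integer encoding of sequences over the full letter set (core first, then
# ambiguity letters, in the order of alphabet$letters).
encode_seq <- function(s, alphabet) {
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], alphabet$letters)
  if (anyNA(idx)) {
    bad <- strsplit(s, "", fixed = TRUE)[[1]][which(is.na(idx))[1]]
    stop("invalid letter '", bad, "' for ", alphabet$name, " alphabet")
  }
  idx
}

# Expansion weight matrix: rows = all letters (core + ambiguity), columns =
# core letters. Row e gives the background-conditional distribution over core
# letters for letter e; core rows are one-hot. Used to score ambiguity
# letters as background-weighted averages over their expansion.
expansion_weights <- function(alphabet, background) {
  K <- length(alphabet$core)
  L <- length(alphabet$letters)
  E <- matrix(0, nrow = L, ncol = K,
              dimnames = list(alphabet$letters, alphabet$core))
  for (i in seq_len(K)) E[i, i] <- 1
  bg <- background$frequencies
  for (e in names(alphabet$ambig)) {
    exp_set <- alphabet$ambig[[e]]
    w <- bg[exp_set] / sum(bg[exp_set])
    E[e, exp_set] <- w
  }
  E
}
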