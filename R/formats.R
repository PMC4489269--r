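#' Construct a motif file container
#'
#' In-memory representation of the minimal MEME motif exchange format:
#' version tag, alphabet, strand note, background and an ordered motif list.
#'
#' @param motifs List of `Motif` objects sharing one alphabet (may be empty).
#' @param alphabet An `Alphabet`; required when `motifs` is empty, otherwise
#'   taken from the motifs.
#' @param background A `Background`; uniform if `NULL`.
#' @param strands Character vector, subset of `c("+", "-")`.
#' @return An object of class `MotifFile`.
#' @export
motif_file <- function(motifs = list(), alphabet = NULL, background = NULL,
                       strands = NULL) {
  if (length(motifs) && is.null(alphabet)) alphabet <- motifs[[1]]$alphabet
  if (is.null(alphabet)) stop("alphabet required for an empty motif file")
  for (m in motifs) {
    if (!identical(m$alphabet$name, alphabet$name)) {
      stop("motif ", m$name, " uses alphabet ", m$alphabet$name,
           ", file uses ", alphabet$name)
    }
  }
  if (is.null(background)) background <- uniform_background(alphabet)
  if (is.null(strands)) {
    strands <- if (is_nucleotide(alphabet)) c("+", "-") else "+"
  }
  out <- list(version = "4", alphabet = alphabet, strands = strands,
              background = background, motifs = motifs)
  class(out) <- "MotifFile"
  out
}

#' @export
print.MotifFile <- function(x, ...) {
  cat(sprintf("<MotifFile: %d %s motif(s)>\n", length(x$motifs), x$alphabet$name))
  invisible(x)
}

#' Write motifs in the minimal MEME motif exchange format
#'
#' Emits the `MEME version 4` dialect: `ALPHABET=`, optional `strands:`,
#' `Background letter frequencies`, then per motif a `MOTIF` line followed by
#' a `letter-probability matrix:` header and `w` probability rows printed
#' with 6 decimals.
#'
#' @param mf A `MotifFile` (or a list of `Motif`s, wrapped automatically).
#' @param path Output file path, or `NULL` to return the text lines.
#' @return The text lines, invisibly when written to `path`.
#' @export
write_meme_motifs <- function(mf, path = NULL) {
  if (!inherits(mf, "MotifFile")) mf <- motif_file(mf)
  alph <- mf$alphabet
  lines <- c("MEME version 4", "",
             paste0("ALPHABET= ", paste(alph$core, collapse = "")), "")
  if (is_nucleotide(alph) && all(c("+", "-") %in% mf$strands)) {
    lines <- c(lines, "strands: + -", "")
  }
  bg <- mf$background$frequencies
  bg6 <- format(round6_sum1(bg), nsmall = 6)
  lines <- c(lines, "Background letter frequencies",
             paste(paste(names(bg), bg6), collapse = " "), "")
  for (m in mf$motifs) {
    head <- if (nzchar(m$alt_name)) paste("MOTIF", m$name, m$alt_name)
            else paste("MOTIF", m$name)
    ev <- if (is.na(m$evalue)) 0 else m$evalue
    lines <- c(lines, head,
               sprintf("letter-probability matrix: alength= %d w= %d nsites= %s E= %s",
                       ncol(m$probs), nrow(m$probs),
                       format(m$nsites, digits = 10), format(ev, digits = 6)),
               apply(m$probs, 1, function(r) {
                 paste(format(round6_sum1(r), nsmall = 6), collapse = " ")
               }),
               "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# round a probability vector to 6 decimals so the printed values sum to
# exactly 1 (largest-remainder method); keeps write -> read -> write a fixed
# point at printed precision
round6_sum1 <- function(p) {
  scaled <- p * 1e6
  fl <- floor(scaled)
  rem <- as.integer(1e6 - sum(fl))
  if (rem > 0) {
    give <- order(scaled - fl, decreasing = TRUE)[seq_len(rem)]
    fl[give] <- fl[give] + 1
  } else if (rem < 0) {
    take <- order(scaled - fl)[seq_len(-rem)]
    fl[take] <- fl[take] - 1
  }
  fl / 1e6
}

#' Parse motifs from the minimal MEME motif exchange format
#'
#' Accepts the `MEME version 4` dialect written by [write_meme_motifs()]:
#' each `letter-probability matrix` block becomes a `Motif` with width,
#' `nsites` and E-value taken from its header; background comes from the
#' `Background letter frequencies` section (uniform when absent). Rows whose
#' probabilities do not sum to 1 within 0.01, or whose length disagrees with
#' the declared `alength`/alphabet, are rejected.
#'
#' @param path Path to a MEME motif file, or a character vector of its lines.
#' @return A `MotifFile`.
#' @export
parse_meme_motifs <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE)
           else if (length(path) == 1L) strsplit(path, "\n", fixed = TRUE)[[1]]
           else path
  lines <- trimws(lines)
  if (!any(grepl("^MEME version", lines))) {
    stop("not a MEME motif file: missing 'MEME version' header")
  }
  alpha_line <- grep("^ALPHABET=", lines, value = TRUE)
  alphabet <- if (length(alpha_line)) {
    letters_str <- gsub("\\s", "", sub("^ALPHABET=", "", alpha_line[1]))
    switch(letters_str,
           "ACGT" = make_alphabet("DNA"),
           "ACGU" = make_alphabet("RNA"),
           "ACDEFGHIKLMNPQRSTVWY" = make_alphabet("protein"),
           stop("unsupported ALPHABET line: ", alpha_line[1]))
  } else make_alphabet("DNA")
  strands <- c("+", "-")
  s_line <- grep("^strands:", lines, value = TRUE)
  if (length(s_line)) {
    strands <- intersect(strsplit(s_line[1], "\\s+")[[1]], c("+", "-"))
  } else if (!is_nucleotide(alphabet)) strands <- "+"
  bg <- uniform_background(alphabet)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- character(0)
    j <- bg_i[1] + 1L
    while (j <= length(lines) && !grepl("^(MOTIF|letter-probability)", lines[j]) &&
           nzchar(lines[j])) {
      toks <- c(toks, strsplit(lines[j], "\\s+")[[1]])
      j <- j + 1L
    }
    if (length(toks) %% 2 != 0) stop("malformed background section")
    letters_v <- toks[seq(1, length(toks), by = 2)]
    freqs <- as.numeric(toks[seq(2, length(toks), by = 2)])
    bg <- background(stats::setNames(freqs, letters_v), alphabet)
  }
  motif_idx <- grep("^MOTIF\\b", lines)
  motifs <- vector("list", length(motif_idx))
  for (k in seq_along(motif_idx)) {
    i <- motif_idx[k]
    toks <- strsplit(lines[i], "\\s+")[[1]]
    name <- if (length(toks) >= 2) toks[2] else stop("MOTIF line without a name")
    alt <- if (length(toks) >= 3) toks[3] else ""
    j <- i + 1L
    while (j <= length(lines) && !grepl("^letter-probability matrix:", lines[j])) {
      if (j %in% motif_idx) stop("motif ", name, " has no letter-probability matrix")
      j <- j + 1L
    }
    if (j > length(lines)) stop("motif ", name, " has no letter-probability matrix")
    hdr <- lines[j]
    get_num <- function(key) {
      mres <- regmatches(hdr, regexec(paste0(key, "=\\s*([0-9.eE+-]+)"), hdr))[[1]]
      if (length(mres) < 2) NA_real_ else as.numeric(mres[2])
    }
    alength <- get_num("alength")
    w <- get_num("w")
    nsites <- get_num("nsites")
    ev <- get_num("E")
    if (!is.na(alength) && alength != length(alphabet$core)) {
      stop("motif ", name, ": alength= ", alength, " disagrees with the ",
           alphabet$name, " alphabet (", length(alphabet$core), ")")
    }
    if (is.na(w) || w < 1) stop("motif ", name, ": missing or invalid w=")
    if (is.na(nsites) || nsites <= 0) nsites <- 20
    rows <- matrix(0, nrow = w, ncol = length(alphabet$core))
    for (r in seq_len(w)) {
      vals <- suppressWarnings(as.numeric(strsplit(lines[j + r], "\\s+")[[1]]))
      vals <- vals[!is.na(vals)]
      if (length(vals) != length(alphabet$core)) {
        stop("motif ", name, " row ", r, " has ", length(vals),
             " values, expected ", length(alphabet$core))
      }
      if (abs(sum(vals) - 1) > 0.01) {
        stop("motif ", name, " row ", r, " sums to ", format(sum(vals)),
             ", not 1")
      }
      # keep as printed when already within the motif tolerance (so the
      # round trip is exact); renormalize only sloppier input
      rows[r, ] <- if (abs(sum(vals) - 1) <= 1e-6) vals else vals / sum(vals)
    }
    motifs[[k]] <- motif(rows, alphabet, name = name, alt_name = alt,
                         nsites = nsites,
                         evalue = if (is.na(ev)) NA_real_ else ev)
  }
  motif_file(motifs, alphabet = alphabet, background = bg, strands = strands)
}
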