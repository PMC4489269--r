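# shared fixtures: alphabets, backgrounds and small planted data sets
DNA <- make_alphabet("DNA")
RNA <- make_alphabet("RNA")
PROT <- make_alphabet("protein")
BG_DNA <- uniform_background(DNA)
BG_PROT <- uniform_background(PROT)

# planted data set with a near-deterministic word motif in every sequence
planted_set <- function(word, n = 10, L = 100, seed = 1, p_match = 0.999,
                        occurrence = "every", placement = "uniform",
                        sd = NULL, alphabet = DNA,
                        background = uniform_background(alphabet)) {
  m <- word_motif(word, alphabet, p_match)
  generate_planted_dataset(n, L, background,
                           plant_spec(m, occurrence = occurrence,
                                      placement = placement, sd = sd),
                           seed = seed)
}

# fraction of agreeing consensus columns under the best ungapped alignment
# of a discovered consensus with the planted word (either strand)
consensus_agreement <- function(found, word, alphabet = DNA) {
  variants <- c(word, if (length(alphabet$complement)) revcomp(word, alphabet))
  best <- 0
  for (v in variants) {
    for (shift in -(nchar(found) - 1):(nchar(v) - 1)) {
      matches <- 0
      for (i in seq_len(nchar(found))) {
        j <- i + shift
        if (j >= 1 && j <= nchar(v) &&
            substr(found, i, i) == substr(v, j, j)) {
          matches <- matches + 1
        }
      }
      best <- max(best, matches)
    }
  }
  best / nchar(word)
}

random_pvec <- function(n) stats::runif(n)^2 * 0.999 + 1e-12
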