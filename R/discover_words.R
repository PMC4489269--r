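#' Dinucleotide-preserving shuffle of a nucleotide sequence set
#'
#' Each sequence is shuffled by the Eulerian-path method: the multigraph of
#' observed dinucleotide transitions is traversed in a random order that
#' starts and ends on the original first and last letters, so every shuffled
#' sequence has exactly the original's dinucleotide count vector (and
#' length). Deterministic given `seed`. Used to build the control set for
#' discriminative word discovery.
#'
#' @param seqs A nucleotide `SequenceSet`.
#' @param seed Integer seed.
#' @return A `SequenceSet` with identifiers suffixed `_shuf`.
#' @export
shuffle_control <- function(seqs, seed = 1L) {
  if (!is_nucleotide(seqs$alphabet)) {
    stop("dinucleotide shuffling requires a nucleotide alphabet")
  }
  res <- withr::with_seed(seed, vapply(seqs$records$residues,
                                       euler_shuffle_one, character(1),
                                       USE.NAMES = FALSE))
  sequence_set(paste0(seqs$records$id, "_shuf"), res, alphabet = seqs$alphabet,
               descriptions = seqs$records$description)
}

# Altschul-Erickson Eulerian shuffle of one sequence
euler_shuffle_one <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 3L) return(s)
  verts <- unique(ch)
  vi <- match(ch, verts)
  from <- vi[-n]; to <- vi[-1]
  last_v <- vi[n]
  edges_by_v <- split(seq_along(from), from)
  out_verts <- as.integer(names(edges_by_v))
  # choose a random "last edge" out of every vertex except the final one so
  # that following last edges from any vertex reaches the final vertex
  for (attempt in seq_len(1000L)) {
    last_edge <- vapply(edges_by_v, function(es) es[sample.int(length(es), 1L)],
                        integer(1))
    tgt <- stats::setNames(to[last_edge], out_verts)
    ok <- TRUE
    for (v in out_verts) {
      if (v == last_v) next
      seen <- integer(0); cur <- v
      repeat {
        if (cur == last_v) break
        if (cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
        nxt <- tgt[as.character(cur)]
        if (is.na(nxt)) { ok <- FALSE; break }
        cur <- nxt
      }
      if (!ok) break
    }
    if (ok) break
  }
  if (!ok) return(s)   # defensive: keep the original if no arborescence found
  # random order of the remaining edges, with the chosen last edge appended
  ordered <- lapply(seq_along(edges_by_v), function(k) {
    es <- setdiff(edges_by_v[[k]], last_edge[k])
    es <- if (length(es)) es[sample.int(length(es))] else integer(0)
    if (out_verts[k] == last_v) {
      # the final vertex may or may not have outgoing edges; last edge rule
      # applies only if it has one chosen
      c(es, last_edge[k])
    } else c(es, last_edge[k])
  })
  names(ordered) <- as.character(out_verts)
  ptr <- stats::setNames(rep(1L, length(ordered)), names(ordered))
  out <- integer(n)
  out[1] <- vi[1]
  cur <- vi[1]
  for (i in 2:n) {
    key <- as.character(cur)
    e <- ordered[[key]][ptr[key]]
    ptr[key] <- ptr[key] + 1L
    cur <- to[e]
    out[i] <- cur
  }
  paste(verts[out], collapse = "")
}

#' Count sequences containing at least one match to an IUPAC word
#'
#' @param word IUPAC string (ambiguity codes match their expansions).
#' @param seqs A `SequenceSet`.
#' @param both_strands Also match the reverse complement (nucleotides).
#' @return Integer: number of sequences with >= 1 match.
#' @export
count_sequences_with_word <- function(word, seqs, both_strands = TRUE) {
  sum(sequences_with_word(word, seqs$records$residues, seqs$alphabet,
                          both_strands))
}

sequences_with_word <- function(word, residues, alphabet, both_strands) {
  rx <- iupac_regex(word, alphabet)
  hit <- grepl(rx, residues, perl = TRUE)
  if (both_strands && is_nucleotide(alphabet)) {
    rc <- revcomp(word, alphabet)
    if (!identical(rc, word)) {
      hit <- hit | grepl(iupac_regex(rc, alphabet), residues, perl = TRUE)
    }
  }
  hit
}

iupac_regex <- function(word, alphabet) {
  ch <- strsplit(toupper(word), "", fixed = TRUE)[[1]]
  bad <- setdiff(ch, alphabet$letters)
  if (length(bad)) stop("invalid IUPAC letter '", bad[1], "' in word ", word)
  parts <- vapply(ch, function(l) {
    if (l %in% alphabet$core) l
    else paste0("[", paste(alphabet$ambig[[l]], collapse = ""), "]")
  }, character(1))
  paste0(paste(parts, collapse = ""))
}

#' One-sided (right-tail) Fisher / hypergeometric enrichment p-value
#'
#' Probability of observing at least `a` positive sequences with the word,
#' given `A` positives, `B` negatives and `a + b` with-word sequences in
#' total (hypergeometric tail with fixed margins).
#'
#' @param a Positives with the word.
#' @param A Total positives.
#' @param b Negatives with the word.
#' @param B Total negatives.
#' @return p-value in (0, 1].
#' @export
fisher_right_tail <- function(a, A, b, B) {
  stopifnot(a >= 0, b >= 0, a <= A, b <= B)
  stats::phyper(a - 1, A, B, a + b, lower.tail = FALSE)
}

#' Discriminative discovery of short nucleotide motifs by word enumeration
#'
#' Enumerates every exact word of length `min_k..max_k` present in the
#' positive set and scores its sequence-level enrichment over the negatives
#' with [fisher_right_tail()] (counting each sequence once, with or
#' without the word, both strands). The best word is greedily generalized by
#' single-position IUPAC relaxations accepted while the p-value strictly
#' improves. A word is reported when its E-value (p-value times the number
#' of words tested so far) passes `e_threshold`; its matching sites are then
#' masked with the wildcard and the enumeration repeats, so no word is
#' reported twice. When no negative set is given, a dinucleotide-preserving
#' shuffle of the positives serves as control.
#'
#' @param positives A nucleotide `SequenceSet`.
#' @param negatives A nucleotide `SequenceSet`, or `NULL` to use
#'   [shuffle_control()] on the positives.
#' @param min_k,max_k Word length range (defaults 3..8).
#' @param e_threshold Report words with E-value at or below this (default
#'   0.05).
#' @param n_motifs Maximum number of words to report.
#' @param seed Integer seed (controls the shuffle).
#' @param background Background for building the reported `Motif` from the
#'   matching sites; estimated from the positives if `NULL`.
#' @param both_strands Count matches on both strands.
#' @return List of class `WordDiscovery`; element `words` is a data.frame
#'   with columns `word`, `positives_with`, `positives_total`,
#'   `negatives_with`, `negatives_total`, `p_value`, `n_tested`, `e_value`;
#'   element `motifs` is the matching list of `Motif`s built from the
#'   positive-set sites of each word.
#' @export
discover_words <- function(positives, negatives = NULL, min_k = 3L, max_k = 8L,
                           e_threshold = 0.05, n_motifs = 5L, seed = 1L,
                           background = NULL, both_strands = TRUE) {
  if (!is_nucleotide(positives$alphabet)) {
    stop("word discovery is nucleotide-only")
  }
  if (min_k > max_k) stop("min_k must not exceed max_k")
  if (is.null(negatives)) negatives <- shuffle_control(positives, seed = seed)
  if (is.null(background)) background <- estimate_background(positives, 1)
  alph <- positives$alphabet
  pos_res <- positives$records$residues
  neg_res <- negatives$records$residues
  A <- length(pos_res); B <- length(neg_res)
  words_out <- list(); motifs_out <- list()
  n_tested <- 0L
  if (n_motifs >= 1L) for (round in seq_len(n_motifs)) {
    cand <- enumerate_word_counts(pos_res, alph, min_k, max_k, both_strands)
    if (!length(cand$word)) break
    neg_counts <- count_words_in(cand$word, neg_res, alph, both_strands)
    pv <- fisher_right_tail(cand$count, A, neg_counts, B)
    n_tested <- n_tested + length(cand$word)
    best_i <- order(pv, cand$word)[1]
    best <- list(word = cand$word[best_i], a = cand$count[best_i],
                 b = neg_counts[best_i], p = pv[best_i])
    # greedy single-position IUPAC generalization while p strictly improves
    repeat {
      improved <- FALSE
      ch <- strsplit(best$word, "", fixed = TRUE)[[1]]
      for (pos in seq_along(ch)) {
        cur_set <- expand_iupac_letter(ch[pos], alph)
        for (amb in names(alph$ambig)) {
          new_set <- alph$ambig[[amb]]
          if (!all(cur_set %in% new_set) || length(new_set) <= length(cur_set)) next
          cand_word <- paste(replace(ch, pos, amb), collapse = "")
          a2 <- sum(sequences_with_word(cand_word, pos_res, alph, both_strands))
          b2 <- sum(sequences_with_word(cand_word, neg_res, alph, both_strands))
          p2 <- fisher_right_tail(a2, A, b2, B)
          n_tested <- n_tested + 1L
          if (p2 < best$p) {
            best <- list(word = cand_word, a = a2, b = b2, p = p2)
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    e_val <- best$p * n_tested
    if (e_val > e_threshold) break
    m <- word_sites_motif(best$word, pos_res, alph, background, both_strands)
    m$name <- best$word
    m$evalue <- e_val
    words_out[[length(words_out) + 1L]] <- data.frame(
      word = best$word, positives_with = best$a, positives_total = A,
      negatives_with = best$b, negatives_total = B, p_value = best$p,
      n_tested = n_tested, e_value = e_val, stringsAsFactors = FALSE)
    motifs_out[[length(motifs_out) + 1L]] <- m
    pos_res <- mask_word(best$word, pos_res, alph, both_strands)
  }
  out <- list(
    words = if (length(words_out)) do.call(rbind, words_out) else data.frame(
      word = character(0), positives_with = integer(0),
      positives_total = integer(0), negatives_with = integer(0),
      negatives_total = integer(0), p_value = numeric(0),
      n_tested = integer(0), e_value = numeric(0)),
    motifs = motifs_out)
  class(out) <- "WordDiscovery"
  out
}

#' @export
print.WordDiscovery <- function(x, ...) {
  cat(sprintf("<WordDiscovery: %d word(s)>\n", nrow(x$words)))
  if (nrow(x$words)) print(x$words[, c("word", "positives_with",
                                       "negatives_with", "p_value", "e_value")])
  invisible(x)
}

expand_iupac_letter <- function(l, alphabet) {
  if (l %in% alphabet$core) l else alphabet$ambig[[l]]
}

# all exact core-letter words of lengths min_k..max_k present in the
# residues, with the number of sequences containing each (both strands)
enumerate_word_counts <- function(residues, alphabet, min_k, max_k,
                                  both_strands) {
  core_rx <- paste0("^[", paste(alphabet$core, collapse = ""), "]+$")
  per_seq <- lapply(residues, function(s) {
    L <- nchar(s)
    words <- character(0)
    variants <- c(s, if (both_strands) revcomp(s, alphabet))
    for (v in variants) {
      for (k in min_k:max_k) {
        if (k > L) next
        subs <- substring(v, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
        words <- c(words, subs)
      }
    }
    unique(words[grepl(core_rx, words)])
  })
  tab <- table(unlist(per_seq))
  w <- names(tab)
  counts <- as.integer(tab)
  if (both_strands) {
    # a word and its reverse complement mark the same sequence set; keep the
    # canonical spelling once (counts are identical under both spellings)
    canon <- pmin(w, revcomp_words(w, alphabet))
    keep <- !duplicated(canon)
    w <- w[keep]; counts <- counts[keep]
  }
  list(word = w, count = counts)
}

# vectorized reverse complement for many same-alphabet words (mixed lengths)
revcomp_words <- function(words, alphabet) {
  comp_from <- paste(names(alphabet$complement), collapse = "")
  comp_to <- paste(unname(alphabet$complement), collapse = "")
  x <- chartr(comp_from, comp_to, words)
  out <- character(length(x))
  for (k in unique(nchar(x))) {
    idx <- which(nchar(x) == k)
    mat <- vapply(k:1, function(i) substring(x[idx], i, i),
                  character(length(idx)))
    if (length(idx) == 1L) mat <- matrix(mat, nrow = 1)
    out[idx] <- do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
  }
  out
}

count_words_in <- function(words, residues, alphabet, both_strands) {
  L <- nchar(residues)
  ks <- sort(unique(nchar(words)))
  per_seq <- lapply(residues, function(s) {
    variants <- c(s, if (both_strands) revcomp(s, alphabet))
    out <- character(0)
    for (v in variants) {
      for (k in ks) {
        if (k > nchar(s)) next
        out <- c(out, substring(v, seq_len(nchar(s) - k + 1L),
                                seq_len(nchar(s) - k + 1L) + k - 1L))
      }
    }
    unique(out)
  })
  tab <- table(unlist(per_seq))
  counts <- as.integer(tab[words])
  counts[is.na(counts)] <- 0L
  counts
}

# build a Motif from the positive-set sites matching an IUPAC word
word_sites_motif <- function(word, residues, alphabet, background,
                             both_strands) {
  k <- nchar(word)
  rx <- iupac_regex(word, alphabet)
  sites <- character(0)
  for (s in residues) {
    mt <- gregexpr(paste0("(?=(", rx, "))"), s, perl = TRUE)[[1]]
    if (mt[1] != -1) sites <- c(sites, substring(s, mt, mt + k - 1L))
    if (both_strands) {
      rs <- revcomp(s, alphabet)
      mt <- gregexpr(paste0("(?=(", rx, "))"), rs, perl = TRUE)[[1]]
      if (mt[1] != -1) sites <- c(sites, substring(rs, mt, mt + k - 1L))
    }
  }
  sites_to_motif(sites, alphabet, background, alpha = 1, name = word)
}

# replace every match of the word (either strand) with wildcards
mask_word <- function(word, residues, alphabet, both_strands) {
  k <- nchar(word)
  wc <- strrep(alphabet$wildcard, k)
  rxs <- iupac_regex(word, alphabet)
  if (both_strands) {
    rc <- revcomp(word, alphabet)
    if (!identical(rc, word)) rxs <- paste0(rxs, "|", iupac_regex(rc, alphabet))
  }
  vapply(residues, function(s) {
    repeat {
      m <- regexpr(rxs, s, perl = TRUE)
      if (m == -1) break
      substr(s, m, m + k - 1L) <- wc
    }
    s
  }, character(1), USE.NAMES = FALSE)
}
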