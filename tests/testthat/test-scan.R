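# brute-force p-values: enumerate all K^w core words, weight by background
enumerate_pvalues <- function(lom, background) {
  core <- lom$motif$alphabet$core
  K <- length(core)
  w <- nrow(lom$bits)
  grid <- do.call(expand.grid, rep(list(seq_len(K)), w))
  ints <- lom$ints[, core, drop = FALSE]
  scores <- apply(grid, 1, function(g) sum(ints[cbind(seq_len(w), g)]))
  weights <- apply(grid, 1, function(g) prod(background$frequencies[g]))
  list(scores = scores, weights = weights,
       pval = function(s) sum(weights[scores >= s]))
}

test_that("DP score distribution equals exhaustive enumeration", {
  set.seed(101)
  for (i in 1:8) {
    w <- sample(2:4, 1)
    m <- counts_to_motif(random_motif(w, DNA, 0.5)$probs * 20 + 0.5, BG_DNA,
                         alpha = 1)
    bgf <- stats::runif(4) + 0.3
    bgx <- background(bgf / sum(bgf), DNA)
    lom <- motif_to_logodds(m, bgx)
    sdist <- score_pvalue_table(lom, bgx)
    oracle <- enumerate_pvalues(lom, bgx)
    for (s in unique(oracle$scores)) {
      expect_equal(motifkit:::score_pvalue(sdist, s), oracle$pval(s),
                   tolerance = 1e-9)
    }
    # maximal score p-value = product of background mass of argmax letters
    pmax_letters <- apply(lom$ints[, DNA$core], 1, function(r) {
      sum(bgx$frequencies[r == max(r)])
    })
    expect_equal(motifkit:::score_pvalue(sdist, sdist$max_score),
                 prod(pmax_letters), tolerance = 1e-9)
    # minimal score has p-value 1 and the pmf sums to 1
    expect_equal(motifkit:::score_pvalue(sdist, 0), 1, tolerance = 1e-9)
    expect_equal(sum(sdist$pmf), 1, tolerance = 1e-9)
    expect_true(all(diff(sdist$tail) <= 1e-12))
  }
})

test_that("width-1 motifs give single-letter tail p-values", {
  m <- motif(matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4, byrow = TRUE), DNA)
  lom <- motif_to_logodds(m, BG_DNA)
  sdist <- score_pvalue_table(lom, BG_DNA)
  # p of A's score: only A scores that high -> 0.25
  expect_equal(motifkit:::score_pvalue(sdist, lom$ints[1, "A"]), 0.25)
  # p of any minority letter's score: all four letters qualify -> 1
  expect_equal(motifkit:::score_pvalue(sdist, lom$ints[1, "C"]), 1)
})

test_that("scan reports hits in forward coordinates on both strands", {
  word <- "TTGACA"
  m <- word_motif(word, DNA, 0.95)
  res <- paste0(strrep("C", 10), word, strrep("C", 10))
  seqs <- sequence_set("s1", res, DNA)
  hits <- scan_motifs(m, seqs, BG_DNA, p_threshold = 1e-3)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 11L)
  expect_equal(plus$stop, 16L)
  expect_equal(plus$matched_sequence, word)
  # reverse-complemented input: strand flips, coordinates mirror
  seqs_rc <- revcomp_set(seqs)
  hits_rc <- scan_motifs(m, seqs_rc, BG_DNA, p_threshold = 1e-3)
  minus <- hits_rc[hits_rc$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  L <- nchar(res)
  expect_equal(minus$start, L - plus$stop + 1L)
  expect_equal(minus$matched_sequence, word)
  expect_equal(minus$score, plus$score)
  expect_equal(minus$p_value, plus$p_value)
  # p_threshold = 0 yields no hits (p-values are strictly positive)
  expect_equal(nrow(scan_motifs(m, seqs, BG_DNA, p_threshold = 0)), 0L)
  # alphabet mismatch is rejected
  expect_error(scan_motifs(random_motif(3, PROT), seqs, BG_DNA), "scan")
})

test_that("scan calibrates on background sequences", {
  set.seed(202)
  m <- counts_to_motif(random_motif(8, DNA, 0.7)$probs * 20 + 0.5, BG_DNA,
                       alpha = 1)
  gen <- generate_planted_dataset(20, 1007, BG_DNA, list(), seed = 77)
  hits <- scan_motifs(m, gen$seqs, BG_DNA, p_threshold = 1e-2,
                      both_strands = FALSE)
  n_windows <- sum(attr(hits, "n_tests"))
  expect_equal(n_windows, 20 * 1000)
  frac <- nrow(hits) / n_windows
  se <- sqrt(1e-2 * 0.99 / n_windows)
  expect_lt(abs(frac - 1e-2), 4 * se)
})

test_that("BH q-values implement the step-up rule (naive reference)", {
  naive_bh <- function(p, m) {
    o <- order(p)
    q <- p[o] * m / seq_along(p)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  expect_equal(bh_qvalues(0.03, 1), 0.03)
  expect_equal(bh_qvalues(c(0.01, 0.04, 0.9), 3), c(0.03, 0.06, 0.9))
  set.seed(9)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    p <- random_pvec(n)
    m <- n + sample(0:20, 1)
    q <- bh_qvalues(p, m)
    expect_equal(q, naive_bh(p, m), tolerance = 1e-12)
    expect_true(all(q >= 0 & q <= 1))
    # q sorted by p is non-decreasing
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_qvalues(c(0.5, 0)), "0, 1")
  expect_error(bh_qvalues(c(0.5, 0.2), m = 1), "at least")
})

test_that("wildcard-heavy windows can be skipped on request", {
  m <- word_motif("TTGACA", DNA, 0.95)
  res <- paste0(strrep("N", 20), "TTGACA", strrep("C", 20))
  seqs <- sequence_set("s1", res, DNA)
  with_mask <- scan_motifs(m, seqs, BG_DNA, p_threshold = 1e-3,
                           skip_masked = TRUE)
  expect_true(all(with_mask$start >= 18))
  expect_lt(sum(attr(with_mask, "n_tests")),
            sum(attr(scan_motifs(m, seqs, BG_DNA, 1e-3), "n_tests")))
})
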