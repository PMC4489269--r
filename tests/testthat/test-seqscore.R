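test_that("best-hit p-values apply the minimum-of-uniforms correction", {
  m <- word_motif("TTGACA", DNA, 0.95)
  # one window only (L = w, single strand): p_seq = p_min
  p1 <- best_hit_pvalues(m, "TTGACA", DNA, BG_DNA, both_strands = FALSE)
  expect_equal(unname(as.numeric(p1)), unname(attr(p1, "p_min")))
  expect_equal(unname(attr(p1, "n_windows")), 1)
  # p_min = 1 stays 1 regardless of the window count
  flat <- motif(matrix(0.25, 4, 4), DNA)
  pf <- best_hit_pvalues(flat, strrep("A", 60), DNA, BG_DNA)
  expect_equal(unname(as.numeric(pf)), 1)
  # motif wider than the sequence contributes 1 with a warning record
  wide <- word_motif(strrep("A", 10), DNA)
  pw <- best_hit_pvalues(list(m, wide), "TTGACA", DNA, BG_DNA,
                         both_strands = FALSE)
  expect_equal(unname(as.numeric(pw)[2]), 1)
  expect_match(attr(pw, "warnings"), "wider")
})

test_that("min-of-n-uniforms correction matches Monte Carlo", {
  set.seed(31)
  n <- 100
  mins <- apply(matrix(stats::runif(1e6), ncol = n), 1, min)
  # analytic: P(min of n uniforms <= p) = 1 - (1 - p)^n
  for (p_min in c(0.001, 0.01, 0.05)) {
    analytic <- 1 - (1 - p_min)^n
    mc <- mean(mins <= p_min)
    expect_lt(abs(mc - analytic) / analytic, 0.05)
  }
})

test_that("combined p-values follow the product-of-uniforms closed form", {
  expect_equal(combine_pvalues(0.2), 0.2)
  expect_equal(combine_pvalues(c(1, 1, 1)), 1)
  expect_error(combine_pvalues(numeric(0)), "empty")
  expect_error(combine_pvalues(c(0.5, 0)), "0, 1")
  # n = 2 closed form: x(1 - ln x)
  x <- 0.01
  expect_equal(combine_pvalues(c(0.1, 0.1)), x * (1 - log(x)),
               tolerance = 1e-12)
  # Monte-Carlo cross-check for n = 2, 3
  set.seed(17)
  for (n in 2:3) {
    u <- matrix(stats::runif(3e5 * n), ncol = n)
    prod_u <- apply(u, 1, prod)
    for (target in c(0.05, 0.2)) {
      ps <- rep(target^(1 / n), n)
      expect_equal(combine_pvalues(ps), mean(prod_u <= target),
                   tolerance = 0.03)
    }
  }
})

test_that("sequence ranking puts the multi-motif sequence first", {
  m1 <- word_motif("TTGACACG", DNA, 0.95, "m1")
  m2 <- word_motif("TATAATGG", DNA, 0.95, "m2")
  set.seed(23)
  for (s in 1:5) {
    gen <- generate_planted_dataset(15, 60, BG_DNA, list(), seed = 400 + s)
    r <- gen$seqs$records$residues
    substr(r[3], 5, 12) <- "TTGACACG"
    substr(r[3], 30, 37) <- "TATAATGG"
    seqs <- sequence_set(gen$seqs$records$id, r, DNA)
    rk <- rank_sequences(list(m1, m2), seqs, BG_DNA)
    expect_equal(rk$sequence_name[1], "seq3")
    expect_equal(rk$e_value, rk$combined_p * 15)
    # permuting input order leaves the ranking unchanged
    perm <- sample(15)
    seqs_p <- sequence_set(seqs$records$id[perm], seqs$records$residues[perm],
                           DNA)
    rk_p <- rank_sequences(list(m1, m2), seqs_p, BG_DNA)
    expect_equal(rk_p$sequence_name, rk$sequence_name)
  }
  # one motif, one sequence: e_value equals the combined p
  one <- sequence_set("a", strrep("ACGT", 10), DNA)
  rk1 <- rank_sequences(m1, one, BG_DNA)
  expect_equal(rk1$e_value, rk1$combined_p)
})

test_that("combined p-values are roughly uniform on background sequences", {
  # smooth (Dirichlet) motifs give many distinct score levels, so the null
  # combined p is nearly continuous; residual deviation reflects overlapping-
  # window dependence, which the min-of-uniforms correction ignores
  set.seed(5)
  m1 <- counts_to_motif(random_motif(8, DNA, 0.7)$probs * 20 + 0.5, BG_DNA,
                        alpha = 1)
  m2 <- counts_to_motif(random_motif(6, DNA, 0.7)$probs * 20 + 0.5, BG_DNA,
                        alpha = 1)
  m1$name <- "m1"; m2$name <- "m2"
  gen <- generate_planted_dataset(1000, 80, BG_DNA, list(), seed = 55)
  rk <- rank_sequences(list(m1, m2), gen$seqs, BG_DNA)
  ks <- suppressWarnings(stats::ks.test(rk$combined_p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("diagram blocks are greedy, non-overlapping and height-capped", {
  mk_hit <- function(start, stop, p, motif = "m1") {
    data.frame(motif_id = motif, motif_alt_id = "", sequence_name = "s",
               start = start, stop = stop, strand = "+", score = 1,
               p_value = p, q_value = p, matched_sequence = "X",
               stringsAsFactors = FALSE)
  }
  hits <- rbind(mk_hit(10, 15, 1e-6), mk_hit(12, 17, 1e-3),
                mk_hit(30, 35, 1e-12), mk_hit(50, 55, 1e-3, "m2"))
  out <- diagram_blocks(hits, p_threshold = 1e-4)
  # overlapping weaker hit dropped; sub-threshold hit dropped
  expect_equal(out$start, c(10, 30))
  # heights capped at the 1e-10 level
  expect_equal(out$height[out$start == 30], 10)
  expect_equal(out$height[out$start == 10], 6)
  expect_match(attr(out, "diagram"), "^9-\\[\\+1\\]-14-\\[\\+1\\]$")
  # no hits under threshold -> empty diagram
  empty <- diagram_blocks(mk_hit(1, 5, 0.5), p_threshold = 1e-4)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "diagram"), "")
})

test_that("N-terminal planting shows up as early block starts", {
  m <- word_motif("MKLVACDEFGH", PROT, 0.95, "sig")
  set.seed(71)
  gen <- generate_planted_dataset(20, 100, BG_PROT, list(), seed = 72)
  r <- gen$seqs$records$residues
  for (i in seq_along(r)) {
    pos <- sample(1:5, 1)
    substr(r[i], pos, pos + 10) <- "MKLVACDEFGH"
  }
  seqs <- sequence_set(gen$seqs$records$id, r, PROT)
  hits <- scan_motifs(m, seqs, BG_PROT, p_threshold = 1e-4,
                      both_strands = FALSE)
  starts <- vapply(split(hits, hits$sequence_name),
                   function(h) min(h$start), numeric(1))
  expect_lt(mean(starts), 0.2 * 100)
})
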