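test_that("standard alphabets carry the expected complements and ambiguities", {
  expect_equal(DNA$core, c("A", "C", "G", "T"))
  expect_equal(unname(DNA$complement[c("A", "C")]), c("T", "G"))
  expect_setequal(DNA$ambig$N, c("A", "C", "G", "T"))
  expect_setequal(DNA$ambig$R, c("A", "G"))
  # complement is an involution on all letters
  expect_equal(unname(DNA$complement[DNA$complement[DNA$letters]]), DNA$letters)
  expect_length(PROT$complement, 0)
  expect_equal(PROT$wildcard, "X")
  expect_equal(RNA$core[4], "U")
  expect_error(make_alphabet("peptide"), "peptide")
  # every ambiguity maps to >= 2 core symbols
  for (a in list(DNA, RNA, PROT)) {
    for (e in names(a$ambig)) {
      expect_true(length(a$ambig[[e]]) >= 2)
      expect_true(all(a$ambig[[e]] %in% a$core))
    }
    expect_setequal(a$ambig[[a$wildcard]], a$core)
  }
})

test_that("background estimation follows pseudocount arithmetic and rejects zeros", {
  s <- sequence_set("s1", "ACGT", DNA)
  bg <- estimate_background(s, pseudocount = 0)
  expect_equal(unname(bg$frequencies), rep(0.25, 4))
  s2 <- sequence_set("s1", "AAAA", DNA)
  expect_error(estimate_background(s2, pseudocount = 0), "positive")
  bg2 <- estimate_background(s2, pseudocount = 1)
  expect_equal(unname(bg2$frequencies["A"]), 0.625)
  expect_equal(unname(bg2$frequencies["C"]), 0.125)
  # ambiguity letters split evenly: R adds half a count to A and to G
  s3 <- sequence_set("s1", "RRCT", DNA)
  bg3 <- estimate_background(s3, pseudocount = 0)
  expect_equal(unname(bg3$frequencies), rep(0.25, 4))
  # a zero frequency violates the Background invariant
  expect_error(estimate_background(sequence_set("s1", "RR", DNA), 0),
               "positive")
  # strand symmetrization
  s4 <- sequence_set("s1", "AAAC", DNA)
  bg4 <- estimate_background(s4, pseudocount = 0, use_both_strands = TRUE)
  expect_equal(unname(bg4$frequencies["A"]), unname(bg4$frequencies["T"]))
  expect_equal(sum(bg4$frequencies), 1, tolerance = 1e-9)
})

test_that("counts_to_motif applies background-proportional pseudocounts", {
  counts <- matrix(c(2, 0, 0, 2), 1, 4, dimnames = list(NULL, DNA$core))
  m <- counts_to_motif(counts, BG_DNA, alpha = 1)
  expect_equal(unname(m$probs[1, ]), c(0.45, 0.05, 0.05, 0.45))
  expect_equal(m$nsites, 4)
  # alpha = 0 with positive counts gives plain relative frequencies
  counts2 <- matrix(c(3, 1, 4, 2), 2, 4)
  counts2 <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1))
  m2 <- counts_to_motif(counts2, BG_DNA, alpha = 0)
  expect_equal(unname(m2$probs[1, ]), c(1, 2, 3, 4) / 10)
  # alpha = 0 with a zero count is rejected
  expect_error(counts_to_motif(counts, BG_DNA, alpha = 0), "zero")
  expect_error(counts_to_motif(matrix(0, 1, 4), BG_DNA), "zeros")
})

test_that("log-odds matrices are zero at background and invert their quantization", {
  m <- motif(matrix(0.25, 3, 4), DNA)
  lom <- motif_to_logodds(m, BG_DNA)
  expect_true(all(abs(lom$bits) < 1e-12))
  m2 <- motif(matrix(c(0.5, 1 / 6, 1 / 6, 1 / 6), 1, 4, byrow = TRUE), DNA)
  lom2 <- motif_to_logodds(m2, BG_DNA)
  expect_equal(unname(lom2$bits[1, 1]), 1)   # log2(0.5 / 0.25)
  # round trip integer -> bits within scale / 2 for every cell
  set.seed(42)
  for (i in 1:5) {
    mr <- random_motif(6, DNA, 0.8)
    mr <- counts_to_motif(mr$probs * 20, BG_DNA, alpha = 1)
    lo <- motif_to_logodds(mr, BG_DNA)
    rec <- lo$offset + lo$scale * lo$ints[, DNA$core]
    expect_true(all(abs(rec - lo$bits) <= lo$scale / 2 + 1e-12))
  }
  m0 <- motif(matrix(c(0.5, 0.5, 0, 0), 1, 4, byrow = TRUE), DNA)
  expect_error(motif_to_logodds(m0, BG_DNA), "zero probability")
})

test_that("information content is the relative entropy in bits", {
  m <- motif(matrix(0.25, 4, 4), DNA)
  expect_equal(information_content(m, BG_DNA)$total, 0)
  md <- motif(matrix(c(1, 0, 0, 0), 1, 4, byrow = TRUE), DNA)
  expect_equal(information_content(md, BG_DNA)$per_position, 2)
  set.seed(7)
  for (i in 1:10) {
    mr <- random_motif(5, DNA, 0.3)
    ic <- information_content(mr, BG_DNA)
    expect_true(all(ic$per_position >= 0))
  }
})

test_that("reverse complement of motifs is an involution preserving IC", {
  set.seed(11)
  for (i in 1:10) {
    m <- random_motif(7, DNA, 0.5)
    m2 <- revcomp_motif(revcomp_motif(m))
    expect_true(max(abs(m2$probs - m$probs)) < 1e-12)
    ic1 <- information_content(m, BG_DNA)$total
    ic2 <- information_content(revcomp_motif(m), BG_DNA)$total
    expect_equal(ic1, ic2, tolerance = 1e-9)
  }
  expect_error(revcomp_motif(random_motif(4, PROT)), "protein")
})

test_that("sequence sets validate identifiers and letters", {
  expect_error(sequence_set(c("a", "a"), c("ACGT", "ACGT"), DNA), "duplicate")
  expect_error(sequence_set("a", "ACGJ", DNA), "'J'")
  s <- sequence_set("a", "acgtn", DNA)
  expect_equal(s$records$residues, "ACGTN")
  expect_equal(revcomp("AACGTN", DNA), "NACGTT")
})
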