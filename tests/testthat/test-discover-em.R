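test_that("seed selection recovers a word present in every sequence", {
  gen <- planted_set("TTGACA", n = 5, L = 40, seed = 21)
  seeds <- seed_starts(gen$seqs, 6, 1, BG_DNA)
  canon <- c(consensus(seeds[[1]]), revcomp(consensus(seeds[[1]]), DNA))
  expect_true("TTGACA" %in% canon)
  # seed matrices stay strictly positive
  expect_true(all(seeds[[1]]$probs > 0))
  # requesting more starts than distinct words truncates
  tiny <- sequence_set("a", "ACGTACG", DNA)
  many <- seed_starts(tiny, 4, 500, BG_DNA)
  expect_lte(length(many), 8)   # 4 forward + 4 reverse windows at most
  expect_error(seed_starts(tiny, 10, 1, BG_DNA), "width")
})

test_that("EM ascends its objective and finds planted OOPS sites", {
  gen <- planted_set("TTGACA", n = 10, L = 100, seed = 42)
  seeds <- seed_starts(gen$seqs, 6, 3, BG_DNA)
  fit <- run_em(gen$seqs, seeds[[1]], model = site_model("oops"),
                background = BG_DNA)
  expect_true(all(diff(fit$trace) >= -1e-9))
  found <- consensus(fit$motif)
  expect_true(found %in% c("TTGACA", revcomp("TTGACA", DNA)))
  # nearly all planted sites located at the truth offsets with confident
  # posteriors (occasional sampled-site mutations can shift one best window)
  sites <- fit$sites[order(fit$sites$sequence), ]
  expect_gte(sum(sites$start == gen$truth$start), 9)
  expect_gte(sum(sites$posterior > 0.9), 9)
  # OOPS posteriors sum to 1 per sequence
  sums <- tapply(fit$posteriors, fit$window_info$seq_id, sum)
  expect_equal(unname(as.numeric(sums)), rep(1, 10), tolerance = 1e-9)
  # an EM fixed point moves the objective by less than tol in one step
  fit2 <- run_em(gen$seqs, fit$motif, model = site_model("oops"),
                 background = BG_DNA, max_iter = 2)
  expect_lt(abs(fit2$trace[2] - fit2$trace[1]),
            1e-5 * (abs(fit2$trace[1]) + 1))
})

test_that("ZOOPS and ANR models run and estimate site priors", {
  gen <- planted_set("TTGACAGG", n = 12, L = 80, seed = 43,
                     occurrence = 0.6)
  seeds <- seed_starts(gen$seqs, 8, 2, BG_DNA)
  fit <- run_em(gen$seqs, seeds[[1]], model = site_model("zoops"),
                background = BG_DNA)
  expect_true(all(diff(fit$trace) >= -1e-9))
  expect_gt(fit$gamma, 0.2)
  expect_lt(fit$gamma, 1)
  fit_anr <- run_em(gen$seqs, seeds[[1]], model = site_model("anr"),
                    background = BG_DNA)
  expect_true(all(diff(fit_anr$trace) >= -1e-9))
  expect_error(site_model("zoops", gamma = 1.5), "gamma")
  expect_error(site_model("anr", gamma = 0), "gamma")
})

test_that("discovery is deterministic and strand-symmetric", {
  gen <- planted_set("TTGACAGC", n = 8, L = 60, seed = 44)
  d1 <- discover_motifs(gen$seqs, 8, 8, seed = 3, n_starts = 5,
                        model = site_model("oops"))
  d2 <- discover_motifs(gen$seqs, 8, 8, seed = 3, n_starts = 5,
                        model = site_model("oops"))
  expect_identical(d1$motifs[[1]]$probs, d2$motifs[[1]]$probs)
  expect_identical(d1$fits[[1]]$llr, d2$fits[[1]]$llr)
  # discovery on the reverse-complemented set agrees up to strand: with both
  # strands searched the reported orientation is arbitrary, so the motif
  # must match the original either directly or after reverse complement
  d_rc <- discover_motifs(revcomp_set(gen$seqs), 8, 8, seed = 3, n_starts = 5,
                          model = site_model("oops"))
  diff_rc <- max(abs(revcomp_motif(d_rc$motifs[[1]])$probs -
                       d1$motifs[[1]]$probs))
  diff_id <- max(abs(d_rc$motifs[[1]]$probs - d1$motifs[[1]]$probs))
  expect_lt(min(diff_rc, diff_id), 1e-6)
})

test_that("significance is monotone in LLR and multiplicity", {
  e1 <- motif_significance(100, 8, 50, 1000)
  expect_equal(motif_significance(100, 8, 100, 1000), 2 * e1)
  expect_lt(motif_significance(120, 8, 50, 1000), e1)
  # a background-equal motif (LLR 0) sits at the maximum for its search
  expect_equal(motif_significance(0, 8, 50, 1000), 50)
  # paired planted vs background-only runs
  gen_sig <- planted_set("TTGACAGG", n = 20, L = 100, seed = 45)
  gen_nul <- generate_planted_dataset(20, 100, BG_DNA, list(), seed = 45)
  d_sig <- discover_motifs(gen_sig$seqs, 8, 8, seed = 4, n_starts = 5,
                           model = site_model("oops"))
  d_nul <- discover_motifs(gen_nul$seqs, 8, 8, seed = 4, n_starts = 5,
                           model = site_model("oops"))
  expect_lt(d_sig$motifs[[1]]$evalue, d_nul$motifs[[1]]$evalue)
})

test_that("erasing prevents rediscovery and respects weight bounds", {
  set.seed(46)
  gen <- generate_planted_dataset(
    12, 90, BG_DNA,
    list(plant_spec(word_motif("TTGACAGC", DNA, 0.999)),
         plant_spec(word_motif("GGATCCTT", DNA, 0.999))),
    seed = 46)
  d <- discover_motifs(gen$seqs, 8, 8, n_motifs = 2, seed = 5, n_starts = 8,
                       model = site_model("oops"))
  cons <- vapply(d$motifs, consensus, character(1))
  agree <- vapply(cons, function(cs) {
    c(consensus_agreement(cs, "TTGACAGC"), consensus_agreement(cs, "GGATCCTT"))
  }, numeric(2))
  # each planted word is matched by one (distinct) discovered motif
  expect_true(all(apply(agree, 1, max) >= 0.75))
  expect_false(cons[1] == cons[2])
  # weight bookkeeping: erasing strong sites keeps weights in [0, 1] and
  # zero posteriors are the identity
  fit <- d$fits[[1]]
  wts <- erase_and_repeat(gen$seqs, fit)
  expect_true(all(unlist(wts) >= 0 & unlist(wts) <= 1))
  fit0 <- fit
  fit0$posteriors <- rep(0, length(fit0$posteriors))
  wts0 <- erase_and_repeat(gen$seqs, fit0)
  expect_true(all(unlist(wts0) == 1))
})

test_that("width search and input validation behave", {
  gen <- planted_set("TTGACA", n = 6, L = 30, seed = 47)
  expect_error(discover_motifs(gen$seqs, 0, 4), "width")
  expect_error(discover_motifs(gen$seqs, 4, 40), "shortest")
  expect_error(discover_motifs(gen$seqs, 4, 4, n_motifs = 0), "n_motifs")
  d <- discover_motifs(gen$seqs, 5, 7, seed = 6, n_starts = 3,
                       model = site_model("oops"))
  expect_true(motif_width(d$motifs[[1]]) %in% 5:7)
})

test_that("protein discovery recovers a planted conserved block", {
  blk <- "MKLVACDEFGH"
  set.seed(48)
  gen <- planted_set(blk, n = 5, L = 100, seed = 48, p_match = 0.9,
                     alphabet = PROT, background = BG_PROT)
  d <- discover_motifs(gen$seqs, 11, 11, seed = 7, n_starts = 10,
                       model = site_model("oops"), background = BG_PROT)
  expect_gte(consensus_agreement(consensus(d$motifs[[1]]), blk, PROT), 9 / 11)
})
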