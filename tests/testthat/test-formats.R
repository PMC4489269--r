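test_that("FASTA reading concatenates lines and splits headers", {
  fa <- ">s1 first desc\nACGT\nACGT\n>s2\nGGGG"
  s <- read_fasta(fa)
  expect_equal(length(s), 2L)
  expect_equal(s$records$id, c("s1", "s2"))
  expect_equal(s$records$description[1], "first desc")
  expect_equal(nchar(s$records$residues[1]), 8L)
})

test_that("FASTA round-trips through write and re-read", {
  set.seed(5)
  gen <- planted_set("TTGACA", n = 5, L = 40, seed = 5)
  tf <- tempfile(fileext = ".fa")
  write_fasta(gen$seqs, tf)
  s2 <- read_fasta(tf)
  expect_equal(s2$records$id, gen$seqs$records$id)
  expect_equal(s2$records$residues, gen$seqs$records$residues)
  # a second write is byte-identical
  tf2 <- tempfile(fileext = ".fa")
  write_fasta(s2, tf2)
  expect_identical(readLines(tf), readLines(tf2))
})

test_that("invalid FASTA letters are reported with their line", {
  tf <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT", "ACGJ"), tf)
  err <- tryCatch(read_fasta(tf, alphabet = DNA), error = conditionMessage)
  expect_match(err, "J")
  expect_match(err, "line 3")
})

test_that("alphabet inference prefers DNA, then RNA, then protein", {
  expect_equal(infer_alphabet("ACGTN")$name, "DNA")
  expect_equal(infer_alphabet("ACGU")$name, "RNA")
  expect_equal(infer_alphabet("MKLVQ")$name, "protein")
})

test_that("MEME motif files round-trip at printed precision", {
  set.seed(13)
  for (rep in 1:20) {
    nm <- sample(1:3, 1)
    motifs <- lapply(seq_len(nm), function(i) {
      m <- random_motif(sample(3:9, 1), DNA, 0.7, name = paste0("M", i))
      m$nsites <- sample(5:50, 1)
      m$evalue <- stats::runif(1)
      m
    })
    bgf <- stats::runif(4) + 0.2
    mf <- motif_file(motifs, background = background(bgf / sum(bgf), DNA))
    txt <- write_meme_motifs(mf)
    mf2 <- parse_meme_motifs(txt)
    expect_equal(length(mf2$motifs), nm)
    for (i in seq_len(nm)) {
      expect_lt(max(abs(mf2$motifs[[i]]$probs - motifs[[i]]$probs)), 1e-5)
      expect_equal(mf2$motifs[[i]]$nsites, motifs[[i]]$nsites)
    }
    # write -> read -> write is a fixed point
    expect_identical(write_meme_motifs(mf2), txt)
  }
})

test_that("MEME parsing takes header metadata and rejects malformed blocks", {
  txt <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "Background letter frequencies",
           "A 0.25 C 0.25 G 0.25 T 0.25", "",
           "MOTIF crp alt1",
           "letter-probability matrix: alength= 4 w= 2 nsites= 20 E= 1.1e-5",
           "0.25 0.25 0.25 0.25", "0.10 0.20 0.30 0.40", "")
  mf <- parse_meme_motifs(txt)
  m <- mf$motifs[[1]]
  expect_equal(m$name, "crp")
  expect_equal(m$alt_name, "alt1")
  expect_equal(nrow(m$probs), 2)
  expect_equal(m$nsites, 20)
  expect_equal(m$evalue, 1.1e-5)
  bad <- txt
  bad[10] <- "0.25 0.25 0.25 0.25 0.25"      # 5 values under DNA
  expect_error(parse_meme_motifs(bad), "row 1")
  bad2 <- txt
  bad2[10] <- "0.80 0.25 0.25 0.25"          # does not sum to 1
  expect_error(parse_meme_motifs(bad2), "sums")
  bad3 <- sub("alength= 4", "alength= 5", txt)
  expect_error(parse_meme_motifs(bad3), "alength")
  # empty motif list still writes a valid header-only file
  empty <- write_meme_motifs(motif_file(alphabet = DNA))
  expect_equal(length(parse_meme_motifs(empty)$motifs), 0)
  expect_equal(sum(grepl("^MOTIF", empty)), 0)
})

test_that("typed motifs: aligned sites build fractional count matrices", {
  ms <- parse_typed_motifs("ACGT\nACGA", DNA, alpha = 0)
  expect_equal(length(ms), 1)
  m <- ms[[1]]
  expect_equal(nrow(m$probs), 4)
  expect_equal(unname(m$probs[4, c("A", "T")]), c(0.5, 0.5))
  expect_equal(m$nsites, 2)
  # n identical sites give that consensus and nsites = n
  ms2 <- parse_typed_motifs("TTGACA\nTTGACA\nTTGACA", DNA, alpha = 0)
  expect_equal(consensus(ms2[[1]]), "TTGACA")
  expect_equal(ms2[[1]]$nsites, 3)
  # IUPAC letters contribute fractionally
  ms3 <- parse_typed_motifs("R\nA", DNA, alpha = 0)
  expect_equal(unname(ms3[[1]]$probs[1, "A"]), 0.75)
  expect_error(parse_typed_motifs("ACGT\nACG", DNA), "inconsistent lengths")
  expect_error(parse_typed_motifs("AC!T", DNA), "unsupported character")
})

test_that("typed motifs: numeric orientation detection and tie-break", {
  # 4 rows x 6 columns whose columns sum to 1 -> rows are letters, width 6
  M <- matrix(1 / 4, 4, 6)
  M[1, 1] <- 0.7; M[2, 1] <- 0.1; M[3, 1] <- 0.1; M[4, 1] <- 0.1
  txt <- paste(apply(M, 1, paste, collapse = " "), collapse = "\n")
  m <- parse_typed_motifs(txt, DNA, alpha = 0)[[1]]
  expect_equal(nrow(m$probs), 6)
  expect_equal(unname(m$probs[1, "A"]), 0.7)
  # a 4x4 probability matrix is ambiguous; rows-as-positions wins
  amb <- paste(rep("0.1 0.2 0.3 0.4", 4), collapse = "\n")
  m2 <- parse_typed_motifs(amb, DNA, alpha = 0)[[1]]
  expect_equal(nrow(m2$probs), 4)
  expect_equal(unname(m2$probs[1, ]), c(0.1, 0.2, 0.3, 0.4))
  # count matrix: nsites = common row total
  cnt <- "5 3 1 1\n2 2 3 3"
  m3 <- parse_typed_motifs(cnt, DNA, alpha = 0)[[1]]
  expect_equal(m3$nsites, 10)
  # blank lines separate multiple motifs
  multi <- parse_typed_motifs("ACGT\nACGT\n\nTTTT\nTTTT", DNA)
  expect_equal(length(multi), 2)
})
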