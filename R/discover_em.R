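#' Site-count models for EM motif discovery
#'
#' `OOPS` assumes exactly one site per sequence, `ZOOPS` zero or one
#' (per-sequence site probability `gamma`), `ANR` any number of repetitions
#' (`gamma` = prior site probability per window). `gamma` is re-estimated at
#' every M-step for ZOOPS and ANR.
#'
#' @param kind `"oops"`, `"zoops"` or `"anr"` (case-insensitive).
#' @param gamma Initial site prior; ignored for OOPS.
#' @return An object of class `SiteModel`.
#' @export
site_model <- function(kind = c("zoops", "oops", "anr"), gamma = 0.5) {
  kind <- tolower(kind[1])
  kind <- match.arg(kind)
  if (kind == "zoops" && (gamma <= 0 || gamma > 1)) stop("ZOOPS gamma must be in (0, 1]")
  if (kind == "anr" && gamma <= 0) stop("ANR gamma must be > 0")
  structure(list(kind = kind, gamma = gamma), class = "SiteModel")
}

# --- window bookkeeping -----------------------------------------------------
# Enumerate all admissible width-w windows of a SequenceSet (both strands for
# nucleotides): an integer letter matrix X (windows x w), the sequence index,
# forward-strand start, strand, and log2 erasure weight of each window.
em_windows <- function(seqs, w, both_strands, weights = NULL) {
  alph <- seqs$alphabet
  n <- length(seqs)
  lens <- seq_lengths(seqs)
  if (w > min(lens)) {
    stop("width ", w, " exceeds the shortest sequence length (", min(lens), ")")
  }
  X_list <- list(); seq_id <- list(); fstart <- list(); strand <- list()
  lw <- list()
  for (i in seq_len(n)) {
    res <- seqs$records$residues[i]
    L <- lens[i]
    m <- L - w + 1L
    s_int <- encode_seq(res, alph)
    Xf <- matrix(0L, m, w)
    for (j in seq_len(w)) Xf[, j] <- s_int[j:(j + m - 1L)]
    posw <- if (is.null(weights)) rep(1, L) else weights[[i]]
    lpw <- log2(pmax(posw, 1e-300))
    lw_f <- as.numeric(stats::filter(lpw, rep(1, w), sides = 1))[w:L]
    X_list[[length(X_list) + 1L]] <- Xf
    seq_id[[length(seq_id) + 1L]] <- rep(i, m)
    fstart[[length(fstart) + 1L]] <- seq_len(m)
    strand[[length(strand) + 1L]] <- rep("+", m)
    lw[[length(lw) + 1L]] <- lw_f
    if (both_strands) {
      rc_int <- encode_seq(revcomp(res, alph), alph)
      Xr <- matrix(0L, m, w)
      for (j in seq_len(w)) Xr[, j] <- rc_int[j:(j + m - 1L)]
      # rc window k starts (forward coords) at L - k - w + 2
      fs <- L - seq_len(m) - w + 2L
      X_list[[length(X_list) + 1L]] <- Xr
      seq_id[[length(seq_id) + 1L]] <- rep(i, m)
      fstart[[length(fstart) + 1L]] <- fs
      strand[[length(strand) + 1L]] <- rep("-", m)
      lw[[length(lw) + 1L]] <- lw_f[fs]
    }
  }
  X <- do.call(rbind, X_list)
  n_letters <- length(alph$letters)
  # one-hot window-letter matrix: column (j-1)*n_letters + e is 1 when the
  # window's j-th letter is e; E- and M-steps become sparse matrix products
  H <- Matrix::sparseMatrix(
    i = rep(seq_len(nrow(X)), w),
    j = as.vector(sweep(X, 2, (seq_len(w) - 1L) * n_letters, "+")),
    x = 1, dims = c(nrow(X), w * n_letters))
  list(X = X, H = H,
       seq_id = unlist(seq_id), fstart = unlist(fstart),
       strand = unlist(strand), lw = unlist(lw),
       n_seqs = n, alphabet = alph, width = w)
}

lse2 <- function(v) { mx <- max(v); mx + log2(sum(2^(v - mx))) }

# grouped E-step (posterior over window offsets per sequence) for OOPS and
# ZOOPS; windows are contiguous per sequence. When all sequences expose the
# same number of windows the computation is one matrix reshape, otherwise a
# per-sequence loop.
estep_grouped <- function(v, kind, gamma, bounds, m_per_seq) {
  n_seqs <- length(m_per_seq)
  if (length(unique(m_per_seq)) == 1L) {
    m2 <- m_per_seq[1]
    V <- matrix(v, nrow = m2)
    mx <- apply(V, 2, max)
    Ex <- 2^(V - rep(mx, each = m2))
    cs <- colSums(Ex)
    if (kind == "oops") {
      z <- as.numeric(Ex / rep(cs, each = m2))
      obj <- sum(mx + log2(cs) - log2(m2))
      return(list(z = z, obj = obj, qsum = NA_real_))
    }
    t0 <- (1 - gamma + 1e-300) * 2^(-mx)
    denom <- t0 + (gamma / m2) * cs
    z <- as.numeric((gamma / m2) * Ex / rep(denom, each = m2))
    obj <- sum(mx + log2(denom))
    return(list(z = z, obj = obj, qsum = sum(z)))
  }
  z <- numeric(length(v))
  obj <- 0; qsum <- 0
  for (s in seq_len(n_seqs)) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    if (kind == "oops") {
      lse <- lse2(v[idx])
      z[idx] <- 2^(v[idx] - lse)
      obj <- obj + lse - log2(m_per_seq[s])
    } else {
      terms <- c(log2(1 - gamma + 1e-300), log2(gamma / m_per_seq[s]) + v[idx])
      lse <- lse2(terms)
      z[idx] <- 2^(terms[-1] - lse)
      qsum <- qsum + sum(z[idx])
      obj <- obj + lse
    }
  }
  list(z = z, obj = obj, qsum = qsum)
}

#' Run expectation-maximization motif refinement from an initial motif
#'
#' Alternates posterior site assignment (E-step, over every admissible
#' window on both strands for nucleotides) with motif re-estimation from
#' posterior-weighted letter counts plus background-proportional
#' pseudocounts (M-step), under an OOPS, ZOOPS or ANR site model. The
#' maximized objective is the log2 likelihood ratio against the
#' background-only model plus the (Dirichlet) pseudocount prior; its trace
#' is non-decreasing, a property asserted by the test suite. Iteration stops
#' when the relative objective change drops below `tol` or after `max_iter`
#' iterations.
#'
#' @param seqs A `SequenceSet`.
#' @param init Initial `Motif` (its width fixes the search width).
#' @param model A `SiteModel` (default ZOOPS with gamma 0.5).
#' @param background A `Background`; uniform if `NULL`.
#' @param max_iter,tol Convergence controls.
#' @param both_strands Search both strands (default: nucleotide alphabets).
#' @param alpha Total pseudocount mass per motif position.
#' @param weights Optional per-sequence position weight vectors in [0, 1]
#'   (probabilistic erasing of already-found sites).
#' @param windows Precomputed [em_windows()] bookkeeping (internal reuse).
#' @return List with `motif`, `sites` (data.frame: `sequence`, `start`,
#'   `strand`, `posterior`), `llr` (unpenalized log2 likelihood ratio),
#'   `trace` (penalized objective per iteration), `gamma`, `iterations`,
#'   and `posteriors` (per-window posterior weights).
#' @export
run_em <- function(seqs, init, model = site_model("zoops"), background = NULL,
                   max_iter = 200L, tol = 1e-6,
                   both_strands = is_nucleotide(seqs$alphabet),
                   alpha = 0.01, weights = NULL, windows = NULL) {
  if (is.null(background)) background <- uniform_background(seqs$alphabet)
  alph <- seqs$alphabet
  w <- motif_width(init)
  both_strands <- both_strands && is_nucleotide(alph)
  if (is.null(windows)) windows <- em_windows(seqs, w, both_strands, weights)
  X <- windows$X
  n_seqs <- windows$n_seqs
  grp <- windows$seq_id
  ord <- order(grp)
  stopifnot(!is.unsorted(grp))    # em_windows emits windows grouped by sequence
  bounds <- c(0L, cumsum(tabulate(grp, n_seqs)))
  m_per_seq <- diff(bounds)
  bg <- background$frequencies
  K <- length(alph$core)
  E <- expansion_weights(alph, background)
  probs <- init$probs
  gamma <- model$gamma
  trace <- numeric(0)
  z <- NULL
  prior_term <- function(p) sum(sweep(log2(p), 2, alpha * bg, "*"))
  bg_ext <- as.numeric(E %*% bg)
  for (iter in seq_len(max_iter)) {
    pm <- probs %*% t(E)
    Lw <- log2(sweep(pm, 2, bg_ext, "/"))
    v <- as.numeric(windows$H %*% as.vector(t(Lw))) + windows$lw
    if (model$kind == "anr") {    # ANR: independent Bernoulli per window
      lr <- 2^v
      z <- gamma * lr / (gamma * lr + (1 - gamma))
      obj <- sum(log2(gamma * lr + (1 - gamma)))
      gamma_new <- min(max(mean(z), 1e-9), 1 - 1e-6)
    } else {
      es <- estep_grouped(v, model$kind, gamma, bounds, m_per_seq)
      z <- es$z
      obj <- es$obj
      if (model$kind == "zoops") {
        gamma_new <- min(max(es$qsum / n_seqs, 1e-6), 1 - 1e-6)
      }
    }
    trace <- c(trace, obj + prior_term(probs))
    # M-step: posterior-weighted letter counts (one sparse crossproduct)
    cnt_ext <- matrix(as.numeric(Matrix::crossprod(windows$H, z)),
                      nrow = nrow(E), ncol = w)
    counts <- t(cnt_ext) %*% E
    colnames(counts) <- alph$core
    probs_new <- sweep(counts, 2, alpha * bg, "+")
    probs_new <- probs_new / rowSums(probs_new)
    if (model$kind != "oops") gamma <- gamma_new
    converged <- length(trace) > 1 &&
      abs(trace[iter] - trace[iter - 1]) <= tol * (abs(trace[iter - 1]) + 1e-9)
    probs <- probs_new
    if (converged) break
  }
  # final objective (unpenalized LLR) under the returned parameters
  llr <- em_objective(probs, windows, model, gamma, background, bounds, m_per_seq)
  nsites <- switch(model$kind, oops = n_seqs, zoops = sum(z), anr = sum(z))
  out_motif <- motif(probs, alph, name = init$name, nsites = max(nsites, 1),
                     evalue = NA_real_)
  sites <- em_sites(z, windows, model, bounds)
  list(motif = out_motif, sites = sites, llr = llr, trace = trace,
       gamma = if (model$kind == "oops") NA_real_ else gamma,
       iterations = length(trace), posteriors = z, windows_n = nrow(X),
       window_info = list(seq_id = windows$seq_id, fstart = windows$fstart,
                          strand = windows$strand))
}

em_objective <- function(probs, windows, model, gamma, background, bounds,
                         m_per_seq) {
  alph <- windows$alphabet
  E <- expansion_weights(alph, background)
  pm <- probs %*% t(E)
  bg_ext <- as.numeric(E %*% background$frequencies)
  Lw <- log2(sweep(pm, 2, bg_ext, "/"))
  v <- as.numeric(windows$H %*% as.vector(t(Lw))) + windows$lw
  n_seqs <- windows$n_seqs
  obj <- 0
  if (model$kind == "oops") {
    for (s in seq_len(n_seqs)) {
      idx <- (bounds[s] + 1L):bounds[s + 1L]
      obj <- obj + lse2(v[idx]) - log2(m_per_seq[s])
    }
  } else if (model$kind == "zoops") {
    for (s in seq_len(n_seqs)) {
      idx <- (bounds[s] + 1L):bounds[s + 1L]
      obj <- obj + lse2(c(log2(1 - gamma + 1e-300),
                          log2(gamma / m_per_seq[s]) + v[idx]))
    }
  } else {
    obj <- sum(log2(gamma * 2^v + (1 - gamma)))
  }
  obj
}

em_sites <- function(z, windows, model, bounds) {
  n_seqs <- windows$n_seqs
  if (model$kind == "anr") {
    keep <- which(z >= 0.5)
  } else {
    keep <- vapply(seq_len(n_seqs), function(s) {
      idx <- (bounds[s] + 1L):bounds[s + 1L]
      idx[which.max(z[idx])]
    }, integer(1))
  }
  data.frame(sequence = windows$seq_id[keep],
             start = windows$fstart[keep],
             strand = windows$strand[keep],
             posterior = z[keep], stringsAsFactors = FALSE)
}

# --- seeding ---------------------------------------------------------------

#' Select high-likelihood starting motifs from observed subsequences
#'
#' Every width-`width` subsequence (both strands for nucleotides) is a
#' candidate seed: the observed word gets match probability `m_match` and
#' the remainder is spread evenly over the other letters, keeping the matrix
#' strictly positive. Candidates are ranked by their one-pass OOPS
#' likelihood (computed jointly for all candidates via sparse match-count
#' algebra) and the `n_starts` best distinct words are returned. At larger
#' problem sizes candidates and evaluation windows are thinned
#' deterministically by even strides (`max_candidates`, `max_eval_windows`).
#'
#' @param seqs A `SequenceSet`.
#' @param width Seed width.
#' @param n_starts Number of seeds to return.
#' @param background A `Background`; uniform if `NULL`.
#' @param both_strands Consider both strands (nucleotides only).
#' @param m_match Seed match probability (default 0.7).
#' @param max_candidates,max_eval_windows Thinning bounds.
#' @param weights Optional erasure weights (as in [run_em()]).
#' @return List of seed `Motif`s, ordered by decreasing one-pass likelihood
#'   (ties broken by canonical word), each named after its word.
#' @export
seed_starts <- function(seqs, width, n_starts, background = NULL,
                        both_strands = is_nucleotide(seqs$alphabet),
                        m_match = 0.7, max_candidates = 2000L,
                        max_eval_windows = 5000L, weights = NULL) {
  if (is.null(background)) background <- uniform_background(seqs$alphabet)
  alph <- seqs$alphabet
  both_strands <- both_strands && is_nucleotide(alph)
  win <- em_windows(seqs, width, both_strands, weights)
  X <- win$X
  K <- length(alph$core)
  core_only <- rowSums(X > K) == 0
  cand_rows <- which(core_only)
  if (!length(cand_rows)) stop("no candidate seeds without ambiguity letters")
  if (length(cand_rows) > max_candidates) {
    cand_rows <- cand_rows[unique(round(seq(1, length(cand_rows),
                                            length.out = max_candidates)))]
  }
  words <- apply(matrix(alph$letters[X[cand_rows, , drop = FALSE]],
                        ncol = width), 1, paste, collapse = "")
  first <- !duplicated(words)
  cand_rows <- cand_rows[first]
  words <- words[first]
  eval_rows <- seq_len(nrow(X))
  if (length(eval_rows) > max_eval_windows) {
    eval_rows <- eval_rows[unique(round(seq(1, length(eval_rows),
                                            length.out = max_eval_windows)))]
  }
  # match counts candidates x eval windows via one-hot sparse crossproduct
  n_letters <- length(alph$letters)
  onehot <- function(rows) {
    Xi <- X[rows, , drop = FALSE]
    Matrix::sparseMatrix(
      i = rep(seq_along(rows), width),
      j = as.vector(sweep(Xi, 2, (seq_len(width) - 1L) * n_letters, "+")),
      x = 1, dims = c(length(rows), width * n_letters))
  }
  M <- as.matrix(onehot(cand_rows) %*% Matrix::t(onehot(eval_rows)))
  bg <- background$frequencies
  bg_ext <- as.numeric(expansion_weights(alph, background) %*% bg)
  mis <- (1 - m_match) / (K - 1)
  # base log2 LR of each eval window if no position matched, plus erasure
  base <- numeric(length(eval_rows))
  Xe <- X[eval_rows, , drop = FALSE]
  for (j in seq_len(width)) base <- base + log2(mis / bg_ext[Xe[, j]])
  base <- base + win$lw[eval_rows]
  step <- log2(m_match / mis)
  V <- sweep(step * M, 2, base, "+")
  P <- 2^V
  grp <- win$seq_id[eval_rows]
  G <- t(rowsum(t(P), grp))                  # candidates x n_groups
  m_g <- as.numeric(table(grp))
  obj <- rowSums(log2(pmax(G, 1e-300)) -
                   matrix(log2(m_g), nrow(G), length(m_g), byrow = TRUE))
  canon <- if (is_nucleotide(alph)) pmin(words, revcomp(words, alph)) else words
  ord <- order(-round(obj, 9), canon, words)
  take <- utils::head(ord, n_starts)
  lapply(take, function(k) {
    ch <- strsplit(words[k], "", fixed = TRUE)[[1]]
    probs <- matrix(mis, width, K, dimnames = list(NULL, alph$core))
    probs[cbind(seq_len(width), match(ch, alph$core))] <- m_match
    motif(probs, alph, name = words[k], nsites = win$n_seqs)
  })
}

# --- significance ----------------------------------------------------------

# Calibration of the null log2 likelihood-ratio scale for the E-value
# estimate, fitted once on background-only simulations (best-of-10-starts
# OOPS fits of seeded EM on i.i.d. background sequences across widths, set
# sizes and both alphabets). The dominant term is the chi-square-like
# overfitting gain of the w*(K-1) free motif parameters; the remainder
# captures start-selection and window-count effects.
.llr0_coef <- c(chisq = 1.042, per_width = 2.669, log_windows = -0.938)

llr_null_expectation <- function(width, alphabet_size, n_windows) {
  co <- .llr0_coef
  max(0, co[["chisq"]] * width * (alphabet_size - 1) / (2 * log(2)) +
        co[["per_width"]] * width +
        co[["log_windows"]] * log2(pmax(n_windows, 2)))
}

#' E-value estimate for a fitted motif
#'
#' `E = n_tests * exp(-max(0, LLR - LLR0))`, where `LLR0` is the expected
#' log2 likelihood ratio of an equally sized fit on background-only data
#' (a calibration constant; see the methods vignette). The estimate is
#' monotone decreasing in the log likelihood ratio at fixed width and site
#' count, and scales linearly with the number of candidate starts tested.
#' It is deliberately conservative: a heuristic multiplicity-corrected
#' bound, not an exact tail probability.
#'
#' @param llr Fitted log2 likelihood ratio (from [run_em()]).
#' @param width Motif width.
#' @param n_tests Number of candidate starts examined in the search.
#' @param n_windows Number of windows searched (for the null calibration).
#' @param alphabet_size Number of core symbols (4 for DNA/RNA, 20 protein).
#' @return Non-negative E-value estimate.
#' @export
motif_significance <- function(llr, width, n_tests, n_windows,
                               alphabet_size = 4L) {
  llr0 <- llr_null_expectation(width, alphabet_size, n_windows)
  unname(n_tests * exp(-max(0, llr - llr0)))
}

# --- erasing and the multi-motif loop --------------------------------------

#' Down-weight positions covered by a found motif's sites
#'
#' Multiplies each covered position's weight by `1 - posterior`, so that
#' subsequent discovery rounds avoid re-finding the same sites. Weights stay
#' in [0, 1]; erasing with all-zero posteriors is the identity.
#'
#' @param seqs The `SequenceSet` that was searched.
#' @param fit A [run_em()] result (uses its window posteriors).
#' @param weights Existing per-sequence weight vectors, or `NULL` for all 1.
#' @param min_posterior Windows below this posterior are skipped (their
#'   effect on the weights is negligible).
#' @return Updated list of per-sequence position weight vectors.
#' @export
erase_and_repeat <- function(seqs, fit, weights = NULL, min_posterior = 0.01) {
  lens <- seq_lengths(seqs)
  if (is.null(weights)) weights <- lapply(lens, function(L) rep(1, L))
  z <- fit$posteriors
  w <- motif_width(fit$motif)
  keep <- which(z > min_posterior)
  info <- fit$window_info
  if (is.null(info)) stop("fit does not carry window coordinates")
  for (k in keep) {
    i <- info$seq_id[k]
    a <- info$fstart[k]
    rng <- a:(a + w - 1L)
    weights[[i]][rng] <- pmin(pmax(weights[[i]][rng] * (1 - z[k]), 0), 1)
  }
  weights
}

#' Discover multiple motifs by seeded EM with probabilistic erasing
#'
#' For each requested motif: seeds are selected at every width in
#' `min_width:max_width`, EM is run to convergence from each seed, the fit
#' with the best (smallest) E-value estimate is kept, its sites are erased,
#' and the search repeats. Deterministic given `seed`.
#'
#' @param seqs A `SequenceSet`.
#' @param min_width,max_width Width range searched (every integer width).
#' @param n_motifs Number of motifs to report.
#' @param model A `SiteModel` (default ZOOPS).
#' @param background A `Background`; uniform if `NULL`.
#' @param seed Integer seed (the search is deterministic; the seed guards
#'   any stochastic sub-steps).
#' @param n_starts Seeds per width (default 50).
#' @param both_strands Search both strands (nucleotides only).
#' @param max_candidates,max_eval_windows Seeding bounds (see
#'   [seed_starts()]).
#' @param ... Further arguments to [run_em()] (`max_iter`, `tol`, `alpha`).
#' @return An object of class `DiscoveryResult`: list with `motifs`
#'   (ordered by ascending E-value estimate) and `fits` (per motif: `sites`,
#'   `llr`, `evalue`, `gamma`, `width`, `iterations`).
#' @export
discover_motifs <- function(seqs, min_width, max_width = min_width,
                            n_motifs = 1L, model = site_model("zoops"),
                            background = NULL, seed = 1L, n_starts = 50L,
                            both_strands = is_nucleotide(seqs$alphabet),
                            max_candidates = 2000L, max_eval_windows = 5000L,
                            ...) {
  if (n_motifs < 1) stop("n_motifs must be at least 1")
  if (min_width < 1 || min_width > max_width) stop("invalid width range")
  if (max_width > min(seq_lengths(seqs))) {
    stop("max_width exceeds the shortest sequence")
  }
  if (is.null(background)) background <- uniform_background(seqs$alphabet)
  both_strands <- both_strands && is_nucleotide(seqs$alphabet)
  weights <- NULL
  motifs <- list(); fits <- list()
  withr::with_seed(seed, {
    for (r in seq_len(n_motifs)) {
      best <- NULL
      n_tests_total <- 0
      cand_fits <- list()
      for (w in min_width:max_width) {
        seeds <- seed_starts(seqs, w, n_starts, background = background,
                             both_strands = both_strands,
                             max_candidates = max_candidates,
                             max_eval_windows = max_eval_windows,
                             weights = weights)
        n_tests_total <- n_tests_total + length(seeds)
        win <- em_windows(seqs, w, both_strands, weights)
        for (sd_m in seeds) {
          fit <- run_em(seqs, sd_m, model = model, background = background,
                        both_strands = both_strands, weights = weights,
                        windows = win, ...)
          fit$width <- w
          cand_fits[[length(cand_fits) + 1L]] <- fit
        }
      }
      for (k in seq_along(cand_fits)) {
        f <- cand_fits[[k]]
        cand_fits[[k]]$evalue <- motif_significance(
          f$llr, f$width, n_tests_total, f$windows_n,
          alphabet_size = length(seqs$alphabet$core))
      }
      evs <- vapply(cand_fits, function(f) f$evalue, numeric(1))
      llrs <- vapply(cand_fits, function(f) f$llr, numeric(1))
      best <- cand_fits[[order(evs, -llrs)[1]]]
      best$motif$name <- paste0("motif_", r)
      best$motif$evalue <- best$evalue
      motifs[[r]] <- best$motif
      fits[[r]] <- best
      if (r < n_motifs) weights <- erase_and_repeat(seqs, best, weights)
    }
  })
  ord <- order(vapply(fits, function(f) f$evalue, numeric(1)))
  out <- list(motifs = motifs[ord], fits = fits[ord])
  class(out) <- "DiscoveryResult"
  out
}

#' @export
print.DiscoveryResult <- function(x, ...) {
  cat(sprintf("<DiscoveryResult: %d motif(s)>\n", length(x$motifs)))
  for (i in seq_along(x$motifs)) {
    m <- x$motifs[[i]]
    cat(sprintf("  %s: width %d, consensus %s, E ~ %.3g\n",
                m$name, motif_width(m), consensus(m), m$evalue))
  }
  invisible(x)
}
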