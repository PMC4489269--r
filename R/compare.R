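#' Similarity between two motif columns
#'
#' `pearson` is the Pearson correlation of the two probability vectors
#' (defined as 0 when either vector is constant); `neg_euclid` is the
#' negated Euclidean distance (maximum 0 for identical columns).
#'
#' @param q_col,t_col Probability vectors over the same alphabet.
#' @param metric `"pearson"` or `"neg_euclid"`.
#' @return Numeric similarity.
#' @export
column_similarity <- function(q_col, t_col, metric = c("pearson", "neg_euclid")) {
  metric <- match.arg(metric)
  if (length(q_col) != length(t_col)) {
    stop("columns come from different alphabets (lengths ",
         length(q_col), " vs ", length(t_col), ")")
  }
  if (metric == "pearson") {
    if (stats::sd(q_col) == 0 || stats::sd(t_col) == 0) return(0)
    stats::cor(q_col, t_col)
  } else {
    -sqrt(sum((q_col - t_col)^2))
  }
}

# standardized rows for fast pearson: z = (x - mean) / sd, zero if constant;
# pearson(q, t) = z_q . z_t / (K - 1)
std_rows <- function(P) {
  mu <- rowMeans(P)
  ctr <- P - mu
  sd <- sqrt(rowSums(ctr^2) / (ncol(P) - 1))
  sd[sd == 0] <- Inf
  ctr / sd
}

# column-similarity matrix between all query and target positions
similarity_matrix <- function(Q, T_, metric) {
  if (metric == "pearson") {
    std_rows(Q) %*% t(std_rows(T_)) / (ncol(Q) - 1)
  } else {
    cross <- Q %*% t(T_)
    d2 <- outer(rowSums(Q^2), rowSums(T_^2), "+") - 2 * cross
    -sqrt(pmax(d2, 0))
  }
}

# per-query-column null value of the metric for non-overlapping columns
null_values <- function(Q, metric, bg) {
  if (metric == "pearson") rep(0, nrow(Q))
  else -sqrt(rowSums((Q - matrix(bg, nrow(Q), ncol(Q), byrow = TRUE))^2))
}

# scores of every admissible shift of the query along the target:
# shift s aligns query column i with target column i + s
alignment_offsets <- function(wq, wt, min_overlap) {
  s <- (min_overlap - wq):(wt - min_overlap)
  i_min <- pmax(1L, 1L - s)
  i_max <- pmin(wq, wt - s)
  data.frame(shift = s, i_min = i_min, i_max = i_max,
             overlap = i_max - i_min + 1L)
}

alignment_scores <- function(S, min_overlap, nv) {
  wq <- nrow(S); wt <- ncol(S)
  off <- alignment_offsets(wq, wt, min_overlap)
  total_nv <- sum(nv)
  sc <- vapply(seq_len(nrow(off)), function(k) {
    i <- off$i_min[k]:off$i_max[k]
    j <- i + off$shift[k]
    sum(S[cbind(i, j)]) + total_nv - sum(nv[i])
  }, numeric(1))
  off$score <- sc
  off
}

#' Optimal ungapped alignment of two motifs
#'
#' Exhaustive search over all shifts with at least `min_overlap` overlapping
#' columns, in both orientations for nucleotide motifs. The score is the sum
#' of column similarities over the overlap; non-overlapping query columns
#' contribute the metric's null value (0 for `pearson`, the negated distance
#' to the background column for `neg_euclid`), so one-column overlaps cannot
#' win trivially. Ties are broken toward larger overlap, then smaller
#' absolute offset, then the forward orientation.
#'
#' @param query,target `Motif` objects over the same alphabet.
#' @param metric `"pearson"` (default) or `"neg_euclid"`.
#' @param min_overlap Minimum overlapping columns (default 4, floored at the
#'   smaller motif width).
#' @param try_rc Also try the reverse-complement orientation (nucleotides).
#' @param background `Background` for the `neg_euclid` null value.
#' @return List with `offset` (target position of query column 1, 0-based),
#'   `orientation` (`"forward"` or `"revcomp"`), `overlap`, `score`.
#' @export
best_alignment <- function(query, target, metric = c("pearson", "neg_euclid"),
                           min_overlap = 4L, try_rc = TRUE, background = NULL) {
  metric <- match.arg(metric)
  if (!identical(query$alphabet$name, target$alphabet$name)) {
    stop("query and target motifs use different alphabets")
  }
  if (is.null(background)) background <- uniform_background(query$alphabet)
  min_overlap <- max(1L, min(min_overlap, motif_width(query), motif_width(target)))
  orientations <- c("forward", if (try_rc && is_nucleotide(query$alphabet)) "revcomp")
  cand <- list()
  for (o in orientations) {
    Q <- if (o == "forward") query$probs else revcomp_motif(query)$probs
    S <- similarity_matrix(Q, target$probs, metric)
    nv <- null_values(Q, metric, background$frequencies)
    sc <- alignment_scores(S, min_overlap, nv)
    sc$orientation <- o
    cand[[o]] <- sc
  }
  all_sc <- do.call(rbind, cand)
  ord <- order(-round(all_sc$score, 9), -all_sc$overlap, abs(all_sc$shift),
               all_sc$orientation != "forward")
  b <- all_sc[ord[1], ]
  list(offset = b$shift, orientation = b$orientation,
       overlap = b$overlap, score = b$score)
}

#' Compare a query motif against a motif database
#'
#' Each target gets its best ungapped alignment with the query plus a
#' Monte-Carlo p-value: the observed best score is referred to the best
#' scores obtained against `n_shuffles` column-shuffled versions of the
#' target (each column's entries permuted independently),
#' `p = (1 + #null >= observed) / (n_shuffles + 1)`. E-values multiply the
#' p-value by the database size; results are ranked by p ascending (ties by
#' E-value then target name).
#'
#' @param query A `Motif`.
#' @param targets Target motifs (`MotifFile`, list, or single `Motif`).
#' @param metric `"pearson"` (default) or `"neg_euclid"`.
#' @param min_overlap Minimum overlapping columns.
#' @param n_shuffles Column-shuffled replicates per target.
#' @param seed Integer seed for the shuffles.
#' @param background `Background` for the `neg_euclid` null value.
#' @return A data.frame with columns `query_id`, `target_id`, `offset`,
#'   `orientation`, `overlap`, `score`, `p_value`, `e_value`.
#' @export
compare_to_database <- function(query, targets, metric = c("pearson", "neg_euclid"),
                                min_overlap = 4L, n_shuffles = 1000L,
                                seed = 1L, background = NULL) {
  metric <- match.arg(metric)
  targets <- as_motif_list(targets)
  if (!length(targets)) stop("empty target database")
  if (is.null(background)) background <- uniform_background(query$alphabet)
  N <- length(targets)
  rows <- withr::with_seed(seed, lapply(targets, function(tg) {
    obs <- best_alignment(query, tg, metric = metric, min_overlap = min_overlap,
                          background = background)
    null_best <- null_alignment_scores(query, tg, metric, min_overlap,
                                       n_shuffles, background)
    p <- (1 + sum(null_best >= obs$score - 1e-12)) / (n_shuffles + 1)
    data.frame(query_id = query$name, target_id = tg$name,
               offset = obs$offset, orientation = obs$orientation,
               overlap = obs$overlap, score = obs$score,
               p_value = p, e_value = min(p * N, N),
               stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$e_value, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# best alignment scores of the query against column-shuffled targets,
# vectorized over all shuffles
null_alignment_scores <- function(query, target, metric, min_overlap,
                                  n_shuffles, background) {
  Tm <- target$probs
  wt <- nrow(Tm); K <- ncol(Tm)
  min_overlap <- max(1L, min(min_overlap, motif_width(query), wt))
  # stack n_shuffles column-permuted copies of the target
  nrow_big <- n_shuffles * wt
  ranks <- random_perm_rows(nrow_big, K)
  src_row <- rep(seq_len(wt), n_shuffles)
  Tbig <- matrix(Tm[cbind(rep(src_row, K), as.vector(ranks))], nrow = nrow_big)
  orientations <- list(fwd = query$probs)
  if (is_nucleotide(query$alphabet)) orientations$rc <- revcomp_motif(query)$probs
  best <- rep(-Inf, n_shuffles)
  for (Q in orientations) {
    S <- similarity_matrix(Q, Tbig, metric)   # wq x (n_shuffles * wt)
    nv <- null_values(Q, metric, background$frequencies)
    off <- alignment_offsets(nrow(Q), wt, min_overlap)
    total_nv <- sum(nv)
    # per-offset scores for every shuffle block at once
    sc_mat <- matrix(-Inf, nrow(off), n_shuffles)
    wq <- nrow(Q)
    for (k in seq_len(nrow(off))) {
      i <- off$i_min[k]:off$i_max[k]
      j <- i + off$shift[k]
      # linear indices into S for shuffle b: column offset (b-1)*wt
      base <- (j - 1L) * wq + i
      idx <- outer(base, (seq_len(n_shuffles) - 1L) * wt * wq, "+")
      sc_mat[k, ] <- colSums(matrix(S[idx], nrow = length(i))) +
        total_nv - sum(nv[i])
    }
    mx <- sc_mat[1, ]
    for (k in seq_len(nrow(off))[-1]) mx <- pmax(mx, sc_mat[k, ])
    best <- pmax(best, mx)
  }
  best
}

# n random permutations of 1..K, one per row (table lookup for small K)
random_perm_rows <- function(n, K) {
  if (K <= 6) {
    tab <- all_perms(K)
    tab[sample.int(nrow(tab), n, replace = TRUE), , drop = FALSE]
  } else {
    t(vapply(seq_len(n), function(i) sample.int(K), integer(K)))
  }
}

all_perms <- function(K) {
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(K - 1L)
  out <- matrix(0L, nrow(sub) * K, K)
  r <- 0L
  for (pos in seq_len(K)) {
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], K, after = pos - 1L)
    }
  }
  out
}
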