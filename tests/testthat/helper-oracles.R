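# Independent brute-force oracles used across the suite. Each one is a
# direct transcription of the definition, kept free of any package code
# paths.

# rank-mean quantile normalization: sort every column, average across
# columns rank-wise, hand tied entries the mean of their positions' means
oracle_quantile_normalize <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    vals <- numeric(nrow(x))
    i <- 1
    while (i <= nrow(x)) {
      run <- i
      while (run < nrow(x) && x[o[run + 1], j] == x[o[i], j]) run <- run + 1
      vals[o[i:run]] <- mean(ref[i:run])
      i <- run + 1
    }
    out[, j] <- vals
  }
  out
}

# per-cell silhouette width (b - a) / max(a, b) from a distance matrix
oracle_silhouette <- function(cl, dmat) {
  n <- length(cl)
  vapply(seq_len(n), function(i) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (length(own) == 0) return(0)
    a <- mean(dmat[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(k)
      mean(dmat[i, cl == k]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# right-tail Fisher p by exhaustive enumeration of the hypergeometric
# support: P(X >= a) when drawing n_spot from a universe of N with K set
# genes
oracle_fisher_p <- function(a, K, N, n_spot) {
  ks <- max(0, n_spot - (N - K)):min(K, n_spot)
  probs <- choose(K, ks) * choose(N - K, n_spot - ks) / choose(N, n_spot)
  sum(probs[ks >= a])
}

# naive double-loop chromosome-ordered window averaging (sliding)
oracle_cnv <- function(values, ann, window, clip) {
  x <- log2(values[ann$gene_id, , drop = FALSE] + 1)
  x <- x - rowMeans(x)
  x <- pmin(pmax(x, -clip), clip)
  out <- NULL
  for (chr in unique(ann$chromosome)) {
    genes <- ann$gene_id[ann$chromosome == chr]
    if (length(genes) < window) next
    for (s in 1:(length(genes) - window + 1)) {
      win <- genes[s:(s + window - 1)]
      out <- cbind(out, colMeans(x[win, , drop = FALSE]))
    }
  }
  out - apply(out, 1, stats::median)
}

# 8-connected components by naive repeated scanning
oracle_components8 <- function(fg) {
  lab <- matrix(0L, nrow(fg), ncol(fg))
  nxt <- 0L
  for (i in seq_len(nrow(fg))) for (j in seq_len(ncol(fg))) {
    if (fg[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      lab[i, j] <- nxt
      repeat {
        changed <- FALSE
        for (a in seq_len(nrow(fg))) for (b in seq_len(ncol(fg))) {
          if (!fg[a, b] || lab[a, b] != 0L) next
          nb <- lab[max(1, a - 1):min(nrow(fg), a + 1),
                    max(1, b - 1):min(ncol(fg), b + 1)]
          if (any(nb == nxt)) { lab[a, b] <- nxt; changed <- TRUE }
        }
        if (!changed) break
      }
    }
  }
  lab
}

# adjusted Rand index (used instead of mclust when unavailable)
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  (sij - si * sj / n2) / ((si + sj) / 2 - si * sj / n2)
}
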