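# Independent oracles used by the test suite. These deliberately avoid the
# code paths they check: the UPGMA oracle is a direct implementation of the
# agglomeration recurrence, and the hypergeometric oracle sums binomial
# coefficients.

# Brute-force UPGMA on a distance matrix. Returns the cophenetic distance
# matrix and the sorted merge heights.
upgma_oracle <- function(D) {
  n <- nrow(D)
  labels <- rownames(D) %or% as.character(seq_len(n))
  members <- lapply(seq_len(n), identity)
  cd <- D
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  while (length(members) > 1L) {
    k <- length(members)
    bv <- Inf
    bi <- bj <- NA_integer_
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        if (cd[i, j] < bv) {
          bv <- cd[i, j]
          bi <- i
          bj <- j
        }
      }
    }
    for (a in members[[bi]]) for (b in members[[bj]]) {
      coph[a, b] <- coph[b, a] <- bv
    }
    heights <- c(heights, bv)
    ni <- length(members[[bi]])
    nj <- length(members[[bj]])
    newd <- (ni * cd[bi, ] + nj * cd[bj, ]) / (ni + nj)
    keep <- setdiff(seq_len(k), c(bi, bj))
    cd <- rbind(cbind(cd[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    members <- c(members[keep], list(c(members[[bi]], members[[bj]])))
  }
  dimnames(coph) <- list(labels, labels)
  list(cophenetic = coph, heights = sort(heights))
}

`%or%` <- function(x, y) if (is.null(x)) y else x

# Upper-tail hypergeometric probability P(X >= k) by direct summation of
# binomial-coefficient mass; independent of phyper.
hyper_tail_oracle <- function(k, K, N, n) {
  top <- min(n, K)
  if (k > top) return(0)
  js <- max(k, max(0L, n + K - N)):top
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# Small fully observed log2 intensity matrix for unit tests.
toy_matrix <- function(values, proteins = NULL, samples = NULL,
                       scale = "log2") {
  m <- as.matrix(values)
  rownames(m) <- proteins %or% sprintf("P%d", seq_len(nrow(m)))
  colnames(m) <- samples %or% sprintf("s%d", seq_len(ncol(m)))
  intensity_matrix(m, scale = scale)
}

# Minimal design for a toy matrix: first `n_a` samples labeled, rest control.
toy_design <- function(mat, n_a) {
  ids <- colnames(im_values(mat))
  sample_design(ids,
                genotype = rep(c("labeled", "control"),
                               c(n_a, length(ids) - n_a)),
                region = "whole", mouse_id = ids)
}
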