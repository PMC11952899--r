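# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (naive scans, exhaustive enumeration,
# power iteration) and share no code with the package internals.

O_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
O_KD <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
          I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
          R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

o_random_seq <- function(L) paste(sample(O_AA, L, replace = TRUE), collapse = "")

# overlapping occurrences of one k-mer by explicit position-wise scan
o_kmer_count <- function(seq, kmer) {
  k <- nchar(kmer); L <- nchar(seq)
  if (L < k) return(0L)
  hits <- 0L
  for (i in 1:(L - k + 1)) if (substr(seq, i, i + k - 1) == kmer) hits <- hits + 1L
  hits
}

o_gravy <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  mean(O_KD[chars])
}

o_aacomp <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  sapply(O_AA, function(a) sum(chars == a)) / nchar(seq)
}

# per-window entropy scan, residue coverage by explicit marking
o_lcr <- function(seq, w = 12, thr = 2.2) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  ent <- function(x) {
    p <- table(x) / length(x)
    -sum(p * log2(p))
  }
  if (L <= w) return(if (ent(chars) < thr) 1 else 0)
  covered <- rep(FALSE, L)
  for (i in 1:(L - w + 1)) {
    if (ent(chars[i:(i + w - 1)]) < thr) covered[i:(i + w - 1)] <- TRUE
  }
  mean(covered)
}

# AUC as pairwise concordance with ties counted 1/2
o_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# ---- graph oracles (adjacency-matrix based) -------------------------------

o_rand_adj <- function(n, p) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- as.integer(runif(n * (n - 1) / 2) < p)
  A + t(A)
}

o_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (s in 1:n) {
    frontier <- s; d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] == 1))))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# number of shortest paths between every pair
o_nsp <- function(A, D) {
  n <- nrow(A)
  S <- matrix(0, n, n); diag(S) <- 1
  for (s in 1:n) {
    reach <- which(is.finite(D[s, ]))
    for (t in reach[order(D[s, reach])]) {
      if (t == s) next
      preds <- which(A[t, ] == 1 & D[s, ] == D[s, t] - 1)
      S[s, t] <- sum(S[s, preds])
    }
  }
  S
}

o_betweenness <- function(A) {
  n <- nrow(A)
  D <- o_distances(A); S <- o_nsp(A, D)
  bt <- numeric(n)
  for (v in 1:n) {
    acc <- 0
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        acc <- acc + S[s, v] * S[v, t] / S[s, t]
    }
    bt[v] <- acc
  }
  bt / ((n - 1) * (n - 2) / 2)
}

o_components <- function(A) {
  n <- nrow(A)
  D <- o_distances(A)
  mem <- integer(n); cl <- 0
  for (v in 1:n) {
    if (mem[v] == 0) {
      cl <- cl + 1
      mem[is.finite(D[v, ])] <- cl
    }
  }
  mem
}

o_eigen <- function(A) {
  n <- nrow(A)
  mem <- o_components(A)
  out <- numeric(n)
  for (cl in unique(mem)) {
    idx <- which(mem == cl)
    B <- A[idx, idx, drop = FALSE]
    if (sum(B) == 0) next
    # shift by I so power iteration cannot oscillate on bipartite components
    Bs <- B + diag(length(idx))
    v <- rep(1, length(idx))
    for (i in 1:10000) {
      v2 <- as.numeric(Bs %*% v)
      v2 <- v2 / sqrt(sum(v2^2))
      if (max(abs(v2 - v)) < 1e-12) { v <- v2; break }
      v <- v2
    }
    out[idx] <- v / max(v)
  }
  out
}

o_pagerank <- function(A, d = 0.85) {
  n <- nrow(A)
  deg <- rowSums(A)
  M <- matrix(0, n, n)
  for (j in 1:n) {
    if (deg[j] == 0) M[, j] <- 1 / n else M[, j] <- A[, j] / deg[j]
  }
  v <- rep(1 / n, n)
  for (i in 1:20000) {
    v2 <- d * as.numeric(M %*% v) + (1 - d) / n
    if (max(abs(v2 - v)) < 1e-13) return(v2)
    v <- v2
  }
  v
}

o_closeness_wf <- function(A) {
  n <- nrow(A)
  D <- o_distances(A)
  sapply(1:n, function(v) {
    reach <- is.finite(D[v, ]) & seq_len(n) != v
    r <- sum(reach) + 1
    if (r == 1) return(0)
    ((r - 1) / (n - 1)) * ((r - 1) / sum(D[v, reach]))
  })
}

o_clustering <- function(A) {
  n <- nrow(A)
  sapply(1:n, function(v) {
    nb <- which(A[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / 2 / choose(k, 2)
  })
}

adj_to_graph <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(nrow(A))))
}

# compare all seven package centralities against the oracles on one graph
expect_centralities_match <- function(A, tol = 1e-6) {
  cen <- compute_centralities(adj_to_graph(A))
  expect_equal(cen$degree, as.numeric(rowSums(A)), tolerance = tol)
  expect_equal(cen$betweenness, o_betweenness(A), tolerance = 1e-8)
  expect_equal(cen$eigenvector, o_eigen(A), tolerance = 1e-5)
  expect_equal(cen$pagerank, o_pagerank(A), tolerance = 1e-8)
  expect_equal(cen$closeness, o_closeness_wf(A), tolerance = 1e-8)
  expect_equal(cen$clustering_coefficient, o_clustering(A), tolerance = 1e-10)
  expect_equal(cen$degree_centrality, as.numeric(rowSums(A)) / (nrow(A) - 1),
               tolerance = tol)
}
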