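# Independent brute-force oracles. These re-derive every quantity from
# first principles (scalar arithmetic, exhaustive enumeration, adjacency
# powers) and share no code with the package internals.

# scalar pair-force evaluation, written out branch by branch
oracle_pair_force <- function(x, d_l = 0, d_e = 5.2, d_h = 12,
                              k1 = 1, k2 = 0.3, k3 = 0.3) {
  mid <- (d_e + d_h) / 2
  if (x > d_l && x < d_e) return(k1 * (1 / x - 1 / d_e))
  if (x > d_e && x <= mid) return(k2 * sin((x - d_e) * pi / (d_h - d_e)))
  if (x > mid) return(k3)
  0
}

# one-dimensional two-body iteration: both agents on a line, each pulled or
# pushed by the other, so the gap changes by twice the per-agent move
oracle_two_body <- function(x0, steps, d_l = 0, d_e = 5.2, d_h = 12,
                            k1 = 1, k2 = 0.3, k3 = 0.3,
                            a = 0.08, b = 0.2, c = 1) {
  x <- x0
  mid <- (d_e + d_h) / 2
  for (t in seq_len(steps)) {
    attract <- 0
    repulse <- 0
    if (x > d_l && x < d_e) repulse <- k1 * (1 / x - 1 / d_e)
    if (x > d_e && x <= mid) attract <- k2 * sin((x - d_e) * pi / (d_h - d_e))
    if (x > mid) attract <- k3
    x <- x - 2 * c * (a * attract - b * repulse)
  }
  x
}

# exhaustive k-nearest neighbors: all candidates ranked by (distance, index)
oracle_knn <- function(m, i, k) {
  d <- sqrt(colSums((t(m) - m[i, ])^2))
  cand <- setdiff(seq_len(nrow(m)), i)
  ord <- cand[order(d[cand], cand)]
  ord[seq_len(k)]
}

# directed adjacency matrix of the k-nearest-neighbor graph (edge j -> i),
# built from the exhaustive oracle
oracle_knn_adjacency <- function(m, k) {
  n <- nrow(m)
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in oracle_knn(m, i, k)) A[j, i] <- 1L
  }
  A
}

# all-pairs directed shortest-path lengths by repeated boolean adjacency
# powers
oracle_geodesics <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n) > 0
  P <- diag(n)
  for (len in seq_len(n - 1)) {
    P <- (P %*% A) > 0
    newly <- P & !reach
    D[newly] <- len
    reach <- reach | P
  }
  D
}

# mean local clustering coefficient by explicit triangle counting on the
# undirected projection
oracle_clustering <- function(A) {
  U <- ((A + t(A)) > 0) * 1L
  diag(U) <- 0L
  n <- nrow(U)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(U[i, ] > 0)
    if (length(nb) < 2) return(0)
    sum(U[nb, nb]) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  mean(vals)
}

# Shannon entropy (nats) of a degree histogram
oracle_entropy <- function(degrees) {
  p <- as.numeric(table(degrees)) / length(degrees)
  -sum(p * log(p))
}

# random rigid rotation matrix (det +1) in d dimensions
random_rotation <- function(d) {
  qr_ <- qr(matrix(stats::rnorm(d * d), d, d))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
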