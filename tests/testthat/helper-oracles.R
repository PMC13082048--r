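# Independent oracles used to cross-check the package implementations.

# Horn's closed-form quaternion solution for the optimal rotation; an
# independent route to the least-squares superposition solved by SVD in the
# package.
horn_superpose <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  S <- crossprod(A, B)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  t <- ct - as.numeric(R %*% cm)
  fitted <- sweep(tcrossprod(mobile, R), 2, t, "+")
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums((fitted - target)^2))))
}

# plain-R affine-gap local alignment DP (Gotoh), same gap convention as the
# package (first gap position scores `open`, later positions `extend`);
# scores only, coded independently of the C++ implementation
r_local_align_score <- function(query, ref, match = 2, mismatch = -1,
                                open = -5, extend = -0.5) {
  q <- strsplit(query, "")[[1]]; r <- strsplit(ref, "")[[1]]
  n <- length(q); m <- length(r)
  NEG <- -1e18
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)   # gap in query (consumes ref)
  F <- matrix(NEG, n + 1, m + 1)   # gap in ref (consumes query)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    E[i + 1, j + 1] <- max(H[i + 1, j] + open, E[i + 1, j] + extend)
    F[i + 1, j + 1] <- max(H[i, j + 1] + open, F[i, j + 1] + extend)
    s <- if (q[i] == r[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
    if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
  }
  best
}

# textbook Welch t statistic and Satterthwaite df
welch_hand <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Benjamini-Hochberg step-up by hand
bh_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n); out[o] <- pmin(1, adj)
  out
}

sphere_volume <- function(r) 4 / 3 * pi * r^3

# union of two equal spheres radius r at center distance d (d <= 2r)
two_sphere_union <- function(r, d) {
  lens <- pi * (4 * r + d) * (2 * r - d)^2 / 12
  2 * sphere_volume(r) - lens
}

rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}
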