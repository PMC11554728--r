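# Independent oracles and small generators shared across the suite.

# RMSD between two point sets after optimal rigid alignment (Kabsch).
kabsch_rmsd <- function(A, B) {
  A1 <- sweep(A, 2, colMeans(A))
  B1 <- sweep(B, 2, colMeans(B))
  s <- svd(t(A1) %*% B1)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((A1 %*% R - B1)^2)))
}

# Brute-force O(ne^2) broad phase: all non-adjacent edge pairs with centers
# within sqrt((lbar/2)^2 + D2^2).
oracle_candidate_pairs <- function(X, rest_len, D2) {
  ne <- nrow(X) - 1L
  ctr <- (X[-1, , drop = FALSE] + X[-nrow(X), , drop = FALSE]) / 2
  bound2 <- (rest_len / 2)^2 + D2^2
  out <- NULL
  for (i in seq_len(ne)) {
    js <- setdiff(seq_len(ne), (i - 1L):(i + 1L))
    js <- js[js > i]
    if (!length(js)) next
    d2 <- rowSums((ctr[js, , drop = FALSE] -
                     matrix(ctr[i, ], length(js), 3, byrow = TRUE))^2)
    hit <- js[d2 <= bound2]
    if (length(hit)) out <- rbind(out, cbind(i, hit))
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else unname(out)
}

# Exact segment-segment distance for the oracle narrow phase (closed-form,
# written independently of the compiled kernel).
oracle_seg_dist <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2)
  b <- sum(d1 * d2); c <- sum(d1 * r); f <- sum(d2 * r)
  den <- a * e - b * b
  s <- if (den > 1e-14) min(1, max(0, (b * f - c * e) / den)) else 0
  t <- if (e > 1e-14) (b * s + f) / e else 0
  if (t < 0) { t <- 0; s <- min(1, max(0, -c / a)) }
  if (t > 1) { t <- 1; s <- min(1, max(0, (b - c) / a)) }
  sqrt(sum((p1 + s * d1 - p2 - t * d2)^2))
}

# Dense-sampling lower oracle for segment distance (grid x grid point pairs).
sampling_seg_dist <- function(p1, q1, p2, q2, n = 400) {
  ts <- seq(0, 1, length.out = n)
  A <- outer(1 - ts, p1) + outer(ts, q1)
  B <- outer(1 - ts, p2) + outer(ts, q2)
  d2 <- outer(rowSums(A^2), rep(1, n)) + outer(rep(1, n), rowSums(B^2)) -
    2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

# Brute-force detection: the collision rule is the conjunction of the
# center-distance condition (broad phase) and the segment-distance
# condition (narrow phase), evaluated over all non-adjacent pairs.
oracle_detect_coil <- function(X, D2, rest_len) {
  ne <- nrow(X) - 1L
  ctr <- (X[-1, , drop = FALSE] + X[-nrow(X), , drop = FALSE]) / 2
  bound2 <- (rest_len / 2)^2 + D2^2
  out <- NULL
  for (i in seq_len(ne)) for (j in seq_len(ne)) {
    if (j <= i + 1L) next
    if (sum((ctr[i, ] - ctr[j, ])^2) > bound2) next
    d <- oracle_seg_dist(X[i, ], X[i + 1L, ], X[j, ], X[j + 1L, ])
    if (d <= D2) out <- rbind(out, c(i, j, d))
  }
  out
}

# Random open tangle that stays within a compact ball (random walk with
# pullback), for collision-detection tests.
random_tangle <- function(n, step = 0.35, pull = 0.05) {
  X <- matrix(0, n, 3)
  for (i in 2:n) {
    d <- rnorm(3)
    X[i, ] <- X[i - 1, ] * (1 - pull) + step * d / sqrt(sum(d^2))
  }
  X
}

# Smooth random space curve (for Bishop-frame and gradient tests).
random_curve <- function(n, wiggle = 0.15) {
  t <- seq(0, 1, length.out = n)
  a <- rnorm(6, sd = wiggle)
  cbind(t + a[1] * sin(2 * pi * t), a[2] * sin(2 * pi * t) + a[3] * cos(4 * pi * t),
        a[4] * sin(4 * pi * t) + a[5] * cos(2 * pi * t) + a[6] * t)
}

# Cubic bounding box of an aneurysm dome with a small margin.
bounding_cube_of <- function(domain) {
  v <- domain$dome_mesh$vertices
  lo <- apply(v, 2, min) - 0.3
  hi <- apply(v, 2, max) + 0.3
  a <- max(hi - lo)
  list(origin = (lo + hi) / 2 - a / 2, a = a)
}

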