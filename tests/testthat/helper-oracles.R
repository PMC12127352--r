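# Independent oracles used across the suite: deliberately naive loop
# implementations and tiny constructors, kept free of the vectorized code
# paths they check.

# Random labeled feature set: C classes, k samples per class, n dims.
rand_fs <- function(C, k, n, seed, sd = 1, spread = 1) {
  set.seed(seed)
  mu <- matrix(rnorm(C * n), C, n) * spread
  lab <- rep(seq_len(C) - 1L, each = k)
  feature_set(mu[lab + 1L, , drop = FALSE] + matrix(rnorm(C * k * n, sd = sd), C * k, n),
              lab)
}

# Naive double-loop FAS components (dimension scaling, unsquared Dbar).
oracle_fas <- function(fs) {
  m <- feature_matrix(fs)
  lab <- fs$label
  classes <- sort(unique(lab))
  C <- length(classes)
  mu <- matrix(0, C, ncol(m))
  for (i in seq_len(C)) {
    rows <- which(lab == classes[i])
    for (j in seq_len(ncol(m))) mu[i, j] <- mean(m[rows, j])
  }
  g <- colMeans(m)
  wv <- 0
  for (r in seq_len(nrow(m))) {
    i <- match(lab[r], classes)
    wv <- wv + sum((m[r, ] - mu[i, ])^2)
  }
  wv <- wv / nrow(m)
  bv <- 0
  for (i in seq_len(C)) bv <- bv + sum((mu[i, ] - g)^2)
  bv <- bv / C
  db <- 0
  for (i in seq_len(C - 1)) for (j in (i + 1):C) {
    db <- db + sqrt(sum((mu[i, ] - mu[j, ])^2))
  }
  db <- db * 2 / (C * (C - 1))
  list(mu = mu, global = g, within = wv, between = bv, dbar = db,
       fas = bv / max(wv, 1e-12) + db / sqrt(ncol(m)))
}

# Brute-force nearest-prototype labels via scalar distance calls.
oracle_classify <- function(protos, queries, metric = "euclidean") {
  dfun <- if (metric == "euclidean") euclidean_distance else cosine_distance
  apply(queries, 1, function(q) {
    d <- apply(protos, 1, function(p) dfun(q, p))
    which(d == min(d))[1] - 1L
  })
}

# Random orthogonal matrix (QR of a Gaussian matrix).
rand_orthogonal <- function(n, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(n * n), n, n)))
}

# Tiny deterministic two-class 1-D set: class 0 = {-1, 1}, class 1 = {1, 3}.
# Hand arithmetic: means 0 and 2, global 1, within 1, between 1, Dbar 2.
tiny_two_class <- function() {
  feature_set(matrix(c(-1, 1, 1, 3), ncol = 1), c(0L, 0L, 1L, 1L))
}
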