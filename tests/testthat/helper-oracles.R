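# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and vectorised shortcuts) so they can serve as ground
# truth for the fast implementations.

# pairwise Euclidean distances, one pair at a time
oracle_pairwise <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
    }
  }
  D
}

# mean distance over explicitly enumerated same-label pairs
oracle_same_label <- function(D, labels) {
  vals <- c()
  n <- nrow(D)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (labels[i] == labels[j]) vals <- c(vals, D[i, j])
    }
  }
  mean(vals)
}

# exact permutation p-value and null mean by full n! enumeration
oracle_exhaustive_perm <- function(D, labels) {
  n <- nrow(D)
  perms <- e1071::permutations(n)
  obs <- oracle_same_label(D, labels)
  nulls <- apply(perms, 1, function(ord) oracle_same_label(D, labels[ord]))
  list(p = mean(nulls <= obs + 1e-12), expected = mean(nulls),
       observed = obs)
}

# Benjamini-Hochberg step-up applied from the written definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- Inf
  for (k in m:1) {
    running_min <- min(running_min, p[ord[k]] * m / k)
    adj[ord[k]] <- min(running_min, 1)
  }
  adj
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
# (zeros dropped first; assumes no ties among |d|)
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  ev <- n * (n + 1) / 4
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-9)
}

# naive average-linkage agglomeration recording merge heights
oracle_average_linkage_heights <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a < b) {
          h <- mean(D[clusters[[a]], clusters[[b]]])
          if (h < best[1]) best <- c(h, a, b)
        }
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}
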