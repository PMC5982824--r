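# Independent brute-force implementations used as oracles. These are written
# from the definitions (pairwise enumeration, direct formulas) and stay
# deliberately naive: no code is shared with the package internals.

# pi as the average number of differences over all pairs of chromosomes,
# enumerated from the implied allele counts site by site
oracle_pi <- function(g) {
  if (!ncol(g)) return(0)
  tot <- 0
  for (j in seq_len(ncol(g))) {
    x <- g[, j]
    x <- x[!is.na(x)]
    nc <- 2 * length(x)
    if (nc < 2) next
    c1 <- sum(x)
    # enumerate unordered chromosome pairs: diff pairs = c1 * (nc - c1)
    tot <- tot + c1 * (nc - c1) / choose(nc, 2)
  }
  tot
}

oracle_theta_w <- function(g) {
  if (!ncol(g)) return(0)
  tot <- 0
  for (j in seq_len(ncol(g))) {
    x <- g[, j]
    x <- x[!is.na(x)]
    nc <- 2 * length(x)
    c1 <- sum(x)
    if (nc >= 2 && c1 > 0 && c1 < nc) {
      tot <- tot + 1 / sum(1 / seq_len(nc - 1))
    }
  }
  tot
}

# textbook Tajima's D for complete data (single sample size)
oracle_tajd <- function(g) {
  n <- 2 * nrow(g)
  cnt <- colSums(g)
  poly <- cnt > 0 & cnt < n
  s <- sum(poly)
  if (s == 0 || n < 4) return(0)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (oracle_pi(g) - oracle_theta_w(g)) / sqrt(e1 * s + e2 * s * (s - 1))
}

oracle_gkl <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  sum(x[ok] != y[ok])
}

oracle_gkl_values <- function(g) {
  n <- nrow(g)
  out <- c()
  for (k in seq_len(n - 1)) {
    for (l in (k + 1):n) out <- c(out, oracle_gkl(g[k, ], g[l, ]))
  }
  out
}

oracle_moments <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(c(0, 0, 0))
  c(m2, mean((x - m)^3) / m2^1.5, mean((x - m)^4) / m2^2)
}

oracle_diplos <- function(g) {
  keep <- rowSums(is.na(g)) == 0
  g <- g[keep, , drop = FALSE]
  keys <- apply(g, 1, paste, collapse = ",")
  p <- sort(table(keys) / nrow(g), decreasing = TRUE)
  p <- as.numeric(p)
  j1 <- sum(p^2)
  j12 <- if (length(p) >= 2) (p[1] + p[2])^2 + sum(p[-(1:2)]^2) else j1
  list(n = length(p), J1 = j1, J12 = j12, J2J1 = (j1 - p[1]^2) / j1)
}

oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  (sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
}

oracle_poly_cols <- function(g) {
  which(vapply(seq_len(ncol(g)), function(j) {
    x <- g[, j][!is.na(g[, j])]
    length(x) >= 1 && sum(x) > 0 && sum(x) < 2 * length(x)
  }, logical(1)))
}

oracle_zns <- function(g) {
  poly <- oracle_poly_cols(g)
  if (length(poly) < 2) return(0)
  vals <- c()
  for (a in seq_along(poly)[-length(poly)]) {
    for (b in (a + 1):length(poly)) {
      vals <- c(vals, oracle_r2(g[, poly[a]], g[, poly[b]]))
    }
  }
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(0)
  mean(vals)
}

# omega-max by direct enumeration of every split
oracle_omega <- function(g) {
  poly <- oracle_poly_cols(g)
  s <- length(poly)
  if (s < 6) return(0)
  r2 <- matrix(NA_real_, s, s)
  for (a in seq_len(s - 1)) {
    for (b in (a + 1):s) {
      r2[a, b] <- r2[b, a] <- oracle_r2(g[, poly[a]], g[, poly[b]])
    }
  }
  best <- 0
  for (l in 3:(s - 3)) {
    wl <- c(); wr <- c(); bw <- c()
    for (a in seq_len(s - 1)) {
      for (b in (a + 1):s) {
        v <- r2[a, b]
        if (is.na(v)) next
        if (b <= l) wl <- c(wl, v) else if (a > l) wr <- c(wr, v) else bw <- c(bw, v)
      }
    }
    if (!length(bw) || sum(bw) == 0) next
    om <- (sum(c(wl, wr)) / (length(wl) + length(wr))) / (sum(bw) / length(bw))
    if (is.finite(om) && om > best) best <- om
  }
  best
}

# AUC by direct enumeration of positive/negative pairs
oracle_auc <- function(score, pos) {
  ps <- score[pos]
  ns <- score[!pos]
  tot <- 0
  for (a in ps) for (b in ns) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ps) * length(ns))
}

random_geno <- function(n, m, p_na = 0) {
  g <- matrix(sample(0:2, n * m, replace = TRUE, prob = c(0.5, 0.3, 0.2)), n, m)
  if (p_na > 0) g[stats::runif(n * m) < p_na] <- NA
  g
}

random_replicate <- function(n_chrom = 8, m = 12) {
  h <- matrix(stats::rbinom(n_chrom * m, 1, stats::runif(1, 0.2, 0.6)), n_chrom, m)
  haplo_replicate(h, sort(stats::runif(m)))
}
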