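#' @importFrom stats cor sd
NULL

geno_entries <- function(geno) {
  if (inherits(geno, "genotype_matrix")) geno$genotypes else {
    g <- as.matrix(geno)
    storage.mode(g) <- "integer"
    g
  }
}

#' Per-site allele counts
#'
#' @param geno a [genotype_matrix()] or plain 0/1/2/NA matrix.
#' @return Tibble with one row per site: `alt` (alternate-allele count) and
#'   `called` (number of successfully genotyped chromosomes, i.e. twice the
#'   non-missing individuals).
#' @export
site_frequencies <- function(geno) {
  g <- geno_entries(geno)
  tibble::tibble(
    alt = as.integer(colSums(g, na.rm = TRUE)),
    called = 2L * as.integer(colSums(!is.na(g)))
  )
}

#' Nucleotide diversity from genotype-derived allele counts
#'
#' Average number of pairwise differences among sampled chromosomes, summed
#' over sites: `sum 2 c (Nc - c) / (Nc (Nc - 1))` with `c` the alternate
#' count and `Nc` the called chromosomes at that site.
#'
#' @inheritParams site_frequencies
#' @return Nonnegative scalar; 0 for an empty window.
#' @export
theta_pi <- function(geno) {
  sf <- site_frequencies(geno)
  sf <- sf[sf$called >= 2L, ]
  if (!nrow(sf)) return(0)
  sum(2 * sf$alt * (sf$called - sf$alt) / (sf$called * (sf$called - 1)))
}

harmonic <- function(k) if (k < 1) 0 else sum(1 / seq_len(k))

#' Watterson's theta
#'
#' Number of segregating sites scaled by the harmonic number `a1` of the
#' sample size. With missing data every polymorphic site contributes
#' `1 / a1(Nc - 1)` using its own called-chromosome count.
#'
#' @inheritParams site_frequencies
#' @return Nonnegative scalar; 0 when there are no polymorphic sites.
#' @export
theta_w <- function(geno) {
  sf <- site_frequencies(geno)
  if (!nrow(sf)) return(0)
  if (all(sf$called < 2L)) stop("need at least 2 called chromosomes")
  sf <- sf[sf$called >= 2L & sf$alt > 0L & sf$alt < sf$called, ]
  if (!nrow(sf)) return(0)
  sum(vapply(sf$called, function(nc) 1 / harmonic(nc - 1L), numeric(1)))
}

#' Tajima's D
#'
#' Standardized difference between pairwise diversity and Watterson's theta,
#' with the usual `e1`, `e2` variance constants. Returns 0 when undefined
#' (no polymorphism, or fewer than 4 called chromosomes) so that the spatial
#' normalization downstream always sees finite values; a flat signal is the
#' appropriate null there.
#'
#' @inheritParams site_frequencies
#' @return Scalar.
#' @export
tajimas_d <- function(geno) {
  sf <- site_frequencies(geno)
  sf <- sf[sf$called >= 2L, ]
  poly <- sf$alt > 0L & sf$alt < sf$called
  s <- sum(poly)
  if (s == 0L) return(0)
  n <- round(mean(sf$called[poly]))
  if (n < 4) return(0)
  a1 <- harmonic(n - 1L)
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * s + e2 * s * (s - 1)
  if (v <= 0) return(0)
  (theta_pi(geno) - theta_w(geno)) / sqrt(v)
}

#' Pairwise genotype distances
#'
#' The genotype (Hamming) distance between individuals `k` and `l` counts the
#' sites at which their unphased genotypes differ. Sites missing in either
#' member of a pair are skipped for that pair.
#'
#' @inheritParams site_frequencies
#' @return Object of class `gkl_dist`: list with `values` (the n(n-1)/2
#'   unordered pair distances) and `matrix` (the full symmetric matrix).
#' @export
genotype_distances <- function(geno) {
  g <- geno_entries(geno)
  n <- nrow(g)
  if (n < 2) stop("need at least 2 individuals for genotype distances")
  obs <- !is.na(g)
  gm <- matrix(0, n, n)
  for (v in 0:2) {
    a <- (g == v) & obs
    storage.mode(a) <- "double"
    gm <- gm + tcrossprod(a)
  }
  comp <- tcrossprod(matrix(as.double(obs), n))
  d <- comp - gm
  structure(list(values = d[lower.tri(d)], matrix = d), class = "gkl_dist")
}

#' Central moments of the genotype-distance distribution
#'
#' Population (n-denominator) variance, skewness (`m3 / m2^(3/2)`) and
#' non-excess kurtosis (`m4 / m2^2`). A constant distribution returns
#' (0, 0, 0) by convention.
#'
#' @param dist a `gkl_dist` from [genotype_distances()], or a numeric vector
#'   of pairwise distances.
#' @return Named numeric vector `c(variance, skewness, kurtosis)`.
#' @export
gkl_moments <- function(dist) {
  x <- if (inherits(dist, "gkl_dist")) dist$values else as.numeric(dist)
  if (!length(x)) stop("empty distance distribution")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(c(variance = 0, skewness = 0, kurtosis = 0))
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  c(variance = m2, skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

#' Multilocus genotype ("diplotype") frequency spectrum
#'
#' Groups identical multilocus genotype vectors and computes the diplotype
#' analogs of the haplotype homozygosity statistics: `J1 = sum p_i^2`,
#' `J12 = (p1 + p2)^2 + sum_{i>=3} p_i^2` and `J2/J1 = (J1 - p1^2) / J1`,
#' with frequencies sorted in decreasing order. Individuals with any missing
#' genotype in the window are excluded.
#'
#' @inheritParams site_frequencies
#' @return List with `frequencies` (sorted), `n_diplos`, `J1`, `J12`, `J2J1`.
#' @export
diplotype_spectrum <- function(geno) {
  g <- geno_entries(geno)
  if (nrow(g) == 0) stop("need at least 1 individual")
  keep <- rowSums(is.na(g)) == 0L
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0) {
    return(list(frequencies = numeric(0), n_diplos = 0L, J1 = 0, J12 = 0, J2J1 = 0))
  }
  key <- apply(g, 1, paste, collapse = "")
  p <- sort(as.numeric(table(key)) / nrow(g), decreasing = TRUE)
  j1 <- sum(p^2)
  j12 <- if (length(p) >= 2) (p[1] + p[2])^2 + sum(p[-(1:2)]^2) else j1
  j2j1 <- (j1 - p[1]^2) / j1
  list(frequencies = p, n_diplos = length(p), J1 = j1, J12 = j12, J2J1 = j2j1)
}

#' Genotypic linkage disequilibrium between two sites
#'
#' Squared Pearson correlation of the two unphased genotype columns across
#' individuals complete at both sites (the Rogers-Huff genotypic r^2).
#'
#' @inheritParams site_frequencies
#' @param site_i,site_j column indices.
#' @return r^2 in \[0, 1\], or `NA` if either column is monomorphic after the
#'   missing-data restriction (such pairs are skipped by the aggregate
#'   statistics, not zero-filled).
#' @export
genotypic_r2 <- function(geno, site_i, site_j) {
  g <- geno_entries(geno)
  x <- g[, site_i]
  y <- g[, site_j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]
  y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

polymorphic_cols <- function(g) {
  alt <- colSums(g, na.rm = TRUE)
  called <- 2L * colSums(!is.na(g))
  which(called >= 2L & alt > 0L & alt < called)
}

r2_matrix <- function(g) {
  suppressWarnings(cor(g, use = "pairwise.complete.obs")^2)
}

#' Kelly's ZnS from genotypic LD
#'
#' Mean genotypic r^2 over all retained pairs of polymorphic sites in the
#' window.
#'
#' @inheritParams site_frequencies
#' @return Value in \[0, 1\]; 0 when fewer than 2 usable sites.
#' @export
zns <- function(geno) {
  g <- geno_entries(geno)
  poly <- polymorphic_cols(g)
  if (length(poly) < 2) return(0)
  r2 <- r2_matrix(g[, poly, drop = FALSE])
  vals <- r2[upper.tri(r2)]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(0)
  mean(vals)
}

#' Maximum of the omega statistic from genotypic LD
#'
#' Contrasts LD within the left and right blocks of a candidate split against
#' LD between blocks, maximized over split positions `l` in `[3, S - 3]`
#' (sites in position order). Splits whose between-block r^2 sum is zero are
#' skipped; if no valid split remains, or fewer than `s_min` polymorphic
#' sites are available, the statistic is 0.
#'
#' @inheritParams site_frequencies
#' @param s_min minimum number of polymorphic sites (default 6).
#' @return Nonnegative scalar.
#' @export
omega_max <- function(geno, s_min = 6L) {
  g <- geno_entries(geno)
  poly <- polymorphic_cols(g)
  s <- length(poly)
  if (s < s_min || s < 6L) return(0)
  omega_from_r2(r2_matrix(g[, poly, drop = FALSE]))
}

## fast path used by compute_profile: one pass over a plain matrix, sharing
## the allele counts and the r^2 matrix across statistics
window_stats_fast <- function(g) {
  n <- nrow(g)
  m <- ncol(g)
  out <- numeric(12)
  names(out) <- stat_names()
  has_na <- anyNA(g)
  obs <- if (has_na) !is.na(g) else NULL
  alt <- if (has_na) colSums(g, na.rm = TRUE) else colSums(g)
  called <- if (has_na) 2L * colSums(obs) else rep(2L * n, m)
  ok <- called >= 2L
  if (any(ok)) {
    a <- alt[ok]; nc <- called[ok]
    out["pi"] <- sum(2 * a * (nc - a) / (nc * (nc - 1)))
    poly <- a > 0L & a < nc
    s <- sum(poly)
    if (s > 0) {
      h <- vapply(nc[poly], function(k) 1 / harmonic(k - 1L), numeric(1))
      out["thetaW"] <- sum(h)
      nbar <- round(mean(nc[poly]))
      if (nbar >= 4) {
        a1 <- harmonic(nbar - 1L)
        a2 <- sum(1 / seq_len(nbar - 1L)^2)
        b1 <- (nbar + 1) / (3 * (nbar - 1))
        b2 <- 2 * (nbar^2 + nbar + 3) / (9 * nbar * (nbar - 1))
        c1 <- b1 - 1 / a1
        c2 <- b2 - (nbar + 2) / (a1 * nbar) + a2 / a1^2
        v <- (c1 / a1) * s + (c2 / (a1^2 + a2)) * s * (s - 1)
        if (v > 0) out["tajD"] <- (out["pi"] - out["thetaW"]) / sqrt(v)
      }
    }
  }
  if (n >= 2 && m >= 1) {
    if (has_na) {
      mom <- gkl_moments(genotype_distances(g))
    } else {
      gm <- matrix(0, n, n)
      for (v in 0:2) {
        a <- g == v
        storage.mode(a) <- "double"
        gm <- gm + tcrossprod(a)
      }
      d <- (m - gm)[lower.tri(gm)]
      mom <- gkl_moments(d)
    }
    out["varGkl"] <- mom[1]; out["skewGkl"] <- mom[2]; out["kurtGkl"] <- mom[3]
  }
  ds <- diplotype_spectrum(g)
  out["nDiplos"] <- ds$n_diplos; out["J1"] <- ds$J1
  out["J12"] <- ds$J12; out["J2J1"] <- ds$J2J1
  poly_idx <- which(ok & alt > 0L & alt < called)
  np <- length(poly_idx)
  if (np >= 2) {
    r2 <- r2_matrix(g[, poly_idx, drop = FALSE])
    vals <- r2[upper.tri(r2)]
    vals <- vals[!is.na(vals)]
    if (length(vals)) out["ZnS"] <- mean(vals)
    if (np >= 6) out["omegaMax"] <- omega_from_r2(r2)
  }
  out
}

## omega-max given a precomputed r^2 matrix over polymorphic sites in
## position order (NAs = skipped pairs)
omega_from_r2 <- function(r2) {
  s <- ncol(r2)
  if (s < 6L) return(0)
  v <- !is.na(r2)
  r2z <- ifelse(v, r2, 0)
  diag(v) <- FALSE
  tot_sum <- sum(r2z[upper.tri(r2z)])
  tot_n <- sum(v[upper.tri(v)])
  best <- 0
  ul_sum <- 0; ul_n <- 0
  ur_sum <- numeric(s); ur_n <- numeric(s)
  for (l in (s - 1):1) {
    cols <- if (l + 2 <= s) (l + 2):s else integer(0)
    ur_sum[l] <- ur_sum[l + 1] + sum(r2z[l + 1, cols])
    ur_n[l] <- ur_n[l + 1] + sum(v[l + 1, cols])
  }
  for (l in seq_len(s - 1)) {
    if (l >= 2) {
      ul_sum <- ul_sum + sum(r2z[seq_len(l - 1), l])
      ul_n <- ul_n + sum(v[seq_len(l - 1), l])
    }
    if (l < 3 || l > s - 3) next
    bw_sum <- tot_sum - ul_sum - ur_sum[l]
    bw_n <- tot_n - ul_n - ur_n[l]
    if (bw_n == 0 || bw_sum == 0) next
    wn <- ul_n + ur_n[l]
    if (wn == 0) next
    om <- ((ul_sum + ur_sum[l]) / wn) / (bw_sum / bw_n)
    if (is.finite(om) && om > best) best <- om
  }
  best
}

#' All 12 unphased window statistics at once
#'
#' Convenience wrapper returning the feature-vector statistics for a single
#' window slice in the fixed row order used throughout the package.
#'
#' @inheritParams site_frequencies
#' @return Named numeric vector of length 12: `pi`, `thetaW`, `tajD`,
#'   `varGkl`, `skewGkl`, `kurtGkl`, `nDiplos`, `J1`, `J12`, `J2J1`, `ZnS`,
#'   `omegaMax`.
#' @export
window_stats <- function(geno) {
  window_stats_fast(geno_entries(geno))
}

#' Names of the 12 feature-vector statistics in canonical row order
#' @return Character vector of length 12.
#' @export
stat_names <- function() {
  c("pi", "thetaW", "tajD", "varGkl", "skewGkl", "kurtGkl",
    "nDiplos", "J1", "J12", "J2J1", "ZnS", "omegaMax")
}
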