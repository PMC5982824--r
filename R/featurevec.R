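#' Subwindow layout for a classified region
#'
#' Splits a half-open span into `w` equal-width, non-overlapping subwindows
#' that tile it exactly. For integer-valued spans the width is
#' `floor(length / w)` and the last subwindow absorbs the remainder; real
#' spans (e.g. the \[0, 1) coordinates of simulated replicates) are divided
#' exactly. The central subwindow is the one a classification refers to.
#'
#' @param span length-2 numeric `[start, end)`.
#' @param w odd number of subwindows, default 11.
#' @return Object of class `window_layout`: list with `span`, `w`, `breaks`
#'   (length `w + 1`) and `central` (1-based index of the central subwindow).
#' @export
make_layout <- function(span, w = 11L) {
  span <- as.numeric(span)
  if (length(span) != 2 || span[2] <= span[1]) stop("span must be [start, end) with end > start")
  w <- as.integer(w)
  if (w < 3L || w %% 2L == 0L) stop("number of subwindows must be odd and >= 3, got ", w)
  len <- span[2] - span[1]
  if (isTRUE(all.equal(span, round(span))) && len >= w) {
    width <- floor(len / w)
    breaks <- span[1] + c(seq(0, by = width, length.out = w), len)
  } else {
    breaks <- seq(span[1], span[2], length.out = w + 1)
  }
  structure(list(span = span, w = w, breaks = breaks, central = (w + 1L) %/% 2L + 0L),
            class = "window_layout")
}

#' @exportS3Method base::print
print.window_layout <- function(x, ...) {
  cat("<window_layout> ", x$w, " subwindows on [", x$span[1], ", ", x$span[2],
      "), central = ", x$central, "\n", sep = "")
  invisible(x)
}

slice_window <- function(geno, lo, hi) {
  keep <- geno$positions >= lo & geno$positions < hi
  genotype_matrix(geno$genotypes[, keep, drop = FALSE], geno$positions[keep],
                  span = c(lo, hi))
}

#' Raw 12 x w profile of summary statistics
#'
#' Computes the 12 unphased statistics in every subwindow of the layout. Rows
#' follow [stat_names()]; columns are subwindows left to right. Empty
#' subwindows receive each statistic's documented degenerate value.
#'
#' @param geno a [genotype_matrix()] whose positions fall inside the layout
#'   span.
#' @param layout a [make_layout()]; defaults to 11 subwindows over the
#'   genotype span.
#' @return Numeric matrix of class `stat_profile`, dimension `12 x w`.
#' @export
compute_profile <- function(geno, layout = make_layout(geno$span)) {
  m <- .stats_profile_cpp(geno$genotypes, geno$positions, layout$breaks)
  rownames(m) <- stat_names()
  colnames(m) <- paste0("win", seq_len(layout$w))
  class(m) <- c("stat_profile", "matrix", "array")
  m
}

# pure-R reference used to validate the compiled fast path
compute_profile_r <- function(geno, layout = make_layout(geno$span)) {
  m <- vapply(seq_len(layout$w), function(i) {
    window_stats(slice_window(geno, layout$breaks[i], layout$breaks[i + 1]))
  }, numeric(12))
  rownames(m) <- stat_names()
  colnames(m) <- paste0("win", seq_len(layout$w))
  class(m) <- c("stat_profile", "matrix", "array")
  m
}

#' Spatial normalization of a statistic profile
#'
#' Applies the scale-free transform per statistic row: if the row minimum is
#' negative the row is first shifted by `-min`, then each element is divided
#' by the row sum, so every row expresses the relative share of the statistic
#' falling in each subwindow. A row that is all zero after the shift carries
#' no spatial information and is set to the uniform value `1/w`.
#'
#' @param profile a `stat_profile` (or any numeric matrix of finite values).
#' @return Matrix of class `feature_image`, same shape, rows on the simplex.
#' @export
normalize_profile <- function(profile) {
  m <- unclass(as.matrix(profile))
  if (!all(is.finite(m))) stop("profile contains non-finite values")
  w <- ncol(m)
  out <- t(apply(m, 1, function(x) {
    if (min(x) < 0) x <- x - min(x)
    s <- sum(x)
    if (s == 0) rep(1 / w, w) else x / s
  }))
  dimnames(out) <- dimnames(m)
  class(out) <- c("feature_image", "matrix", "array")
  out
}

#' Flatten a feature image to the 132-element vector
#'
#' Row-major flattening (statistic-major: all subwindows of statistic 1, then
#' statistic 2, ...), with stable names `<stat>_win<i>`.
#'
#' @param img a `feature_image` (or 12 x w matrix).
#' @return Named numeric vector of length `12 * w` (132 for the default
#'   layout).
#' @export
to_vector <- function(img) {
  m <- unclass(as.matrix(img))
  if (nrow(m) != 12) stop("feature image must have 12 statistic rows, got ", nrow(m))
  v <- as.numeric(t(m))
  names(v) <- feature_names(ncol(m))
  v
}

#' Names of the flattened feature vector entries
#' @param w number of subwindows (default 11).
#' @return Character vector of length `12 * w`.
#' @export
feature_names <- function(w = 11L) {
  as.vector(t(outer(stat_names(), seq_len(w), function(s, i) paste0(s, "_win", i))))
}

#' Reshape a flattened feature vector back into the 12 x w image
#' @param v numeric vector of length `12 * w`.
#' @param w number of subwindows (default 11).
#' @return A `feature_image` matrix.
#' @export
from_vector <- function(v, w = 11L) {
  if (length(v) != 12 * w) stop("expected a vector of length ", 12 * w)
  m <- matrix(as.numeric(v), nrow = 12, byrow = TRUE)
  rownames(m) <- stat_names()
  colnames(m) <- paste0("win", seq_len(w))
  class(m) <- c("feature_image", "matrix", "array")
  m
}

#' Feature vector of one region as a one-row tibble
#'
#' Convenience pipeline: profile, normalize, flatten.
#'
#' @inheritParams compute_profile
#' @return One-row tibble with `12 * w` feature columns.
#' @export
features_from_genotypes <- function(geno, layout = make_layout(geno$span)) {
  v <- to_vector(normalize_profile(compute_profile(geno, layout)))
  tibble::new_tibble(as.list(v), nrow = 1L)
}

#' Feature table from simulation replicates
#'
#' Diploidizes each haplotype replicate and extracts its normalized feature
#' vector; rows chain with the pipe into the classifier functions.
#'
#' @param reps list of [haplo_replicate()] (e.g. from [read_ms_replicates()]).
#' @param labels optional per-replicate class labels, recycled if length 1.
#' @param w number of subwindows.
#' @return Tibble with columns `label` (if given) and the `12 * w` features.
#' @export
features_from_replicates <- function(reps, labels = NULL, w = 11L) {
  if (inherits(reps, "haplo_replicate")) reps <- list(reps)
  ft <- purrr::map_dfr(reps, function(r) {
    geno <- diploidize(r)
    features_from_genotypes(geno, make_layout(c(0, 1), w))
  })
  if (!is.null(labels)) {
    ft <- dplyr::bind_cols(tibble::tibble(label = rep(labels, length.out = nrow(ft))), ft)
  }
  ft
}

#' Write / read a feature table as TSV
#'
#' @param features tibble from [features_from_replicates()] and friends.
#' @param file path.
#' @return `read_feature_tsv` returns the tibble; the writer returns the path
#'   invisibly.
#' @export
write_feature_tsv <- function(features, file) {
  readr::write_tsv(features, file)
  invisible(file)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(file) {
  readr::read_tsv(file, comment = "#", show_col_types = FALSE)
}
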