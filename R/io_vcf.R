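#' Read a BED accessibility mask
#'
#' Three-column BED (chrom, start, end), 0-based half-open, naming intervals
#' to be excluded from analysis.
#'
#' @param file path to a BED file.
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_bed_mask <- function(file) {
  df <- utils::read.table(file, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("chrom", "start", "end")
  tibble::as_tibble(df)
}

in_mask <- function(pos, chrom, mask) {
  if (is.null(mask) || !nrow(mask)) return(rep(FALSE, length(pos)))
  m <- mask[mask$chrom == chrom, , drop = FALSE]
  if (!nrow(m)) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(p >= m$start & p < m$end), logical(1))
}

parse_gt_column <- function(gt) {
  # "0/1", "0|1", "./." etc -> ALT-allele count or NA
  core <- sub(":.*$", "", gt)
  a1 <- substr(core, 1, 1)
  a2 <- substr(core, 3, 3)
  miss <- a1 == "." | a2 == "." | is.na(core) | nchar(core) < 3
  out <- ifelse(miss, NA_integer_,
                (a1 != "0") + (a2 != "0"))
  as.integer(out)
}

#' Extract an unphased genotype window from a VCF
#'
#' Reads biallelic SNPs on `chrom` with 0-based half-open positions in
#' `[start, end)` and returns ALT-allele counts per individual. Multiallelic
#' records and indels are skipped (a count is reported via message),
#' positions overlapping the mask are dropped, and sites missing in more
#' than `max_missing` of individuals are removed.
#'
#' @param vcf path to a VCF (plain or gzipped), or a `vcfR` object.
#' @param chrom chromosome name.
#' @param start,end half-open 0-based window (VCF POS is 1-based; converted
#'   on read).
#' @param samples optional character vector restricting individuals.
#' @param mask optional tibble from [read_bed_mask()].
#' @param max_missing per-site missingness threshold (fraction of
#'   individuals), default 0.25.
#' @return A [genotype_matrix()] with physical 0-based positions and span
#'   `[start, end)`.
#' @export
read_vcf_window <- function(vcf, chrom, start, end, samples = NULL,
                            mask = NULL, max_missing = 0.25) {
  if (end <= start) stop("inverted interval: end must exceed start")
  v <- if (inherits(vcf, "vcfR")) vcf else vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  pos0 <- as.numeric(fix$POS) - 1
  keep <- fix$CHROM == chrom & pos0 >= start & pos0 < end
  snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skip <- sum(keep & !snp, na.rm = TRUE)
  if (n_skip > 0) message("skipped ", n_skip, " non-biallelic-SNP records")
  keep <- keep & snp
  keep[is.na(keep)] <- FALSE
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(gt))
    if (length(missing_s)) stop("unknown samples: ", paste(missing_s, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  gt <- gt[keep, , drop = FALSE]
  pos0 <- pos0[keep]
  ord <- order(pos0)
  gt <- gt[ord, , drop = FALSE]
  pos0 <- pos0[ord]
  if (length(pos0)) {
    masked <- in_mask(pos0, chrom, mask)
    gt <- gt[!masked, , drop = FALSE]
    pos0 <- pos0[!masked]
  }
  g <- apply(gt, 2, parse_gt_column)
  if (!is.matrix(g)) g <- matrix(g, ncol = ncol(gt))
  g <- t(g)  # individuals x sites
  if (ncol(g)) {
    miss_frac <- colMeans(is.na(g))
    ok <- miss_frac <= max_missing
    g <- g[, ok, drop = FALSE]
    pos0 <- pos0[ok]
  }
  genotype_matrix(g, pos0, span = c(start, end))
}

#' Prediction records
#'
#' One classified window per row: coordinates, the five class probabilities
#' in canonical order, and the argmax label.
#'
#' @param chrom,start,end window coordinates (0-based half-open).
#' @param probs matrix (rows = windows) of class probabilities, columns in
#'   [class_levels()] order.
#' @return Tibble of class `prediction_records`.
#' @export
prediction_records <- function(chrom, start, end, probs) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 5L) stop("probs must have 5 columns")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) stop("probabilities must sum to 1")
  colnames(probs) <- class_levels()
  lab <- factor(class_levels()[max.col(probs, ties.method = "first")],
                levels = class_levels())
  out <- dplyr::bind_cols(
    tibble::tibble(chrom = as.character(chrom), start = start, end = end,
                   pred = lab),
    tibble::as_tibble(probs))
  class(out) <- c("prediction_records", class(out))
  out
}

pred_tsv_header <- function() {
  c("chrom", "classifiedWinStart", "classifiedWinEnd", "predClass",
    "prob(neutral)", "prob(linkedSoft)", "prob(linkedHard)", "prob(soft)",
    "prob(hard)")
}

#' Write / read classification output
#'
#' Tab-separated, one row per classified window, with the documented fixed
#' column order: chrom, classifiedWinStart, classifiedWinEnd, predClass,
#' then the five class probabilities (neutral, linkedSoft, linkedHard, soft,
#' hard). Lines starting with `#` are treated as comments on read.
#'
#' @param records a [prediction_records()] tibble (possibly empty).
#' @param file path.
#' @param comment optional provenance lines written before the header,
#'   prefixed with `#`.
#' @return The reader returns a `prediction_records` tibble; the writer the
#'   path, invisibly.
#' @export
write_predictions <- function(records, file, comment = NULL) {
  out <- records[, c("chrom", "start", "end", "pred", class_levels())]
  names(out) <- pred_tsv_header()
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(pred_tsv_header(), collapse = "\t"), con)
  if (nrow(out)) {
    lines <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(file)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    return(prediction_records(character(0), numeric(0), numeric(0),
                              matrix(numeric(0), 0, 5)))
  }
  probs <- as.matrix(df[, paste0("prob(", class_levels(), ")")])
  prediction_records(df$chrom, df$classifiedWinStart, df$classifiedWinEnd, probs)
}

#' Sliding-window feature extraction over a chromosome
#'
#' Slides a classified window of `window_size` bases along `[region_start,
#' region_end)`; each window sits at the center of an 11-subwindow context
#' of total size `11 * window_size` from which the feature image is
#' computed. Windows whose context does not fit in the region, or in which
#' any subwindow has less than `min_unmasked` of its span accessible, are
#' skipped.
#'
#' @param geno a [genotype_matrix()] covering the region (e.g. from
#'   [read_vcf_window()]), with physical positions.
#' @param window_size classified (central subwindow) size in bases.
#' @param region_start,region_end bounds scanned; default the genotype span.
#' @param step slide step, default `window_size`.
#' @param mask optional mask tibble (same chromosome) used for the
#'   accessibility fraction.
#' @param chrom chromosome name for the mask lookup and output.
#' @param min_unmasked minimum accessible fraction per subwindow.
#' @param w number of subwindows.
#' @return Tibble with `chrom`, `start`, `end` (the classified window) and
#'   the feature columns; skipped windows are omitted.
#' @export
vcf_feature_windows <- function(geno, window_size,
                                region_start = geno$span[1],
                                region_end = geno$span[2],
                                step = window_size, mask = NULL,
                                chrom = "chr", min_unmasked = 0.25, w = 11L) {
  half <- (w %/% 2L) * window_size
  starts <- seq(region_start + half, region_end - half - window_size, by = step)
  if (!length(starts)) return(tibble::tibble())
  rows <- purrr::map(starts, function(s0) {
    ctx <- c(s0 - half, s0 + window_size + half)
    layout <- make_layout(ctx, w)
    if (!is.null(mask)) {
      frac <- vapply(seq_len(w), function(i) {
        lo <- layout$breaks[i]; hi <- layout$breaks[i + 1]
        m <- mask[mask$chrom == chrom & mask$end > lo & mask$start < hi, , drop = FALSE]
        covered <- if (nrow(m)) sum(pmin(m$end, hi) - pmax(m$start, lo)) else 0
        1 - covered / (hi - lo)
      }, numeric(1))
      if (any(frac < min_unmasked)) return(NULL)
    }
    keep <- geno$positions >= ctx[1] & geno$positions < ctx[2]
    sub <- genotype_matrix(geno$genotypes[, keep, drop = FALSE],
                           geno$positions[keep], span = ctx)
    ft <- features_from_genotypes(sub, layout)
    dplyr::bind_cols(tibble::tibble(chrom = chrom, start = s0,
                                    end = s0 + window_size), ft)
  })
  dplyr::bind_rows(purrr::compact(rows))
}
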