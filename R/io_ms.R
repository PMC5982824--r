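#' Haplotype replicate
#'
#' Light container for one ms/discoal-style simulation replicate: a matrix of
#' 0/1 haplotypes with fractional site positions on \[0, 1\].
#'
#' @param haplotypes integer matrix, one row per sampled chromosome, entries
#'   in \{0, 1\}.
#' @param positions numeric vector of nondecreasing fractional positions, one
#'   per column of `haplotypes`.
#' @return An object of class `haplo_replicate` with fields `segsites`,
#'   `positions` and `haplotypes`.
#' @export
haplo_replicate <- function(haplotypes, positions) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  positions <- as.numeric(positions)
  if (ncol(haplotypes) != length(positions)) {
    stop("positions length (", length(positions),
         ") does not match number of sites (", ncol(haplotypes), ")")
  }
  if (length(positions) > 1 && any(diff(positions) < 0)) {
    stop("positions must be nondecreasing")
  }
  if (length(haplotypes) && !all(haplotypes %in% c(0L, 1L))) {
    stop("haplotypes must be 0/1")
  }
  structure(
    list(segsites = ncol(haplotypes), positions = positions,
         haplotypes = haplotypes),
    class = "haplo_replicate"
  )
}

#' @exportS3Method base::print
print.haplo_replicate <- function(x, ...) {
  cat("<haplo_replicate> ", nrow(x$haplotypes), " chromosomes x ",
      x$segsites, " segregating sites\n", sep = "")
  invisible(x)
}

#' Read ms/discoal-style replicates
#'
#' Parses the classic coalescent-simulator text dialect: replicates delimited
#' by `//`, each with a `segsites: N` line, a `positions: ...` line (absent
#' when `segsites` is 0), then one 0/1 character row per sampled chromosome.
#'
#' @param file path to a replicate file, or a character vector of lines.
#' @return A list of [haplo_replicate()] objects, one per `//` block.
#' @export
read_ms_replicates <- function(file) {
  lines <- if (length(file) == 1 && file.exists(file)) readLines(file) else as.character(file)
  starts <- which(trimws(lines) == "//")
  if (!length(starts)) stop("no '//' replicate delimiters found")
  ends <- c(starts[-1] - 1L, length(lines))
  purrr::map2(starts, ends, function(s, e) {
    block <- lines[s:e]
    parse_ms_block(block, line_offset = s - 1L)
  })
}

parse_ms_block <- function(block, line_offset = 0L) {
  seg_i <- grep("^segsites:", trimws(block))
  if (!length(seg_i)) {
    stop("replicate starting at line ", line_offset + 1L, " has no 'segsites:' line")
  }
  seg_i <- seg_i[1]
  segsites <- suppressWarnings(as.integer(sub("^segsites:\\s*", "", trimws(block[seg_i]))))
  if (is.na(segsites)) {
    stop("malformed 'segsites:' header at line ", line_offset + seg_i)
  }
  if (segsites == 0L) {
    return(haplo_replicate(matrix(integer(0), nrow = 0, ncol = 0), numeric(0)))
  }
  pos_i <- grep("^positions:", trimws(block))
  if (!length(pos_i)) {
    stop("replicate starting at line ", line_offset + 1L, " has no 'positions:' line")
  }
  pos_i <- pos_i[1]
  positions <- as.numeric(strsplit(trimws(sub("^positions:\\s*", "", trimws(block[pos_i]))),
                                   "\\s+")[[1]])
  if (length(positions) != segsites) {
    stop("positions line at line ", line_offset + pos_i, " has ", length(positions),
         " entries, expected ", segsites)
  }
  rows <- block[-seq_len(pos_i)]
  rows <- rows[nzchar(trimws(rows))]
  haps <- matrix(0L, nrow = length(rows), ncol = segsites)
  for (i in seq_along(rows)) {
    r <- trimws(rows[i])
    if (nchar(r) != segsites) {
      stop("haplotype row at line ", line_offset + pos_i + i, " has length ",
           nchar(r), ", expected ", segsites)
    }
    v <- utf8ToInt(r) - utf8ToInt("0")
    if (any(v < 0L | v > 1L)) {
      stop("non-binary character in haplotype row at line ", line_offset + pos_i + i)
    }
    haps[i, ] <- v
  }
  haplo_replicate(haps, positions)
}

#' Write replicates in the ms dialect
#'
#' @param reps list of [haplo_replicate()] objects.
#' @param file output path.
#' @param header optional first line (command-line echo slot of the dialect).
#' @export
write_ms_replicates <- function(reps, file, header = "sweepimage ms-dialect") {
  if (inherits(reps, "haplo_replicate")) reps <- list(reps)
  out <- c(header, "")
  for (rep in reps) {
    out <- c(out, "//", paste0("segsites: ", rep$segsites))
    if (rep$segsites > 0) {
      out <- c(out,
               paste0("positions: ", paste(formatC(rep$positions, format = "f", digits = 6),
                                           collapse = " ")),
               apply(rep$haplotypes, 1, paste, collapse = ""))
    }
    out <- c(out, "")
  }
  writeLines(out, file)
  invisible(file)
}

#' Unphased genotype matrix
#'
#' The universal input container: one row per diploid individual, one column
#' per biallelic site, entries counting alternate alleles (0, 1, 2) with `NA`
#' for missing calls.
#'
#' @param genotypes integer matrix of \{0, 1, 2, NA\}.
#' @param positions per-site positions (physical or fractional), nondecreasing.
#' @param span length-2 numeric, half-open `[start, end)` of the region.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, positions,
                            span = c(0, if (length(positions)) max(positions) + 1 else 1)) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  positions <- as.numeric(positions)
  if (ncol(genotypes) != length(positions)) {
    stop("positions length does not match number of sites")
  }
  if (length(positions) > 1 && any(diff(positions) < 0)) {
    stop("positions must be nondecreasing")
  }
  ok <- genotypes %in% c(0L, 1L, 2L) | is.na(genotypes)
  if (length(genotypes) && !all(ok)) stop("genotypes must be 0, 1, 2 or NA")
  if (length(positions) && (any(positions < span[1]) || any(positions >= span[2]))) {
    stop("positions fall outside span")
  }
  structure(list(genotypes = genotypes, positions = positions,
                 span = as.numeric(span)),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$genotypes), " individuals x ",
      ncol(x$genotypes), " sites, span [", x$span[1], ", ", x$span[2], ")\n",
      sep = "")
  invisible(x)
}

#' Combine haplotypes into unphased diploid genotypes
#'
#' Pairs consecutive chromosome rows (1-2, 3-4, ...) into individuals and sums
#' their alleles, mirroring how coalescent samples of exchangeable chromosomes
#' are analysed as diploids.
#'
#' @param rep a [haplo_replicate()].
#' @return A [genotype_matrix()] with `n_chrom / 2` individuals on span
#'   `[0, 1)` (fractional positions preserved).
#' @export
diploidize <- function(rep) {
  n <- nrow(rep$haplotypes)
  if (n %% 2L != 0L) stop("need an even number of chromosomes to diploidize, got ", n)
  if (rep$segsites == 0L) {
    return(genotype_matrix(matrix(integer(0), nrow = n %/% 2L, ncol = 0),
                           numeric(0), span = c(0, 1)))
  }
  g <- rep$haplotypes[seq(1, n, by = 2), , drop = FALSE] +
    rep$haplotypes[seq(2, n, by = 2), , drop = FALSE]
  genotype_matrix(g, rep$positions, span = c(0, 1))
}
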