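# Programmatic fixtures: a small VCF writer and a mock classifier whose
# probabilities are fixed, used to probe the evaluation machinery.

write_tiny_vcf <- function(path, records, samples = c("S1", "S2", "S3")) {
  # records: data.frame with chrom, pos (1-based), ref, alt, and one column
  # of genotype strings per sample
  hdr <- c("##fileformat=VCFv4.2",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  paste(samples, collapse = "\t")))
  body <- apply(records, 1, function(r) {
    paste(c(r[["chrom"]], r[["pos"]], ".", r[["ref"]], r[["alt"]], ".",
            "PASS", ".", "GT", r[samples]), collapse = "\t")
  })
  writeLines(c(hdr, body), path)
  path
}

# a classifier stub returning predetermined probabilities row by row
mock_model <- function(probs) {
  structure(list(probs = as.matrix(probs)), class = "sweep_mock")
}

register_mock_model <- function() {
  registerS3method(
    "predict_probs", "sweep_mock",
    function(model, X) {
      stopifnot(nrow(X) == nrow(model$probs))
      model$probs
    },
    envir = asNamespace("sweepimage"))
}

# tiny, almost linearly separable two-class feature set shaped like real
# feature tables (132 columns, labels hard vs neutral)
separable_set <- function(n_per_class = 60) {
  base_hard <- rep(0.05, 132)
  base_hard[seq(56, 66)] <- c(0.02, 0.02, 0.03, 0.05, 0.1, 0.4, 0.1, 0.05, 0.03, 0.02, 0.02)
  base_neut <- rep(1 / 11, 132)
  mk <- function(base, label, n) {
    X <- t(vapply(seq_len(n), function(i) {
      v <- abs(base + stats::rnorm(132, sd = 0.01))
      v
    }, numeric(132)))
    colnames(X) <- feature_names()
    out <- tibble::as_tibble(X)
    out$label <- label
    out
  }
  dplyr::bind_rows(mk(base_hard, "hard", n_per_class),
                   mk(base_neut, "neutral", n_per_class))
}
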