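#' @useDynLib sweepimage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The five sweep classes in canonical order
#'
#' Order is fixed across all outputs: probabilities, prediction TSVs and
#' confusion matrices.
#' @return Character vector of length 5.
#' @export
class_levels <- function() c("neutral", "linkedSoft", "linkedHard", "soft", "hard")

#' Simulation configuration
#'
#' Study conditions for generating labeled training data with the built-in
#' rescaled forward Wright-Fisher simulator. Selection strength, fixation
#' time and soft-sweep starting frequency follow the priors used throughout:
#' alpha = 2Ns ~ U(250, 2500) ("moderate"; "weak" is U(25, 250), "strong"
#' U(2500, 25000)), tau ~ U(0, 0.025) in units of 4N generations under
#' constant size (U(0, 0.0004) under growth), f ~ U(0, 0.2).
#'
#' The mutation and recombination totals are artifact choices (sized so that
#' neutral replicates carry roughly 40-60 segregating sites per subwindow at
#' n = 60 chromosomes, with enough recombination that a moderate sweep's
#' footprint spans only a few of the 11 subwindows).
#'
#' @param n_chrom sampled haploid chromosomes (must be even; diploids = n/2).
#' @param scenario one of "moderate", "weak", "strong" (sets `alpha_range`).
#' @param alpha_range uniform prior bounds on alpha = 2Ns.
#' @param tau_range uniform prior bounds on time since fixation (4N units).
#' @param f_range uniform prior bounds on soft-sweep starting frequency.
#' @param N rescaled diploid population size of the simulator.
#' @param L number of discrete sites in the region.
#' @param theta population-scaled mutation rate (4 N mu) for the region.
#' @param rho population-scaled recombination rate (4 N r) for the region.
#' @param n_sub number of subwindows (odd).
#' @param burnin_factor neutral burn-in length in units of N generations.
#' @param n_retry rejection budget for conditioning on fixation.
#' @param demography `NULL` for constant size, or a [growth_demography()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 60L,
                       scenario = c("moderate", "weak", "strong"),
                       alpha_range = NULL,
                       tau_range = NULL,
                       f_range = c(0, 0.2),
                       N = 100L, L = 2200L, theta = 110, rho = 550,
                       n_sub = 11L, burnin_factor = 10, n_retry = 1000L,
                       demography = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(alpha_range)) {
    alpha_range <- switch(scenario,
                          moderate = c(250, 2500),
                          weak = c(25, 250),
                          strong = c(2500, 25000))
  }
  if (is.null(tau_range)) {
    tau_range <- if (is.null(demography)) c(0, 0.025) else c(0, 0.0004)
  }
  if (n_chrom %% 2L != 0L) stop("n_chrom must be even")
  if (n_chrom / 2 > N) stop("sample of ", n_chrom / 2, " diploids exceeds population size ", N)
  structure(list(n_chrom = as.integer(n_chrom), scenario = scenario,
                 alpha_range = alpha_range, tau_range = tau_range,
                 f_range = f_range, N = as.integer(N), L = as.integer(L),
                 theta = theta, rho = rho, n_sub = as.integer(n_sub),
                 burnin_factor = burnin_factor, n_retry = as.integer(n_retry),
                 demography = demography),
            class = "sim_config")
}

#' Population growth demography
#'
#' Piecewise-constant size history: the population sits at `1/fold_change` of
#' its current size, then grows instantaneously to the current size
#' `duration` time units before sampling. Strong recent growth produces the
#' familiar excess of rare variants (negative Tajima's D) in neutral data.
#'
#' @param fold_change growth factor, >= 1 (1 recovers constant size).
#' @param duration time since growth in units of 4N generations (current N).
#' @return List of class `growth_demography`.
#' @export
growth_demography <- function(fold_change = 30, duration = 0.05) {
  if (fold_change < 1) stop("fold_change must be >= 1")
  if (duration <= 0) stop("duration must be positive")
  structure(list(fold_change = fold_change, duration = duration),
            class = "growth_demography")
}

#' Draw one sweep model from the priors
#'
#' @param label class label, one of [class_levels()].
#' @param config a [sim_config()].
#' @param sweep_win 1-based subwindow holding the selected site; defaults to
#'   the central subwindow for hard/soft and a uniform draw among the 10
#'   flanking subwindows for the linked classes.
#' @return List of class `sweep_model` with the realized parameter draws.
#' @export
draw_sweep_model <- function(label, config, sweep_win = NULL) {
  label <- match.arg(label, class_levels())
  central <- (config$n_sub + 1L) %/% 2L
  kind <- switch(label, neutral = "none",
                 hard = , linkedHard = "hard",
                 soft = , linkedSoft = "soft")
  if (kind == "none") {
    sweep_win <- NA_integer_
  } else if (is.null(sweep_win)) {
    sweep_win <- if (label %in% c("hard", "soft")) central else {
      flank <- setdiff(seq_len(config$n_sub), central)
      flank[sample.int(length(flank), 1L)]
    }
  }
  alpha <- if (kind == "none") NA_real_ else stats::runif(1, config$alpha_range[1], config$alpha_range[2])
  tau <- if (kind == "none") NA_real_ else stats::runif(1, config$tau_range[1], config$tau_range[2])
  f0 <- if (kind == "soft") stats::runif(1, config$f_range[1], config$f_range[2]) else
    if (kind == "hard") 1 / (2 * config$N) else NA_real_
  structure(list(label = label, kind = kind, sweep_win = sweep_win,
                 alpha = alpha, tau = tau, f0 = f0),
            class = "sweep_model")
}

#' Simulate one haplotype replicate
#'
#' Runs the rescaled forward Wright-Fisher engine: neutral burn-in (plus any
#' demographic phase), optional sweep conditioned on fixation of the
#' beneficial allele (soft sweeps first drift a single injected copy
#' neutrally up to frequency `f`, so the standing variant carries a genuine
#' neutral haplotype background), then `tau * 4N` neutral generations before
#' sampling. Randomness comes from R's RNG, so `set.seed()` upstream fixes
#' the replicate.
#'
#' @param model a [draw_sweep_model()], or a class label (a model is drawn).
#' @param config a [sim_config()].
#' @return A [haplo_replicate()] with attribute `meta` (one-row tibble of the
#'   realized parameters).
#' @export
simulate_replicate <- function(model, config = sim_config()) {
  if (is.character(model)) model <- draw_sweep_model(model, config)
  N <- config$N
  mu <- config$theta / (4 * N)
  rr <- config$rho / (4 * N)
  if (is.null(config$demography)) {
    phase_gens <- as.integer(round(config$burnin_factor * N))
    phase_N <- N
  } else {
    n0 <- max(5L, as.integer(round(N / config$demography$fold_change)))
    phase_gens <- c(as.integer(round(config$burnin_factor * n0)),
                    as.integer(round(config$demography$duration * 4 * N)))
    phase_N <- c(n0, N)
  }
  sel_site <- if (model$kind == "none") -1L else
    as.integer(round((model$sweep_win - 0.5) * config$L / config$n_sub))
  s <- if (model$kind == "none") 0 else model$alpha / (2 * N)
  tau_gens <- if (model$kind == "none") 0L else as.integer(round(model$tau * 4 * N))
  res <- .sim_sweep_cpp(config$n_chrom %/% 2L, config$L, mu, rr,
                        phase_gens, phase_N,
                        model$kind, sel_site, s,
                        if (is.na(model$f0)) 0 else model$f0,
                        tau_gens, config$n_retry, 50000L)
  rep <- haplo_replicate(res$haplotypes, res$positions)
  attr(rep, "meta") <- tibble::tibble(
    label = model$label, sweep_win = model$sweep_win,
    alpha = model$alpha, tau = model$tau,
    f_target = model$f0, f_realized = res$f_realized,
    attempts = res$attempts, segsites = res$segsites)
  rep
}

#' Build a balanced labeled training (and test) set
#'
#' Simulates `n_per_class` replicates for each of the five classes (plus an
#' independent test set drawn by the same procedure), converts each to its
#' normalized 12 x 11 feature image, and returns everything as one tibble.
#' Hard/soft examples place the sweep in the central subwindow; the linked
#' classes draw the sweep subwindow uniformly among the 10 flanking
#' positions. The set is balanced by construction.
#'
#' @param config a [sim_config()].
#' @param n_per_class training replicates per class (>= 1).
#' @param n_test_per_class independent test replicates per class (0 to skip).
#' @param keep_replicates if TRUE, the raw [haplo_replicate()] objects are
#'   attached as attribute `replicates`.
#' @param progress print a line per simulated batch.
#' @return Tibble with columns `set` ("train"/"test"), `label` (factor over
#'   [class_levels()]), `sweep_win`, `alpha`, `tau`, `f_realized`, and the
#'   `12 * n_sub` feature columns.
#' @export
build_training_set <- function(config = sim_config(), n_per_class = 100L,
                               n_test_per_class = 0L, keep_replicates = FALSE,
                               progress = FALSE) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  layout <- make_layout(c(0, 1), config$n_sub)
  all_reps <- list()
  sim_block <- function(set_name, n_each) {
    purrr::map_dfr(class_levels(), function(lab) {
      if (progress) message("simulating ", n_each, " '", lab, "' (", set_name, ")")
      purrr::map_dfr(seq_len(n_each), function(i) {
        rep <- simulate_replicate(lab, config)
        if (keep_replicates) all_reps[[length(all_reps) + 1L]] <<- rep
        meta <- attr(rep, "meta")
        ft <- features_from_genotypes(diploidize(rep), layout)
        dplyr::bind_cols(
          tibble::tibble(set = set_name, label = meta$label,
                         sweep_win = meta$sweep_win, alpha = meta$alpha,
                         tau = meta$tau, f_realized = meta$f_realized),
          ft)
      })
    })
  }
  out <- sim_block("train", n_per_class)
  if (n_test_per_class > 0) out <- dplyr::bind_rows(out, sim_block("test", n_test_per_class))
  out$label <- factor(out$label, levels = class_levels())
  if (keep_replicates) attr(out, "replicates") <- all_reps
  out
}
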