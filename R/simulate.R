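# Two-library count simulator with known ground truth.
#
# Emulates the design of a two-library normalized cDNA sequencing study:
# a fixed sequencing yield per library allocated multinomially over contigs,
# with an abundance profile flattened by normalization, a configurable
# fraction of truly enriched contigs at known fold effects, and optional
# structurally library-exclusive contigs.

#' Simulation configuration
#'
#' Defaults reproduce the scale of a 454 two-library study: ~45.5k contigs
#' and ~7.2-7.4e5 reads per library.
#'
#' @param n_contigs Number of contigs; default 45538.
#' @param n_reads_a,n_reads_b Library sizes (multinomial totals); defaults
#'   742771 (library A, female) and 721543 (library B, male).
#' @param abundance_model `"flat"` (all contigs share one base rate; the
#'   idealized limit of a normalized library) or `"lognormal"` (base rates
#'   `10^rnorm(0, sigma_log10)`, a flattened but not degenerate profile).
#' @param sigma_log10 Dispersion of the lognormal model on the log10 scale;
#'   default 0.5.
#' @param frac_enriched Fraction of contigs that are truly differentially
#'   represented; split evenly between the two directions.
#' @param fold_grid True fold effects assigned to enriched contigs, cycled
#'   in order; default `c(2, 10, 100)`.
#' @param frac_exclusive Fraction of contigs whose rate is structurally zero
#'   in one library (split evenly between directions).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_contigs = 45538,
                              n_reads_a = 742771,
                              n_reads_b = 721543,
                              abundance_model = c("flat", "lognormal"),
                              sigma_log10 = 0.5,
                              frac_enriched = 0,
                              fold_grid = c(2, 10, 100),
                              frac_exclusive = 0,
                              seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  if (n_contigs < 1 || n_reads_a < 1 || n_reads_b < 1)
    stop_config("n_contigs and library sizes must be positive")
  if (frac_enriched < 0 || frac_exclusive < 0 ||
      frac_enriched + frac_exclusive >= 1)
    stop_config("frac_enriched + frac_exclusive must lie in [0, 1)")
  if (length(fold_grid) < 1 || any(fold_grid <= 0))
    stop_config("fold_grid must be positive")
  if (sigma_log10 < 0) stop_config("sigma_log10 must be >= 0")
  structure(list(n_contigs = as.integer(n_contigs),
                 n_reads_a = as.integer(n_reads_a),
                 n_reads_b = as.integer(n_reads_b),
                 abundance_model = abundance_model,
                 sigma_log10 = sigma_log10,
                 frac_enriched = frac_enriched,
                 fold_grid = fold_grid,
                 frac_exclusive = frac_exclusive,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a two-library count table with known truth
#'
#' Per-contig relative abundances are drawn from the configured model.
#' Enriched contigs have their rate multiplied by `sqrt(fold)` in the
#' favoured library and divided by `sqrt(fold)` in the other, so the true
#' rate ratio equals the assigned fold. Counts are then drawn multinomially
#' per library, so column sums equal the configured library sizes exactly.
#' Contigs that receive zero reads in both libraries are dropped (a real
#' assembly has no such contig) and their number is reported.
#'
#' @param config A [simulation_config()] object.
#' @return A list with `counts` (data frame `contig_id`, `count_a`,
#'   `count_b`), `sizes` (a [library_sizes()], basis `reads_in_contigs`),
#'   `truth` (data frame `contig_id`, `true_class`, `true_fold`, restricted
#'   to retained contigs), and `n_dropped` (contigs with zero reads in both
#'   libraries).
#' @export
simulate_study <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    stop_config("config must be a simulation_config object")
  set.seed(config$seed)
  n <- config$n_contigs

  base <- switch(config$abundance_model,
                 flat = rep(1, n),
                 lognormal = 10^stats::rnorm(n, 0, config$sigma_log10))

  n_enr <- round(config$frac_enriched * n)
  n_exc <- round(config$frac_exclusive * n)
  true_class <- rep("null", n)
  true_fold <- rep(1, n)
  if (n_enr > 0) {
    idx <- seq_len(n_enr)
    true_class[idx] <- rep(c("enriched_A", "enriched_B"), length.out = n_enr)
    true_fold[idx] <- rep(config$fold_grid, length.out = n_enr)
  }
  if (n_exc > 0) {
    idx <- n_enr + seq_len(n_exc)
    true_class[idx] <- rep(c("exclusive_A", "exclusive_B"), length.out = n_exc)
    true_fold[idx] <- Inf
  }
  # scatter the planted contigs uniformly over contig indices
  perm <- sample.int(n)
  true_class <- true_class[perm]
  true_fold <- true_fold[perm]

  half <- sqrt(ifelse(is.finite(true_fold), true_fold, 1))
  w_a <- base * ifelse(true_class == "enriched_A", half,
                       ifelse(true_class == "enriched_B", 1 / half, 1))
  w_b <- base * ifelse(true_class == "enriched_B", half,
                       ifelse(true_class == "enriched_A", 1 / half, 1))
  w_a[true_class == "exclusive_B"] <- 0
  w_b[true_class == "exclusive_A"] <- 0

  count_a <- as.vector(stats::rmultinom(1, config$n_reads_a, w_a))
  count_b <- as.vector(stats::rmultinom(1, config$n_reads_b, w_b))

  ids <- sprintf("contig%05d", seq_len(n))
  keep <- count_a + count_b > 0
  list(counts = data.frame(contig_id = ids[keep],
                           count_a = count_a[keep], count_b = count_b[keep],
                           stringsAsFactors = FALSE),
       sizes = library_sizes(config$n_reads_a, config$n_reads_b,
                             basis = "reads_in_contigs"),
       truth = data.frame(contig_id = ids[keep],
                          true_class = true_class[keep],
                          true_fold = true_fold[keep],
                          stringsAsFactors = FALSE),
       n_dropped = sum(!keep))
}

#' Empirical power and false-positive rate over a simulation grid
#'
#' For every combination of expected per-library depth, true fold and
#' significance cutoff, simulates a study in which `frac_enriched` of the
#' contigs carry the given fold, applies [call_enrichment()], and tabulates
#' the fraction of truly enriched contigs called (power) and of truly null
#' contigs called (false-positive rate), with Wilson 95% intervals.
#' `fold = 1` rows are pure null simulations whose power column *is* the
#' FPR. Library sizes are set to `depth * n_contigs` for both libraries.
#'
#' @param config A [simulation_config()]; `n_contigs`, `frac_enriched`,
#'   `abundance_model` and `seed` are taken from it.
#' @param alpha_grid Significance cutoffs; default 0.001.
#' @param fold_grid True folds to plant; default `c(1, 2, 10, 100)`.
#' @param depth_grid Expected reads per contig per library; default
#'   `c(5, 20, 50)`.
#' @return Data frame with one row per (depth, fold, alpha) cell:
#'   `depth`, `fold`, `alpha`, `n_true`, `power`, `power_lo`, `power_hi`,
#'   `n_null`, `fpr`, `fpr_lo`, `fpr_hi`.
#' @export
power_curve <- function(config = simulation_config(n_contigs = 20000,
                                                   frac_enriched = 0.05),
                        alpha_grid = 0.001,
                        fold_grid = c(1, 2, 10, 100),
                        depth_grid = c(5, 20, 50)) {
  if (length(alpha_grid) < 1 || length(fold_grid) < 1 || length(depth_grid) < 1)
    stop_config("grids must be non-empty")
  rows <- vector("list", length(depth_grid) * length(fold_grid))
  k <- 0L
  for (depth in depth_grid) for (fold in fold_grid) {
    k <- k + 1L
    cfg <- simulation_config(
      n_contigs = config$n_contigs,
      n_reads_a = depth * config$n_contigs,
      n_reads_b = depth * config$n_contigs,
      abundance_model = config$abundance_model,
      sigma_log10 = config$sigma_log10,
      frac_enriched = if (fold == 1) 0 else config$frac_enriched,
      fold_grid = fold,
      seed = config$seed + k)
    sim <- simulate_study(cfg)
    cells <- lapply(alpha_grid, function(alpha) {
      # exclusive contigs enter the test here: at high fold a truly enriched
      # contig often lands all its reads in one library, and leaving it
      # untested would make measured power non-monotone in fold
      calls <- call_enrichment(sim$counts, sim$sizes,
                               enrichment_config(alpha = alpha,
                                                 include_exclusive = TRUE))
      hit <- calls$enriched
      is_true <- sim$truth$true_class %in% c("enriched_A", "enriched_B")
      n_true <- sum(is_true)
      n_null <- sum(!is_true)
      k_true <- sum(hit & is_true)
      k_null <- sum(hit & !is_true)
      # a pure-null cell (fold = 1) has no true positives: its power IS the FPR
      pow <- if (n_true > 0) k_true / n_true else k_null / n_null
      pci <- if (n_true > 0) wilson_ci(k_true, n_true) else wilson_ci(k_null, n_null)
      fci <- wilson_ci(k_null, n_null)
      data.frame(depth = depth, fold = fold, alpha = alpha,
                 n_true = n_true, power = pow,
                 power_lo = pci[["lower"]], power_hi = pci[["upper"]],
                 n_null = n_null, fpr = k_null / n_null,
                 fpr_lo = fci[["lower"]], fpr_hi = fci[["upper"]])
    })
    rows[[k]] <- do.call(rbind, cells)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
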