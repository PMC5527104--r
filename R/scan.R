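#' Control parameters for an SMP scan
#'
#' @param B permutation replicates per column per test (default 10,000).
#' @param alpha per-test detection threshold used in the contribution
#'   summary (default 0.05).
#' @param q_threshold BH FDR threshold for calling SMPs (default 0.10).
#' @param min_genes minimum number of distinct mutated genes for a column to
#'   be tested (default 2).
#' @param seed master RNG seed; per-(column, test) streams are derived from
#'   it deterministically.
#' @param entropy_base base of the column-entropy logarithm (default natural
#'   log).
#' @param eps boundary clamp for Z-score combination.
#' @param randomized if `TRUE`, permutation and Poisson p-values are
#'   tie-randomized: under the null they are exactly uniform on `(0, 1)`
#'   instead of discrete and slightly conservative.  Intended for
#'   calibration diagnostics (e.g. KS uniformity checks), not for reporting;
#'   default `FALSE`.
#' @return a list of class `smp_control`.
#' @export
smp_control <- function(B = 10000, alpha = 0.05, q_threshold = 0.10,
                        min_genes = 2, seed = 1, entropy_base = exp(1),
                        eps = 1e-4, randomized = FALSE) {
  stopifnot(B >= 1, alpha > 0, alpha < 1, q_threshold >= 0, min_genes >= 1)
  structure(list(B = as.integer(B), alpha = alpha,
                 q_threshold = q_threshold, min_genes = as.integer(min_genes),
                 seed = as.integer(seed), entropy_base = entropy_base,
                 eps = eps, randomized = isTRUE(randomized)),
            class = "smp_control")
}

#' Scan an aligned domain family for significantly mutated positions
#'
#' The full analysis in one call: fits the empirical background from
#' non-domain mutations, runs the seven-test panel on every column mutated
#' in at least `min_genes` genes, combines the per-column p-values with
#' Fisher's method (Z-scores alongside for comparison), BH-adjusts across
#' tested columns, and calls SMPs at `q < q_threshold`.
#'
#' @param alignment an `smp_alignment` from [read_alignment()] or
#'   [simulate_family()].
#' @param mutations an `smp_mutations` data frame from [read_mutations()].
#' @param sequences named character vector of full protein sequences
#'   (background residue counting).
#' @param scores optional per-gene cancer-likelihood scores (enables the
#'   Cancer Genes test).
#' @param distances optional patristic distance matrix (enables the Gene
#'   Relatedness test).
#' @param control an [smp_control()] list.
#' @return an object of class `smp_scan` with elements `background`,
#'   `tests` (per-column panel), `combined` (Fisher/Z/q per column), `smps`
#'   (called SMP rows), `contributions`, `characterization`, `control`.
#' @examples
#' cfg <- smp_sim_config(n_genes = 40, domain_length = 40,
#'                       flank_length = 40, n_patients = 50,
#'                       baseline_rate = 1e-3, seed = 7,
#'                       planted = list(plant(column = 10, fold = 15)))
#' sim <- simulate_smp_data(cfg)
#' fit <- smp_scan(sim$family$alignment, sim$mutations,
#'                 sim$family$sequences, sim$family$scores,
#'                 sim$family$distances, smp_control(B = 200, seed = 1))
#' fit$smps$column  # contains the planted column 10
#' @export
smp_scan <- function(alignment, mutations, sequences, scores = NULL,
                     distances = NULL, control = smp_control()) {
  stopifnot(inherits(alignment, "smp_alignment"))
  background <- fit_background(mutations, sequences, alignment)
  tests <- run_all_tests(alignment, mutations, background, scores,
                         distances, control)
  combined <- combine_tests(tests, control$q_threshold, control$eps)
  smps <- call_smps(combined, control$q_threshold)
  contributions <- if (nrow(tests)) test_contributions(tests, combined,
                                                       control$alpha)
                   else NULL
  characterization <- characterize_smps(smps$column, alignment, mutations,
                                        tested_columns = tests$column,
                                        entropy_base = control$entropy_base)
  structure(
    list(background = background, tests = tests, combined = combined,
         smps = smps, contributions = contributions,
         characterization = characterization, control = control,
         n_columns = alignment$n_columns),
    class = "smp_scan")
}

#' @export
print.smp_scan <- function(x, ...) {
  cat("SMP scan\n")
  cat("  columns tested (>= ", x$control$min_genes,
      " mutated genes): ", nrow(x$tests), " of ", x$n_columns, "\n",
      sep = "")
  cat("  SMPs at q < ", x$control$q_threshold, ": ", nrow(x$smps), "\n",
      sep = "")
  if (nrow(x$smps)) {
    top <- head(x$smps, 5)
    cat("  top columns: ",
        paste0(top$column, " (q=", signif(top$q, 3), ")",
               collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.smp_scan <- function(object, ...) {
  structure(list(scan = object), class = "summary.smp_scan")
}

#' @export
print.summary.smp_scan <- function(x, ...) {
  s <- x$scan
  print(s)
  if (!is.null(s$contributions)) {
    cat("\nPer-test detections at p < ", s$control$alpha, ":\n", sep = "")
    ct <- s$contributions$per_test
    for (i in seq_len(nrow(ct)))
      cat(sprintf("  %-20s %d/%d SMPs, %d/%d other columns\n",
                  ct$test[i], ct$smp_detected[i], ct$n_smp[i],
                  ct$nonsmp_detected[i], ct$n_nonsmp[i]))
    cat("  SMPs detected by >=2 tests: ", s$contributions$smp_multi[["ge2"]],
        "; by >=3: ", s$contributions$smp_multi[["ge3"]], "\n", sep = "")
  }
  mn <- s$characterization$means
  cat("\nColumn characteristics (means):\n")
  for (i in seq_len(nrow(mn)))
    cat(sprintf(paste0("  %-7s n=%4d  aligned=%6.1f  mutations=%6.1f  ",
                       "mutated genes=%5.1f  entropy=%4.2f\n"),
                mn$stratum[i], mn$n_columns[i], mn$n_aligned[i],
                mn$n_mutations[i], mn$n_mutated_genes[i], mn$entropy[i]))
  invisible(x)
}

#' Plot an SMP scan
#'
#' Manhattan-style view: `-log10(q)` per tested column, SMPs highlighted,
#' the FDR threshold as a horizontal line.
#'
#' @param x an `smp_scan`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.smp_scan <- function(x, ...) {
  cb <- x$combined
  plot(cb$column, -log10(cb$q), xlab = "alignment column",
       ylab = expression(-log[10](q)), pch = 16,
       col = ifelse(cb$is_smp, "firebrick", "grey40"), ...)
  abline(h = -log10(x$control$q_threshold), lty = 2)
  invisible(x)
}
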