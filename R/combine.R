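#' Combine p-values with Fisher's method
#'
#' `X^2_{2k} = -2 sum_i ln p_i`, referred to the upper tail of a chi-square
#' distribution with `2k` degrees of freedom.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return list with `stat` and `p`.
#' @export
fisher_combine <- function(p) {
  if (length(p) < 1) stop("no p-values to combine")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stat <- -2 * sum(log(p))
  list(stat = stat, p = pchisq(stat, df = 2 * length(p),
                               lower.tail = FALSE))
}

#' Combine p-values with the unweighted Z-score (Stouffer) method
#'
#' `z = sum_i qnorm(1 - p_i) / sqrt(k)`, one-sided.  Boundary p-values are
#' clamped to `[eps, 1 - eps]` (with a message) so the normal quantile is
#' finite; the default `eps = 1e-4` matches the resolution floor of the
#' default permutation grid (`1/(B+1)` at `B = 10000`), so a tied p-value of
#' 1 is treated symmetrically with one at the permutation floor.
#'
#' @inheritParams fisher_combine
#' @param eps clamping tolerance.
#' @return list with `z` and `p`.
#' @export
stouffer_combine <- function(p, eps = 1e-4) {
  if (length(p) < 1) stop("no p-values to combine")
  if (any(p <= 0 | p >= 1)) {
    message("boundary p-value(s) clamped to [", eps, ", 1 - ", eps,
            "] for Z-score combination")
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  z <- sum(qnorm(1 - p)) / sqrt(length(p))
  list(z = z, p = pnorm(z, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR adjustment with cumulative-minimum monotonicity,
#' computed over the tested columns only.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return numeric vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Combine the per-column test panel and control FDR
#'
#' For each tested column the available test p-values (missing / inapplicable
#' tests are dropped, with the chi-square degrees of freedom adjusted to the
#' number actually combined) are merged by Fisher's method and, for
#' comparison, by unweighted Z-scores.  Fisher p-values are BH-adjusted
#' across the tested columns.
#'
#' @param tests an `smp_testtable` from [run_all_tests()].
#' @param q_threshold FDR threshold for the SMP flag (default 0.10).
#' @param eps clamping tolerance passed to [stouffer_combine()].
#' @return data frame of class `smp_combined`: `column`, `k` (tests
#'   combined), `fisher_stat`, `fisher_p`, `z_stat`, `z_p`, `q`, `is_smp`.
#' @export
combine_tests <- function(tests, q_threshold = 0.10, eps = 1e-4) {
  pcols <- paste0(TEST_NAMES, "_p")
  rows <- lapply(seq_len(nrow(tests)), function(i) {
    p <- unlist(tests[i, pcols])
    p <- p[!is.na(p)]
    if (length(p) == 0)
      return(data.frame(column = tests$column[i], k = 0L,
                        fisher_stat = NA_real_, fisher_p = NA_real_,
                        z_stat = NA_real_, z_p = NA_real_))
    f <- fisher_combine(p)
    z <- suppressMessages(stouffer_combine(p, eps))
    data.frame(column = tests$column[i], k = length(p),
               fisher_stat = f$stat, fisher_p = f$p,
               z_stat = z$z, z_p = z$p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(column = integer(), k = integer(),
                      fisher_stat = numeric(), fisher_p = numeric(),
                      z_stat = numeric(), z_p = numeric())
  out$q <- if (nrow(out)) bh_fdr(out$fisher_p) else numeric()
  out$is_smp <- !is.na(out$q) & out$q < q_threshold
  class(out) <- c("smp_combined", "data.frame")
  out
}

#' Call significantly mutated positions
#'
#' @param combined an `smp_combined` data frame.
#' @param q_threshold FDR threshold (default 0.10).
#' @return the SMP rows, sorted by `q`.
#' @export
call_smps <- function(combined, q_threshold = 0.10) {
  smps <- combined[!is.na(combined$q) & combined$q < q_threshold, ,
                   drop = FALSE]
  smps[order(smps$q, smps$fisher_p), , drop = FALSE]
}

#' Per-test contribution to SMP detection
#'
#' Counts, for each test, the SMPs (and non-SMP tested columns) at which the
#' test's raw p-value falls below `alpha`, plus how many columns are detected
#' by at least two and at least three tests.
#'
#' @param tests an `smp_testtable`.
#' @param combined an `smp_combined` over the same columns.
#' @param alpha per-test detection threshold (default 0.05).
#' @return list with `per_test` (data frame: test, smp_detected, n_smp,
#'   nonsmp_detected, n_nonsmp), `smp_multi` and `nonsmp_multi` (counts of
#'   columns detected by >= 2 and >= 3 tests).
#' @export
test_contributions <- function(tests, combined, alpha = 0.05) {
  stopifnot(identical(tests$column, combined$column))
  is_smp <- combined$is_smp
  pm <- as.matrix(tests[paste0(TEST_NAMES, "_p")])
  det <- !is.na(pm) & pm < alpha
  per_test <- data.frame(
    test = TEST_NAMES,
    smp_detected = colSums(det[is_smp, , drop = FALSE]),
    n_smp = sum(is_smp),
    nonsmp_detected = colSums(det[!is_smp, , drop = FALSE]),
    n_nonsmp = sum(!is_smp),
    row.names = NULL)
  ndet <- rowSums(det)
  list(per_test = per_test,
       smp_multi = c(ge2 = sum(ndet[is_smp] >= 2),
                     ge3 = sum(ndet[is_smp] >= 3)),
       nonsmp_multi = c(ge2 = sum(ndet[!is_smp] >= 2),
                        ge3 = sum(ndet[!is_smp] >= 3)))
}

#' Characterize SMP columns against the rest of the alignment
#'
#' Per column and averaged over three strata (SMPs, all tested columns, all
#' alignment columns): number of aligned domains, mutations, mutated genes,
#' mutations per aligned domain, mutations per mutated gene, fraction of
#' aligned genes mutated, and column entropy.
#'
#' @param smp_columns integer vector of SMP column indices.
#' @param alignment an `smp_alignment`.
#' @param dataset an `smp_mutations` data frame.
#' @param tested_columns integer vector of all tested columns (for the
#'   middle stratum); defaults to the SMP columns.
#' @param entropy_base base for [column_entropy()].
#' @return list with `per_column` (data frame over SMP columns) and `means`
#'   (data frame with one row per stratum).
#' @export
characterize_smps <- function(smp_columns, alignment, dataset,
                              tested_columns = smp_columns,
                              entropy_base = exp(1)) {
  dom <- dataset[dataset$in_domain, , drop = FALSE]
  stats_for <- function(a) {
    n_aligned <- sum(alignment$mat[, a] != "-")
    rows <- dom$column == a
    n_mut <- sum(rows)
    n_genes <- length(unique(dom$gene[rows]))
    data.frame(column = a, n_aligned = n_aligned, n_mutations = n_mut,
               n_mutated_genes = n_genes,
               mut_per_aligned = if (n_aligned > 0) n_mut / n_aligned else 0,
               mut_per_mut_gene = if (n_genes > 0) n_mut / n_genes else 0,
               frac_genes_mutated = if (n_aligned > 0) n_genes / n_aligned
                                    else 0,
               entropy = column_entropy(alignment, a, entropy_base))
  }
  per_column <- do.call(rbind, lapply(smp_columns, stats_for))
  strata <- list(smp = smp_columns, tested = tested_columns,
                 all = seq_len(alignment$n_columns))
  means <- do.call(rbind, lapply(names(strata), function(nm) {
    cols <- strata[[nm]]
    if (length(cols) == 0)
      return(data.frame(stratum = nm, n_columns = 0, n_aligned = NA,
                        n_mutations = NA, n_mutated_genes = NA,
                        mut_per_aligned = NA, mut_per_mut_gene = NA,
                        frac_genes_mutated = NA, entropy = NA))
    tab <- do.call(rbind, lapply(cols, stats_for))
    data.frame(stratum = nm, n_columns = length(cols),
               t(colMeans(tab[-1], na.rm = TRUE)))
  }))
  list(per_column = per_column, means = means)
}
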