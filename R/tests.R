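#' Empirical p-value from a permutation null
#'
#' Add-one estimator: `p = (1 + # replicates at least as extreme as the
#' observed statistic) / (B + 1)`, ties counted as extreme.  This keeps every
#' p-value strictly positive (so Fisher combination is always defined) and is
#' a valid p-value under exchangeability of the observed statistic with the
#' replicates.
#'
#' @param observed observed statistic (finite scalar).
#' @param null numeric vector of `B >= 1` replicate statistics.
#' @param tail `"upper"` (extreme means `>= observed`) or `"lower"`
#'   (`<= observed`).
#' @return p-value in `(0, 1]`.
#' @export
empirical_p <- function(observed, null, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (length(null) < 1) stop("empty null distribution")
  if (!is.finite(observed)) stop("non-finite observed statistic")
  extreme <- if (tail == "upper") sum(null >= observed)
             else sum(null <= observed)
  (1 + extreme) / (length(null) + 1)
}

# p-value against a permutation null.  The default is the exported add-one
# estimator.  `randomized = TRUE` breaks ties with a uniform draw, giving a
# p-value that is EXACTLY uniform under exchangeability despite the discrete
# null; used for calibration diagnostics only (must be called with the RNG
# already seeded).
perm_p <- function(stat, null, tail, randomized = FALSE) {
  if (!randomized) return(empirical_p(stat, null, tail))
  more <- if (tail == "upper") sum(null > stat) else sum(null < stat)
  ties <- 1 + sum(null == stat)
  (more + runif(1) * ties) / (length(null) + 1)
}

test_result <- function(test, column, statistic, p, tail, B = NA_integer_,
                        seed = NA_integer_, applicable = TRUE) {
  structure(list(test = test, column = column, statistic = statistic,
                 p = p, tail = tail, B = B, seed = seed,
                 applicable = applicable),
            class = "smp_test_result")
}

#' Mutation Number test
#'
#' Upper-tail Poisson test of the total mutation count at a column.  Each
#' residue contributes mutations at its background rate `E_r`, so the column
#' total is Poisson with mean `E_a = sum_r E_r R_ar`; the p-value is
#' `P(X >= N_a)` in closed form.  Mutation-level: recurrent events are
#' non-redundant.
#'
#' @param profile an `smp_profile`.
#' @param model an `smp_background`.
#' @param randomized tie-randomized p-value for calibration diagnostics
#'   (see [smp_control()]); default `FALSE`.
#' @param seed RNG seed (used only when `randomized = TRUE`).
#' @return an `smp_test_result`.
#' @export
test_mutation_number <- function(profile, model, randomized = FALSE,
                                 seed = 1) {
  E_a <- expected_column_rate(model, profile)
  N_a <- profile$N_a
  if (N_a > 0 && E_a == 0)
    stop("degenerate Poisson null: E_a = 0 with N_a > 0 at column ",
         profile$column)
  p <- if (randomized)
    with_seed(seed, ppois(N_a, E_a, lower.tail = FALSE) +
                runif(1) * stats::dpois(N_a, E_a))
  else if (N_a == 0) 1
  else ppois(N_a - 1, E_a, lower.tail = FALSE)
  test_result("mutation_number", profile$column, N_a, p, "upper")
}

# chi-square goodness-of-fit statistic over label count classes:
# X2 = sum_c (O_c - E_c)^2 / E_c with E_c = N_a * N_c / N
label_chisq_stat <- function(O_c, N_a, prob) {
  E_c <- N_a * prob
  sum((O_c - E_c)^2 / E_c)
}

#' Patient / Cancer Type label distribution test
#'
#' Asks whether the mutations at a column are distributed among patients (or
#' cancer types) as expected given how often each label occurs in the whole
#' dataset.  Each label carries a mutation count `c`; observed per-class
#' counts at the column are compared by chi-square to `E_ac = N_a N_c / N`.
#' The null is empirical: `N_a` labels are redrawn with replacement from the
#' full dataset's label multiset (domain and non-domain mutations alike,
#' deliberately) and the statistic recomputed.  Mutation-level test.
#'
#' @inheritParams test_mutation_number
#' @param label_family `"patient"` or `"cancer_type"`.
#' @param B number of null replicates.
#' @param seed RNG seed for the null draws.
#' @return an `smp_test_result` (upper tail).
#' @export
test_label_distribution <- function(profile, model,
                                    label_family = c("patient", "cancer_type"),
                                    B = 10000, seed = 1,
                                    randomized = FALSE) {
  label_family <- match.arg(label_family)
  if (B < 1) stop("B must be >= 1")
  N_a <- profile$N_a
  if (N_a < 1) stop("no mutations at column ", profile$column)
  fam <- model[[label_family]]
  obs_labels <- if (label_family == "patient") profile$O_patient
                else profile$O_cancer_type
  # class of each observed label = its dataset-wide mutation count
  cls <- as.integer(fam$counts[names(obs_labels)])
  if (anyNA(cls))
    stop("label(s) at column ", profile$column,
         " absent from the background label table")
  O_c <- vapply(fam$classes, function(cc)
    sum(obs_labels[cls == cc]), numeric(1))
  stat <- label_chisq_stat(O_c, N_a, fam$prob)
  # a redrawn label lands in class c with probability N_c / N, so the null
  # statistic depends only on multinomial class counts
  p <- with_seed(seed, {
    cnt <- rmultinom(B, N_a, fam$prob)
    E_c <- N_a * fam$prob
    perm_p(stat, colSums((cnt - E_c)^2 / E_c), "upper", randomized)
  })
  test_result(paste0(label_family, "s"), profile$column, stat, p, "upper",
              B, seed)
}

#' Reference Residues test
#'
#' Asks whether the residues being mutated at a column are the ones expected
#' from the column's composition and the background rates: `E_ar = R_ar E_r`,
#' chi-square over residue types present at the column with `E_ar > 0`.
#' Residue-level: identical substitutions collapse to one event.  The null
#' redraws the same number of events from residue types weighted by `E_ar`.
#'
#' @inheritParams test_label_distribution
#' @return an `smp_test_result` (upper tail).
#' @export
test_reference_residues <- function(profile, model, B = 10000, seed = 1,
                                    randomized = FALSE) {
  if (B < 1) stop("B must be >= 1")
  support <- names(profile$R_ar)[profile$R_ar > 0 &
                                   !is.na(model$E_r) & model$E_r > 0]
  E_ar <- profile$R_ar[support] * model$E_r[support]
  if (length(E_ar) == 0 || sum(E_ar) == 0)
    stop("all residue expectations zero at column ", profile$column)
  O_ar <- profile$O_ar[support]
  m <- sum(profile$O_ar)
  if (m < 1) stop("no residue-level events at column ", profile$column)
  stat <- sum((O_ar - E_ar)^2 / E_ar)
  p <- with_seed(seed, {
    cnt <- rmultinom(B, m, E_ar / sum(E_ar))
    perm_p(stat, colSums((cnt - E_ar)^2 / E_ar), "upper", randomized)
  })
  test_result("reference_residues", profile$column, stat, p, "upper", B,
              seed)
}

#' Variant Residues test
#'
#' Asks whether the amino acids produced by mutation at a column are the ones
#' expected from the background substitution spectrum:
#' `E_av = sum_r P_rv O_ar`, chi-square over variant types with `E_av > 0`.
#' Residue-level.  The null redraws variant types weighted by `E_av`, event
#' count fixed.
#'
#' @inheritParams test_label_distribution
#' @return an `smp_test_result` (upper tail).
#' @export
test_variant_residues <- function(profile, model, B = 10000, seed = 1,
                                  randomized = FALSE) {
  if (B < 1) stop("B must be >= 1")
  obs_r <- names(profile$O_ar)[profile$O_ar > 0]
  m <- sum(profile$O_ar)
  if (m < 1) stop("no residue-level events at column ", profile$column)
  undef <- obs_r[is.na(model$P_rv[obs_r, 1])]
  if (length(undef))
    stop("substitution probabilities undefined for reference residue(s): ",
         paste(undef, collapse = ", "))
  E_av <- colSums(model$P_rv[obs_r, , drop = FALSE] *
                    profile$O_ar[obs_r])
  support <- names(E_av)[E_av > 0]
  E_av <- E_av[support]
  O_av <- profile$O_av[support]
  stat <- sum((O_av - E_av)^2 / E_av)
  p <- with_seed(seed, {
    cnt <- rmultinom(B, m, E_av / sum(E_av))
    perm_p(stat, colSums((cnt - E_av)^2 / E_av), "upper", randomized)
  })
  test_result("variant_residues", profile$column, stat, p, "upper", B,
              seed)
}

# Weighted gene draws without replacement shared by the two gene-level tests.
# A gene's weight at a column is the background rate E_r of its own aligned
# residue; genes with undefined E_r are excluded from the draw.  Draws are
# without replacement: after gene-level collapse a gene can appear at most
# once at a column.
gene_null_draws <- function(profile, model, B, seed) {
  res <- aligned_residues_of_profile(profile)
  w <- model$E_r[res]
  keep <- !is.na(w) & w > 0
  genes <- names(res)[keep]
  w <- w[keep]
  m <- profile$n_mutated_genes
  if (length(genes) < m)
    stop("fewer weight-eligible aligned genes than mutated genes at column ",
         profile$column)
  draws <- with_seed(seed, {
    vapply(seq_len(B),
           function(b) sample.int(length(genes), m, prob = w),
           integer(m))
  })
  list(genes = genes, draws = matrix(draws, nrow = m))
}

# residues per aligned (non-gap) gene at the profile's column
aligned_residues_of_profile <- function(profile) {
  profile$aligned
}

#' Cancer Genes test
#'
#' Asks whether the genes mutated at a column are enriched in likely cancer
#' genes: the statistic is the mean cancer-likelihood score of the mutated
#' genes (smaller = more cancer-like), compared against weighted draws of
#' the same number of genes from those aligned at the column.  Gene-level;
#' lower-tail p-value.
#'
#' @inheritParams test_label_distribution
#' @param scores named numeric vector of per-gene cancer-likelihood scores
#'   covering every gene aligned at the column.
#' @return an `smp_test_result` (lower tail).
#' @export
test_cancer_genes <- function(profile, scores, model, B = 10000, seed = 1,
                              randomized = FALSE) {
  if (B < 1) stop("B must be >= 1")
  mg <- names(profile$mutated_genes)
  if (length(mg) < 1) stop("no gene-level events at column ", profile$column)
  aligned <- names(aligned_residues_of_profile(profile))
  missing <- setdiff(aligned, names(scores))
  if (length(missing))
    stop("scores missing for aligned gene(s): ",
         paste(missing, collapse = ", "))
  stat <- mean(scores[mg])
  nd <- gene_null_draws(profile, model, B, seed)
  sc <- scores[nd$genes]
  null <- colMeans(matrix(sc[nd$draws], nrow = nrow(nd$draws)))
  p <- with_seed(derive_seed(seed, 1, 1),
                 perm_p(stat, null, "lower", randomized))
  test_result("cancer_genes", profile$column, stat, p, "lower", B, seed)
}

#' Gene Relatedness test
#'
#' Asks whether the genes mutated at a column sit closer together on the
#' family guide tree than weighted random draws of aligned genes: the
#' statistic is the mean pairwise patristic distance among mutated genes.
#' Gene-level; lower-tail p-value; requires at least two mutated genes
#' (otherwise flagged not applicable).
#'
#' @inheritParams test_cancer_genes
#' @param distances symmetric patristic distance matrix covering every gene
#'   aligned at the column (see [read_newick_distances()]).
#' @return an `smp_test_result` (lower tail), or a not-applicable result
#'   when fewer than two genes are mutated.
#' @export
test_gene_relatedness <- function(profile, distances, model, B = 10000,
                                  seed = 1, randomized = FALSE) {
  if (B < 1) stop("B must be >= 1")
  mg <- names(profile$mutated_genes)
  if (length(mg) < 2)
    return(test_result("gene_relatedness", profile$column, NA_real_,
                       NA_real_, "lower", B, seed, applicable = FALSE))
  aligned <- names(aligned_residues_of_profile(profile))
  missing <- setdiff(aligned, rownames(distances))
  if (length(missing))
    stop("distance matrix missing aligned gene(s): ",
         paste(missing, collapse = ", "))
  mean_pair <- function(idx, D) sum(D[idx, idx]) / (length(idx) *
                                                      (length(idx) - 1))
  Dm <- distances[mg, mg, drop = FALSE]
  stat <- sum(Dm) / (length(mg) * (length(mg) - 1))
  nd <- gene_null_draws(profile, model, B, seed)
  D <- distances[nd$genes, nd$genes, drop = FALSE]
  null <- vapply(seq_len(ncol(nd$draws)),
                 function(b) mean_pair(nd$draws[, b], D), numeric(1))
  p <- with_seed(derive_seed(seed, 1, 1),
                 perm_p(stat, null, "lower", randomized))
  test_result("gene_relatedness", profile$column, stat, p, "lower", B,
              seed)
}

TEST_NAMES <- c("mutation_number", "patients", "cancer_types",
                "reference_residues", "variant_residues",
                "cancer_genes", "gene_relatedness")

#' Run the full seven-test panel over all eligible columns
#'
#' Tests every alignment column mutated in at least `min_genes` distinct
#' genes (gene-level count; default 2).  Tests whose preconditions fail at a
#' column (e.g. Gene Relatedness with a single mutated gene) are recorded as
#' missing.  Per-(column, test) RNG streams are derived from the master seed,
#' so results are deterministic and independent of evaluation order.
#'
#' @param alignment an `smp_alignment`.
#' @param dataset an `smp_mutations` data frame.
#' @param model an `smp_background` fit on the same dataset.
#' @param scores optional per-gene score vector (Cancer Genes test; skipped
#'   if `NULL`).
#' @param distances optional patristic distance matrix (Gene Relatedness
#'   test; skipped if `NULL`).
#' @param control a list from [smp_control()]: uses `B`, `seed`, `min_genes`.
#' @return data frame of class `smp_testtable`: one row per tested column
#'   with `column`, `n_aligned`, `n_mutations`, `n_mutated_genes`, and a
#'   `<test>_stat` / `<test>_p` pair for each of the seven tests.
#' @export
run_all_tests <- function(alignment, dataset, model, scores = NULL,
                          distances = NULL, control = smp_control()) {
  dom <- dataset[dataset$in_domain, , drop = FALSE]
  gene_counts <- table(unique(dom[c("gene", "column")])$column)
  tested <- sort(as.integer(names(gene_counts)[gene_counts >=
                                                 control$min_genes]))
  if (!is.null(scores)) {
    missing <- setdiff(alignment$genes, names(scores))
    if (length(missing))
      stop("score table missing gene(s): ",
           paste(head(missing, 5), collapse = ", "))
  }
  if (!is.null(distances)) {
    missing <- setdiff(alignment$genes, rownames(distances))
    if (length(missing))
      stop("distance matrix missing gene(s): ",
           paste(head(missing, 5), collapse = ", "))
  }

  cols <- list()
  for (a in tested) {
    profile <- column_profile(alignment, dataset, a, level = "residue")
    row <- list(column = a, n_aligned = profile$n_aligned,
                n_mutations = profile$N_a,
                n_mutated_genes = profile$n_mutated_genes)
    run1 <- function(idx, fun, ...) {
      tryCatch(fun(profile, ...),
               error = function(e) test_result(TEST_NAMES[idx], a,
                                               NA_real_, NA_real_, "upper",
                                               applicable = FALSE))
    }
    B <- control$B; ms <- control$seed
    rz <- isTRUE(control$randomized)
    r <- vector("list", 7)
    r[[1]] <- run1(1, test_mutation_number, model, rz, derive_seed(ms, a, 1))
    r[[2]] <- run1(2, test_label_distribution, model, "patient", B,
                   derive_seed(ms, a, 2), rz)
    r[[3]] <- run1(3, test_label_distribution, model, "cancer_type", B,
                   derive_seed(ms, a, 3), rz)
    r[[4]] <- run1(4, test_reference_residues, model, B,
                   derive_seed(ms, a, 4), rz)
    r[[5]] <- run1(5, test_variant_residues, model, B,
                   derive_seed(ms, a, 5), rz)
    r[[6]] <- if (is.null(scores))
      test_result("cancer_genes", a, NA_real_, NA_real_, "lower",
                  applicable = FALSE)
    else run1(6, test_cancer_genes, scores, model, B, derive_seed(ms, a, 6),
              rz)
    r[[7]] <- if (is.null(distances))
      test_result("gene_relatedness", a, NA_real_, NA_real_, "lower",
                  applicable = FALSE)
    else run1(7, test_gene_relatedness, distances, model, B,
              derive_seed(ms, a, 7), rz)
    for (i in seq_len(7)) {
      row[[paste0(TEST_NAMES[i], "_stat")]] <- r[[i]]$statistic
      row[[paste0(TEST_NAMES[i], "_p")]] <- r[[i]]$p
    }
    cols[[length(cols) + 1]] <- row
  }
  out <- do.call(rbind, lapply(cols, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(out))
    out <- data.frame(column = integer(), n_aligned = integer(),
                      n_mutations = integer(), n_mutated_genes = integer())
  class(out) <- c("smp_testtable", "data.frame")
  out
}
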