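#' Fit the empirical background model from non-domain mutations
#'
#' The null hypothesis for every column test is that aligned-domain mutations
#' are produced by the same processes as the mutations falling outside the
#' aligned domains of the same genes.  This fits that background:
#'
#' * `E_r = O_r / N_r`: expected mutations per residue of type `r`, where
#'   `O_r` counts non-domain mutations at residues of type `r` (silent
#'   mutations included) and `N_r` counts type-`r` residues outside the
#'   domains across all gene sequences.
#' * `P_rv`: 20x20 row-stochastic substitution matrix estimated from
#'   non-domain (ref, var) pairs; the diagonal carries the silent mass.
#'   Rows with no observations are left undefined (`NA`) unless a
#'   pseudocount is requested.
#' * Patient and cancer-type mutation-count tables.  Each label's count `c`
#'   is the number of mutations carrying it; `N_c` is the total number of
#'   mutations from labels with count `c`.  Unlike everything else, these
#'   tables deliberately use ALL mutations (domain and non-domain), as the
#'   patient / cancer-type tests condition on the full dataset.
#'
#' @param dataset an `smp_mutations` data frame.
#' @param sequences named character vector of full protein sequences for all
#'   genes in the dataset.
#' @param alignment the `smp_alignment` (supplies per-gene domain spans used
#'   to count non-domain residues).
#' @param pseudocount added to every cell of the substitution count matrix
#'   before row normalization (default 0; useful only for tiny fixtures).
#' @return an object of class `smp_background` with elements `E_r`, `O_r`,
#'   `N_r`, `P_rv`, `patient`, `cancer_type` (each a list with `counts`,
#'   `classes`, `N_c`, `prob`), `N`, `n_nondomain`.
#' @export
fit_background <- function(dataset, sequences, alignment, pseudocount = 0) {
  nd <- dataset[!dataset$in_domain, , drop = FALSE]
  if (nrow(nd) == 0)
    stop("no non-domain mutations: the empirical null is undefinable")

  genes <- intersect(alignment$genes, names(sequences))
  if (length(genes) == 0) stop("sequences do not cover the aligned genes")

  # residue counts outside the domain span, per type
  N_r <- setNames(numeric(length(AA20)), AA20)
  for (g in genes) {
    s <- strsplit(sequences[[g]], "", fixed = TRUE)[[1]]
    dom <- seq.int(alignment$domain_start[[g]], alignment$domain_end[[g]])
    outside <- s[-dom]
    if (length(outside))
      N_r <- N_r + tabulate(factor(outside, levels = AA20), nbins = 20)
  }
  O_r <- tabulate(factor(nd$ref, levels = AA20), nbins = 20)
  O_r <- setNames(as.numeric(O_r), AA20)
  E_r <- ifelse(N_r > 0, O_r / N_r, NA_real_)
  E_r <- setNames(E_r, AA20)

  counts <- table(factor(nd$ref, levels = AA20),
                  factor(nd$var, levels = AA20))
  counts <- matrix(as.numeric(counts), 20, 20,
                   dimnames = list(AA20, AA20)) + pseudocount
  rs <- rowSums(counts)
  P_rv <- counts / ifelse(rs > 0, rs, NA_real_)

  label_table <- function(labels) {
    per_label <- table(labels)               # c for each label
    classes <- sort(unique(as.integer(per_label)))
    N_c <- vapply(classes, function(cc)
      sum(per_label[per_label == cc]), numeric(1))
    list(counts = per_label, classes = classes,
         N_c = setNames(N_c, classes), prob = N_c / sum(N_c))
  }

  structure(
    list(E_r = E_r, O_r = O_r, N_r = N_r, P_rv = P_rv,
         patient = label_table(dataset$patient),
         cancer_type = label_table(dataset$cancer_type),
         N = nrow(dataset), n_nondomain = nrow(nd)),
    class = "smp_background")
}

#' Expected mutation count at an aligned column
#'
#' `E_a = sum_r E_r * R_ar`: the per-type background rates weighted by the
#' column's aligned residue composition.  This is the Poisson mean of the
#' Mutation Number test and underlies the residue-level expectations.
#'
#' @param model an `smp_background`.
#' @param profile an `smp_profile`.
#' @return non-negative scalar `E_a`.
#' @export
expected_column_rate <- function(model, profile) {
  present <- names(profile$R_ar)[profile$R_ar > 0]
  if (length(present) == 0) return(0)
  undef <- present[is.na(model$E_r[present])]
  if (length(undef))
    stop("background rate E_r undefined for aligned residue type(s): ",
         paste(undef, collapse = ", "))
  sum(model$E_r[present] * profile$R_ar[present])
}

#' Serialize / restore a background model as JSON
#'
#' @param model an `smp_background`.
#' @param path file to write to / read from.
#' @return `write_background_json` returns `path` invisibly;
#'   `read_background_json` returns an `smp_background`.
#' @export
write_background_json <- function(model, path) {
  x <- list(E_r = as.list(model$E_r), O_r = as.list(model$O_r),
            N_r = as.list(model$N_r),
            P_rv = apply(model$P_rv, 1, as.list, simplify = FALSE),
            patient = list(counts = as.list(c(model$patient$counts)),
                           classes = model$patient$classes,
                           N_c = as.list(model$patient$N_c)),
            cancer_type = list(counts = as.list(c(model$cancer_type$counts)),
                               classes = model$cancer_type$classes,
                               N_c = as.list(model$cancer_type$N_c)),
            N = model$N, n_nondomain = model$n_nondomain)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_background_json
#' @export
read_background_json <- function(path) {
  x <- jsonlite::read_json(path)
  num <- function(l) vapply(l, function(v) if (is.null(v)) NA_real_
                            else as.numeric(v), numeric(1))
  P <- do.call(rbind, lapply(x$P_rv, num))
  dimnames(P) <- list(AA20, AA20)
  relabel <- function(l) {
    counts <- num(l$counts)
    classes <- as.integer(unlist(l$classes))
    N_c <- num(l$N_c)
    names(N_c) <- classes
    list(counts = counts, classes = classes, N_c = N_c,
         prob = N_c / sum(N_c))
  }
  structure(
    list(E_r = num(x$E_r), O_r = num(x$O_r), N_r = num(x$N_r), P_rv = P,
         patient = relabel(x$patient), cancer_type = relabel(x$cancer_type),
         N = as.integer(x$N), n_nondomain = as.integer(x$n_nondomain)),
    class = "smp_background")
}

#' @export
print.smp_background <- function(x, ...) {
  cat("Empirical mutation background\n")
  cat("  dataset mutations: ", x$N, " (", x$n_nondomain,
      " outside the aligned domains)\n", sep = "")
  cat("  mean E_r: ", signif(mean(x$E_r, na.rm = TRUE), 4),
      " mutations per residue\n", sep = "")
  cat("  substitution rows defined: ", sum(!is.na(x$P_rv[, 1])), "/20\n",
      sep = "")
  invisible(x)
}
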