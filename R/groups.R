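#' Eligible gene groups for within-group re-analysis
#'
#' Small or heterogeneous groups give results that swing on single
#' mutations, so the within-group scan is limited to groups strictly
#' exceeding both a membership and a domain-mutation threshold, with
#' catch-all labels excluded.
#'
#' @param groups data frame `gene`, `group` (see [read_gene_groups()]).
#' @param dataset an `smp_mutations` data frame.
#' @param alignment an `smp_alignment`.
#' @param min_members groups must have MORE than this many aligned member
#'   genes (default 20).
#' @param min_mutations groups must have MORE than this many in-domain
#'   mutations (default 2000).
#' @param exclude group labels excluded outright (case-insensitive; default
#'   `c("atypical", "other")`).
#' @return data frame with `group`, `n_members`, `n_domain_mutations` for
#'   eligible groups, plus a `members` list-column.
#' @export
eligible_groups <- function(groups, dataset, alignment, min_members = 20,
                            min_mutations = 2000,
                            exclude = c("atypical", "other")) {
  groups <- groups[groups$gene %in% alignment$genes, , drop = FALSE]
  dom <- dataset[dataset$in_domain, , drop = FALSE]
  labs <- unique(groups$group)
  rows <- lapply(labs, function(lab) {
    members <- groups$gene[groups$group == lab]
    data.frame(group = lab, n_members = length(members),
               n_domain_mutations = sum(dom$gene %in% members))
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(labs, function(lab) groups$gene[groups$group == lab])
  keep <- out$n_members > min_members &
    out$n_domain_mutations > min_mutations &
    !(tolower(out$group) %in% tolower(exclude))
  out[keep, , drop = FALSE]
}

#' Re-run the SMP scan inside one gene group
#'
#' Restricts the alignment and mutation catalog to the group's member genes,
#' refits the background from the members' non-domain mutations (the null
#' should derive from the same mutational processes as the tested
#' mutations), reruns the seven-test panel, and applies a per-group FDR.
#' Each group SMP is annotated with whether the main analysis also called
#' it.
#'
#' @param alignment the full `smp_alignment`.
#' @param dataset the full `smp_mutations` data frame.
#' @param members character vector of the group's gene ids.
#' @param sequences named full protein sequences.
#' @param scores,distances optional inputs as in [smp_scan()].
#' @param control an [smp_control()] list.
#' @param main_smps optional integer vector of SMP columns from the main
#'   analysis for the `in_main` annotation.
#' @return an `smp_scan` object whose `smps` gain an `in_main` column.
#' @export
run_group_analysis <- function(alignment, dataset, members, sequences,
                               scores = NULL, distances = NULL,
                               control = smp_control(), main_smps = NULL) {
  sub_aln <- subset_alignment(alignment, members)
  sub <- dataset[dataset$gene %in% members, , drop = FALSE]
  if (!any(!sub$in_domain))
    stop("group has no non-domain mutations; background undefinable")
  fit <- smp_scan(sub_aln, sub, sequences[sub_aln$genes],
                  if (!is.null(scores)) scores[sub_aln$genes] else NULL,
                  if (!is.null(distances))
                    distances[sub_aln$genes, sub_aln$genes] else NULL,
                  control)
  if (nrow(fit$smps))
    fit$smps$in_main <- fit$smps$column %in% (main_smps %||% integer(0))
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scan every eligible group
#'
#' @inheritParams run_group_analysis
#' @param groups data frame `gene`, `group`.
#' @param ... thresholds passed to [eligible_groups()].
#' @return named list of per-group `smp_scan` objects.
#' @export
run_groups <- function(alignment, dataset, groups, sequences, scores = NULL,
                       distances = NULL, control = smp_control(),
                       main_smps = NULL, ...) {
  elig <- eligible_groups(groups, dataset, alignment, ...)
  res <- lapply(seq_len(nrow(elig)), function(i)
    run_group_analysis(alignment, dataset, elig$members[[i]], sequences,
                       scores, distances, control, main_smps))
  names(res) <- elig$group
  res
}
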