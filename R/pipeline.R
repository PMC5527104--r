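#' End-to-end pipeline over input files
#'
#' Reads every input, runs [smp_scan()] (and optionally the per-group
#' re-analysis), and writes a results bundle: the per-column test table, the
#' combined/FDR table, the SMP report, the background model, and an echo of
#' the configuration.  Counts of filtered records are logged with
#' `message()`.
#'
#' @param alignment_file aligned FASTA of domain sequences.
#' @param mutation_file mutation TSV
#'   (`gene pos ref var patient cancer_type silent source`).
#' @param sequence_file FASTA of full protein sequences.
#' @param domain_file TSV `gene start end` of domain coordinates (optional
#'   when domains start at position 1).
#' @param tree_file optional Newick guide tree (enables Gene Relatedness).
#' @param score_file optional TSV `gene score` (enables Cancer Genes).
#' @param group_file optional TSV `gene group` (enables the group analysis).
#' @param out_dir directory for outputs.
#' @param control an [smp_control()] list.
#' @param run_groups_analysis run the per-group scans when `group_file` is
#'   given.
#' @return the main `smp_scan` object, invisibly; outputs on disk.
#' @export
run_pipeline <- function(alignment_file, mutation_file, sequence_file,
                         domain_file = NULL, tree_file = NULL,
                         score_file = NULL, group_file = NULL,
                         out_dir = "smpscan_results",
                         control = smp_control(),
                         run_groups_analysis = !is.null(group_file)) {
  coords <- if (!is.null(domain_file)) read_domain_coords(domain_file)
  alignment <- read_alignment(alignment_file, coords)
  sequences <- read_protein_sequences(sequence_file)
  mutations <- read_mutations(mutation_file, alignment, sequences)
  message(nrow(mutations), " mutations retained; ",
          sum(mutations$in_domain), " map to the aligned domains")
  scores <- if (!is.null(score_file)) read_gene_scores(score_file)
  distances <- if (!is.null(tree_file)) read_newick_distances(tree_file)

  fit <- smp_scan(alignment, mutations, sequences, scores, distances,
                  control)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(fit$tests, "position_tests.tsv")
  tsv(fit$combined, "combined.tsv")
  tsv(report(fit, alignment), "smps.tsv")
  write_background_json(fit$background, file.path(out_dir,
                                                  "background.json"))
  jsonlite::write_json(
    list(B = fit$control$B, alpha = fit$control$alpha,
         q_threshold = fit$control$q_threshold,
         min_genes = fit$control$min_genes, seed = fit$control$seed),
    file.path(out_dir, "config.json"), auto_unbox = TRUE)

  if (run_groups_analysis && !is.null(group_file)) {
    groups <- read_gene_groups(group_file)
    gres <- run_groups(alignment, mutations, groups, sequences, scores,
                       distances, control, main_smps = fit$smps$column)
    for (g in names(gres))
      if (nrow(gres[[g]]$smps))
        tsv(gres[[g]]$smps, paste0("group_", g, "_smps.tsv"))
    summary_rows <- do.call(rbind, lapply(names(gres), function(g)
      data.frame(group = g, n_tested = nrow(gres[[g]]$tests),
                 n_smps = nrow(gres[[g]]$smps),
                 n_new = if (nrow(gres[[g]]$smps))
                   sum(!gres[[g]]$smps$in_main) else 0L)))
    if (!is.null(summary_rows)) tsv(summary_rows, "group_summary.tsv")
  }
  invisible(fit)
}

#' Human-readable SMP report
#'
#' One row per SMP: aligned column, FDR, the corresponding residue and
#' protein position in each mutated gene (from the coordinate map), and
#' summary counts.
#'
#' @param fit an `smp_scan`.
#' @param alignment the `smp_alignment` the scan was run on.
#' @param max_genes cap on the per-gene residue listing per row.
#' @return data frame with one row per SMP (zero rows if none).
#' @export
report <- function(fit, alignment, max_genes = 10) {
  smps <- fit$smps
  if (nrow(smps) == 0)
    return(data.frame(column = integer(), q = numeric(),
                      n_mutations = integer(), n_mutated_genes = integer(),
                      residues = character()))
  tests <- fit$tests
  rows <- lapply(seq_len(nrow(smps)), function(i) {
    a <- smps$column[i]
    ti <- tests[tests$column == a, ]
    ch <- fit$characterization$per_column
    ch <- ch[ch$column == a, ]
    res <- aligned_residues(alignment, a)
    dom_pos <- alignment$col_to_pos[names(res), a]
    shown <- head(seq_along(res), max_genes)
    data.frame(column = a, q = smps$q[i],
               n_mutations = ti$n_mutations,
               n_mutated_genes = ti$n_mutated_genes,
               n_aligned = ti$n_aligned,
               entropy = ch$entropy,
               residues = paste0(names(res)[shown], ":", res[shown],
                                 dom_pos[shown], collapse = ","))
  })
  do.call(rbind, rows)
}
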