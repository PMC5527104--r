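#' Read ungapped protein sequences
#'
#' @param path FASTA file of full-length protein sequences (no gaps).
#' @return named character vector of sequences.
#' @export
read_protein_sequences <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Read per-gene domain coordinates
#'
#' @param path TSV with header `gene start end`; 1-based inclusive protein
#'   coordinates of the aligned domain within each gene.
#' @return data frame with columns `gene`, `start`, `end`.
#' @export
read_domain_coords <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "start", "end") %in% names(x)))
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  if (anyNA(x$start) || anyNA(x$end) || any(x$end < x$start))
    stop("malformed domain coordinates")
  x
}

#' Read a per-gene cancer-likelihood score table
#'
#' Smaller scores indicate genes more likely to be cancer-related; the Cancer
#' Genes test asks whether mutated genes at a column have smaller scores than
#' expected.
#'
#' @param path TSV with header `gene score`.
#' @return named numeric vector of scores.
#' @export
read_gene_scores <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "score") %in% names(x)))
  s <- as.numeric(x$score)
  if (anyNA(s) || any(!is.finite(s))) stop("non-finite gene scores")
  setNames(s, x$gene)
}

#' Read per-gene group labels
#'
#' @param path TSV with header `gene group` (e.g. UniProt kinase groups).
#' @return data frame with columns `gene`, `group`.
#' @export
read_gene_groups <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "group") %in% names(x)))
  x[c("gene", "group")]
}

#' Read and validate a somatic point-mutation table
#'
#' Reads a TSV of missense and silent point mutations, removes duplicates
#' (identical records reported by multiple sources collapse to one), assigns
#' the reserved `"missing/other"` cancer-type label to unannotated records,
#' checks reference residues against the supplied protein sequences (with an
#' optional isoform-offset reconciliation step), and maps each record onto the
#' alignment, flagging records inside the aligned domain.
#'
#' @param path TSV with header
#'   `gene pos ref var patient cancer_type silent source` (`silent` and
#'   `source` optional; `silent` is derived from `ref == var` when absent).
#' @param alignment an `smp_alignment` (with domain coordinates attached if
#'   the domains do not start at protein position 1).
#' @param sequences optional named character vector of full protein sequences
#'   used to validate reference residues; mismatching records are dropped
#'   with a message.
#' @param isoform_offsets optional data frame `gene offset` of candidate
#'   alternative position offsets; for each gene the offset conserving the
#'   most mutations is chosen before mismatches are dropped.
#' @return a data frame of class `smp_mutations` with columns `gene`, `pos`,
#'   `ref`, `var`, `patient`, `cancer_type`, `silent`, `in_domain`, `column`.
#' @export
read_mutations <- function(path, alignment, sequences = NULL,
                           isoform_offsets = NULL) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = "character")
  req <- c("gene", "pos", "ref", "var", "patient")
  if (!all(req %in% names(x)))
    stop("mutation table must have columns: ", paste(req, collapse = ", "))
  pos <- suppressWarnings(as.integer(x$pos))
  if (anyNA(pos)) stop("malformed protein position in mutation table: '",
                       x$pos[which(is.na(pos))[1]], "'")
  x$pos <- pos
  if (is.null(x$cancer_type)) x$cancer_type <- NA_character_
  x$cancer_type[is.na(x$cancer_type) | x$cancer_type == ""] <- MISSING_LABEL
  x$ref <- toupper(x$ref); x$var <- toupper(x$var)
  bad_aa <- !(x$ref %in% AA20) | !(x$var %in% AA20)
  if (any(bad_aa)) {
    warning(sum(bad_aa), " record(s) with non-standard residues skipped")
    x <- x[!bad_aa, , drop = FALSE]
  }
  x$silent <- x$ref == x$var

  unknown <- !(x$gene %in% alignment$genes)
  if (any(unknown)) {
    warning(sum(unknown), " record(s) in genes absent from the alignment ",
            "skipped: ", paste(unique(x$gene[unknown])[1:min(5, sum(unknown))],
                               collapse = ", "))
    x <- x[!unknown, , drop = FALSE]
  }

  # duplicates: identical on all substantive fields (source may differ)
  key <- c("gene", "pos", "ref", "var", "patient", "cancer_type")
  x <- x[!duplicated(x[key]), , drop = FALSE]

  # isoform reconciliation: pick the per-gene offset conserving the most
  # mutations, then drop remaining reference-residue mismatches
  if (!is.null(sequences)) {
    off <- setNames(rep(0L, length(unique(x$gene))), unique(x$gene))
    if (!is.null(isoform_offsets)) {
      for (g in intersect(names(off), isoform_offsets$gene)) {
        cand <- unique(c(0L, as.integer(
          isoform_offsets$offset[isoform_offsets$gene == g])))
        rows <- which(x$gene == g)
        hits <- vapply(cand, function(o) {
          p <- x$pos[rows] + o
          ok <- p >= 1 & p <= nchar(sequences[[g]])
          sum(ok & substring(sequences[[g]], p, p) == x$ref[rows])
        }, integer(1))
        off[[g]] <- cand[which.max(hits)]
      }
    }
    p_adj <- x$pos + off[x$gene]
    in_seq <- !is.na(match(x$gene, names(sequences)))
    ok <- in_seq & p_adj >= 1 &
      p_adj <= nchar(sequences)[match(x$gene, names(sequences))]
    ok[ok] <- substring(sequences[x$gene[ok]], p_adj[ok], p_adj[ok]) ==
      x$ref[ok]
    if (any(!ok))
      message(sum(!ok), " record(s) dropped: reference residue does not ",
              "match the chosen isoform sequence")
    x <- x[ok, , drop = FALSE]
    x$pos <- p_adj[ok]
  }

  col <- rep(NA_integer_, nrow(x))
  for (g in unique(x$gene)) {
    rows <- which(x$gene == g)
    col[rows] <- position_to_column(alignment, g, x$pos[rows])
  }
  x$in_domain <- !is.na(col)
  x$column <- col
  out <- x[c("gene", "pos", "ref", "var", "patient", "cancer_type",
             "silent", "in_domain", "column")]
  rownames(out) <- NULL
  class(out) <- c("smp_mutations", "data.frame")
  out
}

#' Collapse mutation records at a column to events
#'
#' Recurrent mutations are handled at three levels. `"mutation"` keeps every
#' record (recurrent events are non-redundant); `"residue"` treats identical
#' amino-acid substitutions as one event (e.g. a K>E change seen in 48
#' patients counts once); `"gene"` treats all mutations of one gene at the
#' column as one event (two different substitutions of the same residue in
#' one gene count once).
#'
#' @param dataset an `smp_mutations` data frame.
#' @param level one of `"mutation"`, `"residue"`, `"gene"`.
#' @param column alignment column to collapse at.
#' @return data frame of events (subset of rows of `dataset`).
#' @export
collapse_events <- function(dataset, level = c("mutation", "residue", "gene"),
                            column) {
  level <- match.arg(level)
  d <- dataset[dataset$in_domain & !is.na(dataset$column) &
                 dataset$column == column, , drop = FALSE]
  if (nrow(d) == 0 || level == "mutation") return(d)
  key <- switch(level,
                residue = paste(d$gene, d$pos, d$ref, d$var),
                gene    = d$gene)
  d[!duplicated(key), , drop = FALSE]
}

#' Per-column counting profile
#'
#' Collects every count the seven tests consume at one alignment column:
#' aligned residue composition, mutation totals, event tables at the given
#' collapse level, and the identities of mutated genes.
#'
#' @inheritParams collapse_events
#' @param alignment an `smp_alignment`.
#' @return a list of class `smp_profile` with elements `column`, `aligned`
#'   (named residues of the genes aligned at the column), `R_ar`
#'   (named residue counts among aligned genes), `n_aligned`, `N_a` (total
#'   mutation count at the column), `events` (collapsed event rows), `O_ar`,
#'   `O_av` (event counts by reference / variant residue type), `O_patient`,
#'   `O_cancer_type` (mutation-level label counts), `mutated_genes` (named
#'   character: gene -> its aligned residue), `n_mutated_genes`, and
#'   `collapse_level`.
#' @export
column_profile <- function(alignment, dataset, column,
                           level = c("mutation", "residue", "gene")) {
  level <- match.arg(level)
  res <- aligned_residues(alignment, column)
  R_ar <- table(factor(res, levels = AA20))
  R_ar <- setNames(as.integer(R_ar), AA20)

  muts <- collapse_events(dataset, "mutation", column)
  events <- collapse_events(dataset, level, column)
  gene_ev <- collapse_events(dataset, "gene", column)
  mg <- setNames(res[match(gene_ev$gene, names(res))], gene_ev$gene)

  structure(
    list(column = column,
         aligned = res,
         R_ar = R_ar,
         n_aligned = length(res),
         N_a = nrow(muts),
         events = events,
         O_ar = c(table(factor(events$ref, levels = AA20))),
         O_av = c(table(factor(events$var, levels = AA20))),
         O_patient = table(muts$patient),
         O_cancer_type = table(muts$cancer_type),
         mutated_genes = mg,
         n_mutated_genes = nrow(gene_ev),
         collapse_level = level),
    class = "smp_profile")
}
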