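#' Construct an alignment object from a character matrix
#'
#' Internal constructor shared by [read_alignment()] and the synthetic
#' generator.  Rows are domain sequences (one per gene), columns are alignment
#' columns; gaps are `"-"`.
#'
#' @param mat character matrix (genes x columns) of single residues/gaps.
#' @param domain_start named integer vector: 1-based protein position of the
#'   first domain residue per gene (default 1 for every gene).
#' @return an object of class `smp_alignment`.
#' @keywords internal
new_alignment <- function(mat, domain_start = NULL) {
  genes <- rownames(mat)
  if (is.null(genes) || anyDuplicated(genes))
    stop("alignment records must carry unique gene identifiers")
  if (is.null(domain_start)) {
    domain_start <- setNames(rep(1L, nrow(mat)), genes)
  }
  domain_start <- domain_start[genes]
  if (anyNA(domain_start))
    stop("domain coordinates missing for: ",
         paste(genes[is.na(domain_start)], collapse = ", "))

  # protein position per (gene, column); NA at gaps
  nongap <- mat != "-"
  col_to_pos <- matrix(NA_integer_, nrow(mat), ncol(mat),
                       dimnames = list(genes, NULL))
  for (i in seq_len(nrow(mat))) {
    idx <- which(nongap[i, ])
    col_to_pos[i, idx] <- domain_start[[i]] + seq_along(idx) - 1L
  }
  n_res <- rowSums(nongap)
  structure(
    list(genes = genes,
         n_columns = ncol(mat),
         mat = mat,
         col_to_pos = col_to_pos,
         domain_start = domain_start,
         domain_end = setNames(as.integer(domain_start + n_res - 1L), genes)),
    class = "smp_alignment")
}

#' Read a multiple sequence alignment of domain sequences
#'
#' Reads an aligned FASTA file (gap characters `-` and `.`, the latter
#' normalized to `-`) and builds the bidirectional mapping between
#' `(gene, protein position)` and alignment column that every downstream test
#' relies on.  Protein positions are 1-based; alignment columns are 1-based.
#'
#' @param path path to an aligned FASTA file.
#' @param domain_coords optional data frame with columns `gene`, `start`,
#'   `end` giving the 1-based inclusive protein coordinates of each gene's
#'   domain.  When omitted, each domain is assumed to start at protein
#'   position 1.
#' @return an object of class `smp_alignment` with elements `genes`,
#'   `n_columns`, `mat` (character matrix), `col_to_pos`, `domain_start`,
#'   `domain_end`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "AC-D", ">g2", "ACED"), fa)
#' aln <- read_alignment(fa)
#' aln$n_columns
#' position_to_column(aln, "g1", 3)  # D sits in column 4
#' @export
read_alignment <- function(path, domain_coords = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stop("cannot parse FASTA: ",
                                            conditionMessage(e)))
  if (length(seqs) == 0) stop("empty alignment file: ", path)
  if (length(seqs) < 2) stop("an alignment needs at least 2 records")
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1) {
    bad <- names(seqs)[w != w[1]][1]
    stop("ragged alignment: record '", bad, "' has length ", w[w != w[1]][1],
         ", expected ", w[1])
  }
  chars <- toupper(as.character(seqs))
  chars <- gsub(".", "-", chars, fixed = TRUE)
  mat <- do.call(rbind, strsplit(chars, "", fixed = TRUE))
  rownames(mat) <- sub("\\s.*$", "", names(seqs))

  domain_start <- NULL
  if (!is.null(domain_coords)) {
    stopifnot(all(c("gene", "start", "end") %in% names(domain_coords)))
    domain_start <- setNames(as.integer(domain_coords$start),
                             domain_coords$gene)
    # sanity: declared span must match the number of non-gap residues
    n_res <- rowSums(mat != "-")
    span <- setNames(as.integer(domain_coords$end - domain_coords$start + 1L),
                     domain_coords$gene)
    common <- intersect(names(span), rownames(mat))
    off <- common[span[common] != n_res[common]]
    if (length(off))
      stop("domain coordinates disagree with ungapped length for: ",
           paste(off, collapse = ", "))
  }
  new_alignment(mat, domain_start)
}

#' Map protein positions to alignment columns
#'
#' @param alignment an `smp_alignment`.
#' @param gene a single gene id.
#' @param pos integer vector of 1-based protein positions.
#' @return integer vector of 1-based columns; `NA` where the position falls
#'   outside the aligned domain.
#' @export
position_to_column <- function(alignment, gene, pos) {
  if (!gene %in% alignment$genes) return(rep(NA_integer_, length(pos)))
  match(pos, alignment$col_to_pos[gene, ])
}

#' Map alignment columns back to protein positions
#'
#' @inheritParams position_to_column
#' @param column integer vector of 1-based columns.
#' @return integer vector of protein positions; `NA` at gaps.
#' @export
column_to_position <- function(alignment, gene, column) {
  unname(alignment$col_to_pos[gene, column])
}

#' Residues aligned at a column
#'
#' @inheritParams position_to_column
#' @param column a single column index.
#' @return named character vector of residues for genes with a non-gap
#'   residue at the column.
#' @export
aligned_residues <- function(alignment, column) {
  res <- alignment$mat[, column]
  res[res != "-"]
}

#' Shannon entropy of an alignment column
#'
#' Entropy of the amino-acid frequency distribution over the non-gap residues
#' at a column.  Defaults to natural log (nats), so the maximum over 20 amino
#' acids is `ln 20 ~ 3.0`; the base is configurable.
#'
#' @inheritParams aligned_residues
#' @param base logarithm base (default `exp(1)`).
#' @return entropy in units of `log(base)`; `NA` for an all-gap column.
#' @export
column_entropy <- function(alignment, column, base = exp(1)) {
  res <- aligned_residues(alignment, column)
  if (length(res) == 0) return(NA_real_)
  p <- tabulate(factor(res, levels = unique(res)))
  p <- p / sum(p)
  -sum(p * log(p)) / log(base)
}

#' Restrict an alignment to a subset of genes
#'
#' Used by the per-group analysis; columns are kept (so column numbering is
#' shared with the full alignment), only rows are dropped.
#'
#' @inheritParams position_to_column
#' @param genes character vector of gene ids to keep.
#' @return an `smp_alignment` over the subset.
#' @export
subset_alignment <- function(alignment, genes) {
  keep <- intersect(alignment$genes, genes)
  if (length(keep) < 2) stop("fewer than 2 genes left after subsetting")
  new_alignment(alignment$mat[keep, , drop = FALSE],
                alignment$domain_start[keep])
}

#' @export
print.smp_alignment <- function(x, ...) {
  cat("Domain family alignment: ", length(x$genes), " sequences x ",
      x$n_columns, " columns\n", sep = "")
  occ <- colSums(x$mat != "-")
  cat("  mean aligned sequences per column: ", round(mean(occ), 1), "\n",
      sep = "")
  invisible(x)
}
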