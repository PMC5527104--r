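default_residue_factors <- function() {
  # modest, fixed non-uniformity in per-residue-type mutability so that
  # background-rate recovery is a non-trivial check
  setNames(exp(seq(-0.35, 0.35, length.out = 20)), AA20)
}

# amino acids reachable from each amino acid by a single-nucleotide codon
# change (standard genetic code, stops excluded), weighted by the number of
# codon paths
codon_neighbor_weights <- function() {
  bases <- c("T", "C", "A", "G")
  aa_tab <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
    AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
    CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  W <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  for (cod in names(aa_tab)) {
    aa <- aa_tab[[cod]]
    if (aa == "*") next
    for (i in 1:3) for (b in setdiff(bases, substr(cod, i, i))) {
      mut <- cod
      substr(mut, i, i) <- b
      aa2 <- aa_tab[[mut]]
      if (aa2 != "*") W[aa, aa2] <- W[aa, aa2] + 1
    }
  }
  W
}

default_spectrum <- function(silent_mass = 0.23, floor_mass = 0.02) {
  # somatic point mutations are single-nucleotide events, so the reachable
  # variant set per reference residue is sparse and genetic-code determined;
  # the silent fraction sits on the diagonal and a small floor spreads over
  # all variants (multi-nucleotide events are rare but observed)
  W <- codon_neighbor_weights()
  diag(W) <- 0
  P <- matrix(floor_mass / 19, 20, 20, dimnames = list(AA20, AA20))
  diag(P) <- 0
  P <- P + W / rowSums(W) * (1 - silent_mass - floor_mass)
  diag(P) <- silent_mass
  P
}

#' Declare a planted effect at an alignment column
#'
#' @param column alignment column (1-based) to plant at.
#' @param fold mutation-rate fold enrichment (>= 1; 1 means counts are not
#'   enriched).
#' @param variant optional single residue: variants at the column are forced
#'   to this amino acid (a variant-spectrum bias at matched counts).
#' @param genes optional character vector restricting the effect to a gene
#'   subset (default: all genes aligned at the column).
#' @param score_shift optional additive shift applied to the scores of
#'   `genes` (negative = more cancer-like).
#' @return a list describing the planted effect.
#' @export
plant <- function(column, fold = 1, variant = NULL, genes = NULL,
                  score_shift = 0) {
  stopifnot(fold >= 1, length(column) == 1)
  if (!is.null(variant)) stopifnot(variant %in% AA20)
  list(column = as.integer(column), fold = fold, variant = variant,
       genes = genes, score_shift = score_shift)
}

#' Configuration for the synthetic domain-family generator
#'
#' Defaults emulate a mid-sized homologous domain family: 200 genes sharing a
#' 300-column domain alignment, with 300 flanking non-domain residues on each
#' side so that roughly one third of mutations fall inside the domain (the
#' typical proportion when a ~300-residue domain sits in a ~900-residue
#' protein); ~400 patients with lognormal mutation burdens spread over 8
#' cancer types; mildly non-uniform per-residue mutability; and a
#' genetic-code-aware substitution spectrum (single-nucleotide reachability,
#' 23% silent mass on the diagonal).  At these settings the expected catalog
#' is roughly 5,000 point mutations.
#'
#' @param n_genes number of genes (domain sequences).
#' @param domain_length alignment columns.
#' @param flank_length non-domain residues on EACH side of the domain.
#' @param n_patients number of patients.
#' @param baseline_rate per-residue, per-patient mutation probability.
#' @param conservation Dirichlet concentration of per-column residue
#'   frequency profiles (small = conserved columns).
#' @param tree_scale multiplier on branch lengths after normalizing the mean
#'   root-to-tip depth to 1; `0` collapses the tree so all sequences are
#'   identical.
#' @param gaps if `TRUE`, columns receive random per-gene gap masks with
#'   occupancy drawn from `gap_occupancy`, emulating the very uneven column
#'   occupancy of real domain alignments; if `FALSE` (default) the alignment
#'   is gap-free and column truth is unambiguous.
#' @param gap_occupancy range of per-column occupancy when `gaps = TRUE`.
#' @param residue_factors named per-residue-type mutability multipliers.
#' @param spectrum 20x20 row-stochastic substitution matrix (diagonal =
#'   silent mass).
#' @param patient_burden `c(meanlog, sdlog)` of the lognormal patient
#'   mutation-burden weights.
#' @param cancer_type_props named proportions of patients per cancer type.
#' @param n_groups,group_props gene-group labels and their proportions.
#' @param planted list of [plant()] effects.
#' @param seed RNG seed; the whole bundle is deterministic given the config.
#' @return a list of class `smp_sim_config`.
#' @export
smp_sim_config <- function(n_genes = 200, domain_length = 300,
                           flank_length = 300, n_patients = 400,
                           baseline_rate = 7e-5, conservation = 0.2,
                           tree_scale = 1, gaps = FALSE,
                           gap_occupancy = c(0.3, 1),
                           residue_factors = default_residue_factors(),
                           spectrum = default_spectrum(),
                           patient_burden = c(meanlog = 0, sdlog = 1),
                           cancer_type_props = c(CRC = 0.25, LUAD = 0.20,
                                                 BRCA = 0.15, SKCM = 0.12,
                                                 GBM = 0.10, HNSC = 0.08,
                                                 PRAD = 0.06, OV = 0.04),
                           n_groups = 5,
                           group_props = c(0.3, 0.25, 0.2, 0.15, 0.1),
                           planted = list(), seed = 1) {
  stopifnot(n_genes >= 2, domain_length >= 1, flank_length >= 0,
            n_patients >= 1, baseline_rate > 0, conservation > 0,
            tree_scale >= 0,
            abs(sum(cancer_type_props) - 1) < 1e-8,
            abs(sum(group_props) - 1) < 1e-8,
            all(abs(rowSums(spectrum) - 1) < 1e-8))
  for (pl in planted)
    if (pl$column > domain_length)
      stop("planted column ", pl$column, " exceeds domain_length")
  structure(as.list(environment()), class = "smp_sim_config")
}

#' Simulate a domain family (alignment, tree, scores, groups)
#'
#' Sequences are evolved down a random tree with a simple per-column
#' substitution process: each column has its own residue-frequency profile
#' (Dirichlet draw), the root is sampled from it, and along each branch a
#' site substitutes with probability `1 - exp(-t)` to a fresh draw from the
#' column profile.  Flanking non-domain sequence (uniform composition) is
#' appended on both sides.  No indel process; optional random gap masks.
#'
#' @param config an `smp_sim_config`.
#' @return a list of class `smp_family`: `alignment` (an `smp_alignment`),
#'   `sequences` (full proteins), `tree` (phylo), `distances` (patristic
#'   matrix), `scores`, `groups` (data frame), `domain_coords`, `truth`
#'   (true `E_r`, `P_rv`, column profiles, planted effects), `config`.
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "smp_sim_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    L <- config$domain_length
    genes <- sprintf("G%04d", seq_len(n))

    tree <- ape::rtree(n, tip.label = genes)
    # scale to mean root-to-tip depth 1 so substitution saturation is mild
    depth <- ape::node.depth.edgelength(tree)[seq_len(n)]
    tree$edge.length <- tree$edge.length / mean(depth) * config$tree_scale

    # per-column residue profiles
    prof <- matrix(rgamma(20 * L, shape = config$conservation), 20, L)
    prof <- sweep(prof, 2, colSums(prof), "/")

    # evolve down the tree, preorder
    n_nodes <- n + tree$Nnode
    seqs <- matrix(NA_character_, n_nodes, L)
    root <- n + 1L
    seqs[root, ] <- vapply(seq_len(L),
                           function(j) sample(AA20, 1, prob = prof[, j]),
                           character(1))
    edges <- reorder(tree, "cladewise")$edge
    elen <- reorder(tree, "cladewise")$edge.length
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1]; child <- edges[e, 2]
      s <- seqs[par, ]
      hit <- which(runif(L) < 1 - exp(-elen[e]))
      if (length(hit))
        s[hit] <- vapply(hit,
                         function(j) sample(AA20, 1, prob = prof[, j]),
                         character(1))
      seqs[child, ] <- s
    }
    mat <- seqs[seq_len(n), , drop = FALSE]
    rownames(mat) <- genes

    if (config$gaps) {
      occ <- runif(L, config$gap_occupancy[1], config$gap_occupancy[2])
      gap <- matrix(runif(n * L), n, L) > rep(occ, each = n)
      # keep every gene anchored with a minimum of aligned columns
      for (i in which(rowSums(!gap) < 10))
        gap[i, sample.int(L, 10)] <- FALSE
      mat[gap] <- "-"
    }

    fl <- config$flank_length
    sequences <- setNames(vapply(seq_len(n), function(i) {
      dom <- mat[i, mat[i, ] != "-"]
      paste0(paste(sample(AA20, fl, replace = TRUE), collapse = ""),
             paste(dom, collapse = ""),
             paste(sample(AA20, fl, replace = TRUE), collapse = ""))
    }, character(1)), genes)

    domain_start <- setNames(rep(fl + 1L, n), genes)
    alignment <- new_alignment(mat, domain_start)

    scores <- setNames(rnorm(n), genes)
    for (pl in config$planted)
      if (!is.null(pl$genes) && pl$score_shift != 0)
        scores[pl$genes] <- scores[pl$genes] + pl$score_shift

    groups <- data.frame(
      gene = genes,
      group = sample(paste0("GRP", seq_len(config$n_groups)), n,
                     replace = TRUE, prob = config$group_props))

    structure(
      list(alignment = alignment, sequences = sequences, tree = tree,
           distances = ape::cophenetic.phylo(tree)[genes, genes],
           scores = scores, groups = groups,
           domain_coords = data.frame(gene = genes, start = domain_start,
                                      end = alignment$domain_end,
                                      row.names = NULL),
           truth = list(
             E_r = config$baseline_rate * config$residue_factors *
               config$n_patients,
             P_rv = config$spectrum,
             column_profiles = prof,
             planted = config$planted),
           config = config),
      class = "smp_family")
  })
}

#' Simulate a somatic point-mutation catalog for a family
#'
#' Every residue of every gene (domain and flanks) mutates independently:
#' the per-site Poisson mean is `baseline_rate x residue factor x planted
#' fold x total patient burden`.  Each mutation is assigned to a patient
#' with probability proportional to the patient's lognormal burden weight
#' and inherits that patient's cancer type; the variant residue is drawn
#' from the spectrum row of the reference (silent when the draw lands on the
#' diagonal), or forced to the planted variant at biased columns.
#'
#' @param family an `smp_family`.
#' @param config the `smp_sim_config` used to build it.
#' @return a list with `mutations` (an `smp_mutations` data frame) and
#'   `truth` (expected total count and per-site rate summaries).
#' @export
simulate_mutations <- function(family, config) {
  aln <- family$alignment
  with_seed(config$seed + 1L, {
    np <- config$n_patients
    w <- stats::rlnorm(np, config$patient_burden[["meanlog"]],
                       config$patient_burden[["sdlog"]])
    w <- w / sum(w) * np
    patients <- sprintf("P%05d", seq_len(np))
    pat_type <- sample(names(config$cancer_type_props), np, replace = TRUE,
                       prob = config$cancer_type_props)

    # long site table over all genes
    gene_v <- character(0); pos_v <- integer(0); res_v <- character(0)
    fold_v <- numeric(0); bias_v <- character(0); dom_v <- logical(0)
    for (g in family$alignment$genes) {
      s <- strsplit(family$sequences[[g]], "", fixed = TRUE)[[1]]
      fold <- rep(1, length(s))
      bias <- rep(NA_character_, length(s))
      in_dom <- seq_along(s) >= aln$domain_start[[g]] &
        seq_along(s) <= aln$domain_end[[g]]
      for (pl in config$planted) {
        if (!is.null(pl$genes) && !(g %in% pl$genes)) next
        p <- column_to_position(aln, g, pl$column)
        if (is.na(p)) next
        fold[p] <- fold[p] * pl$fold
        if (!is.null(pl$variant)) bias[p] <- pl$variant
      }
      gene_v <- c(gene_v, rep(g, length(s)))
      pos_v <- c(pos_v, seq_along(s))
      res_v <- c(res_v, s)
      fold_v <- c(fold_v, fold)
      bias_v <- c(bias_v, bias)
      dom_v <- c(dom_v, in_dom)
    }
    lambda <- config$baseline_rate * config$residue_factors[res_v] *
      fold_v * np
    counts <- rpois(length(lambda), lambda)
    idx <- rep.int(seq_along(counts), counts)
    n_mut <- length(idx)

    ref <- res_v[idx]
    var <- character(n_mut)
    for (r in unique(ref)) {
      at <- which(ref == r)
      var[at] <- sample(AA20, length(at), replace = TRUE,
                        prob = config$spectrum[r, ])
    }
    biased <- !is.na(bias_v[idx])
    var[biased] <- bias_v[idx][biased]

    pat_idx <- sample.int(np, n_mut, replace = TRUE, prob = w)
    d <- data.frame(gene = gene_v[idx], pos = pos_v[idx], ref = ref,
                    var = var, patient = patients[pat_idx],
                    cancer_type = pat_type[pat_idx],
                    silent = ref == var, stringsAsFactors = FALSE)
    col <- rep(NA_integer_, n_mut)
    for (g in unique(d$gene)) {
      rows <- which(d$gene == g)
      col[rows] <- position_to_column(aln, g, d$pos[rows])
    }
    d$in_domain <- !is.na(col)
    d$column <- col
    class(d) <- c("smp_mutations", "data.frame")
    list(mutations = d,
         truth = list(expected_total = sum(lambda),
                      expected_nondomain = sum(lambda[!dom_v])))
  })
}

#' Simulate a complete analysis bundle
#'
#' Runs [simulate_family()] and [simulate_mutations()] and optionally writes
#' every input file in exactly the dialects the readers consume (aligned
#' FASTA, protein FASTA, mutation TSV, Newick tree, score/group/coordinate
#' TSVs, truth JSON).
#'
#' @param config an `smp_sim_config`.
#' @param dir optional directory to write the file bundle into.
#' @return list with `family`, `mutations`, `truth`, and (when `dir` is
#'   given) `paths`.
#' @export
simulate_smp_data <- function(config, dir = NULL) {
  family <- simulate_family(config)
  sim <- simulate_mutations(family, config)
  out <- list(family = family, mutations = sim$mutations,
              truth = c(family$truth, sim$truth))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      alignment = file.path(dir, "alignment.fasta"),
      proteins = file.path(dir, "proteins.fasta"),
      mutations = file.path(dir, "mutations.tsv"),
      tree = file.path(dir, "tree.nwk"),
      scores = file.path(dir, "scores.tsv"),
      groups = file.path(dir, "groups.tsv"),
      domain_coords = file.path(dir, "domain_coords.tsv"),
      truth = file.path(dir, "truth.json"))
    aln <- family$alignment
    writeLines(as.vector(rbind(paste0(">", aln$genes),
                               apply(aln$mat, 1, paste, collapse = ""))),
               paths$alignment)
    writeLines(as.vector(rbind(paste0(">", names(family$sequences)),
                               unname(family$sequences))),
               paths$proteins)
    m <- sim$mutations
    write.table(data.frame(gene = m$gene, pos = m$pos, ref = m$ref,
                           var = m$var, patient = m$patient,
                           cancer_type = m$cancer_type,
                           silent = m$silent, source = "sim"),
                paths$mutations, sep = "\t", quote = FALSE,
                row.names = FALSE)
    ape::write.tree(family$tree, paths$tree)
    write.table(data.frame(gene = names(family$scores),
                           score = unname(family$scores)),
                paths$scores, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(family$groups, paths$groups, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(family$domain_coords, paths$domain_coords, sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(E_r = as.list(family$truth$E_r),
           planted = lapply(config$planted, function(pl)
             list(column = pl$column, fold = pl$fold,
                  variant = pl$variant, score_shift = pl$score_shift)),
           expected_total = sim$truth$expected_total),
      paths$truth, auto_unbox = TRUE, digits = NA, na = "null")
    out$paths <- paths
  }
  out
}
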