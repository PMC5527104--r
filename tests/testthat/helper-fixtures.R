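# Fixtures are built in code; oracles here are written independently of the
# implementation paths they check (direct enumeration / path summation).

write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

# A 5-gene hand-made family: gapped alignment, domains offset into longer
# proteins, deterministic.
tiny_family <- function() {
  aln_seqs <- c(g1 = "KRD-A",
                g2 = "KRDEA",
                g3 = "K-DEA",
                g4 = "QRDEA",
                g5 = "KRD--")
  fl <- "GGGG"  # 4-residue flanks both sides
  ungapped <- gsub("-", "", aln_seqs)
  proteins <- setNames(paste0(fl, ungapped, fl), names(aln_seqs))
  coords <- data.frame(gene = names(aln_seqs), start = 5,
                       end = 4 + nchar(ungapped))
  aln_path <- write_fasta(aln_seqs)
  prot_path <- write_fasta(proteins)
  alignment <- read_alignment(aln_path, coords)
  list(alignment = alignment, proteins = proteins, coords = coords,
       aln_path = aln_path, prot_path = prot_path)
}

# Assemble an smp_mutations data frame in memory (maps columns itself).
make_dataset <- function(alignment, gene, pos, ref, var,
                         patient = paste0("p", seq_along(gene)),
                         cancer_type = "T1") {
  d <- data.frame(gene = gene, pos = as.integer(pos), ref = ref, var = var,
                  patient = patient, cancer_type = cancer_type,
                  silent = ref == var, stringsAsFactors = FALSE)
  col <- rep(NA_integer_, nrow(d))
  for (g in unique(d$gene)) {
    rows <- which(d$gene == g)
    col[rows] <- position_to_column(alignment, g, d$pos[rows])
  }
  d$in_domain <- !is.na(col)
  d$column <- col
  class(d) <- c("smp_mutations", "data.frame")
  d
}

# write a mutation TSV in the external dialect
write_mutation_tsv <- function(d, path = tempfile(fileext = ".tsv"),
                               source = "src1") {
  out <- data.frame(gene = d$gene, pos = d$pos, ref = d$ref, var = d$var,
                    patient = d$patient, cancer_type = d$cancer_type,
                    silent = d$silent, source = source)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# ---- oracles -------------------------------------------------------------

# all compositions of m into k non-negative parts
compositions <- function(m, k) {
  if (k == 1) return(matrix(m, 1, 1))
  out <- list()
  for (i in 0:m) {
    rest <- compositions(m - i, k - 1)
    out[[length(out) + 1]] <- cbind(i, rest)
  }
  do.call(rbind, out)
}

# exact P(chi-square stat is at least / at most obs) for counts ~
# multinomial(m, prob), statistic sum((cnt - E)^2 / E)
enum_multinom_chisq_p <- function(m, prob, E, obs, tail = "upper") {
  cnt <- compositions(m, length(prob))
  pr <- apply(cnt, 1, function(x) dmultinom(x, prob = prob))
  stat <- apply(cnt, 1, function(x) sum((x - E)^2 / E))
  if (tail == "upper") sum(pr[stat >= obs - 1e-12])
  else sum(pr[stat <= obs + 1e-12])
}

# exact tail probability for weighted sampling WITHOUT replacement of m items
# (successive sampling, as sample() does), statistic = stat_fun(index set)
enum_wor_p <- function(w, m, stat_fun, obs, tail = "lower") {
  n <- length(w)
  total <- 0
  rec <- function(chosen, remaining, prob) {
    if (length(chosen) == m) {
      s <- stat_fun(chosen)
      hit <- if (tail == "lower") s <= obs + 1e-12 else s >= obs - 1e-12
      if (hit) total <<- total + prob
      return(invisible())
    }
    for (i in remaining)
      rec(c(chosen, i), setdiff(remaining, i),
          prob * w[i] / sum(w[remaining]))
  }
  rec(integer(0), seq_len(n), 1)
  total
}

# patristic distances by explicit path enumeration over the tree's edge list
# (independent of ape::cophenetic)
patristic_oracle <- function(tree) {
  n <- length(tree$tip.label)
  nodes <- n + tree$Nnode
  adj <- vector("list", nodes)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; len <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, len))
    adj[[b]] <- rbind(adj[[b]], c(a, len))
  }
  dist_from <- function(src) {
    d <- rep(NA_real_, nodes); d[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1]; len <- adj[[v]][k, 2]
        if (is.na(d[u])) { d[u] <- d[v] + len; queue <- c(queue, u) }
      }
    }
    d[seq_len(n)]
  }
  D <- t(vapply(seq_len(n), dist_from, numeric(n)))
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

# 3 Monte-Carlo standard errors plus the add-one estimator's bias bound
mc_tol <- function(p, B) 3 * sqrt(p * (1 - p) / B) + 2 / (B + 1)

# Profiles handed to the test functions directly, bypassing alignment
# plumbing, so null behaviour can be controlled exactly.
mk_profile <- function(column = 1, aligned = c(), R_ar = NULL, N_a = 0,
                       O_ar = NULL, O_av = NULL, O_patient = table(character()),
                       O_cancer = table(character()), mutated = c()) {
  zero <- setNames(rep(0L, 20), smpscan:::AA20)
  if (is.null(R_ar)) {
    R_ar <- zero
    if (length(aligned)) {
      tb <- table(aligned)
      R_ar[names(tb)] <- as.integer(tb)
    }
  }
  structure(list(column = column, aligned = aligned, R_ar = R_ar,
                 n_aligned = length(aligned), N_a = N_a, events = NULL,
                 O_ar = if (is.null(O_ar)) zero else O_ar,
                 O_av = if (is.null(O_av)) zero else O_av,
                 O_patient = O_patient, O_cancer_type = O_cancer,
                 mutated_genes = mutated,
                 n_mutated_genes = length(mutated),
                 collapse_level = "residue"),
            class = "smp_profile")
}

counts20 <- function(...) {
  x <- setNames(rep(0L, 20), smpscan:::AA20)
  v <- c(...)
  x[names(v)] <- as.integer(v)
  x
}

mk_model <- function(E_r = NULL, P_rv = NULL, patient_counts = NULL,
                     cancer_counts = NULL, N = NULL) {
  lab <- function(counts) {
    if (is.null(counts)) return(NULL)
    per_label <- as.table(counts)
    classes <- sort(unique(as.integer(counts)))
    N_c <- vapply(classes, function(cc) sum(counts[counts == cc]),
                  numeric(1))
    list(counts = per_label, classes = classes,
         N_c = setNames(N_c, classes), prob = N_c / sum(N_c))
  }
  structure(list(E_r = E_r, P_rv = P_rv, patient = lab(patient_counts),
                 cancer_type = lab(cancer_counts),
                 N = if (is.null(N)) sum(patient_counts) else N),
            class = "smp_background")
}

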