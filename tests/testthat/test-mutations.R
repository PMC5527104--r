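test_that("duplicate records from multiple sources collapse to one", {
  fam <- tiny_family()
  d <- make_dataset(fam$alignment, gene = c("g1", "g1"), pos = c(5, 5),
                    ref = c("K", "K"), var = c("E", "E"),
                    patient = c("p1", "p1"))
  path <- tempfile(fileext = ".tsv")
  write.table(rbind(
    data.frame(gene = "g1", pos = 5, ref = "K", var = "E", patient = "p1",
               cancer_type = "T1", silent = FALSE, source = "A"),
    data.frame(gene = "g1", pos = 5, ref = "K", var = "E", patient = "p1",
               cancer_type = "T1", silent = FALSE, source = "B")),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  ds <- read_mutations(path, fam$alignment, fam$proteins)
  expect_equal(nrow(ds), 1)
  # reading twice yields identical datasets (dedup idempotence)
  ds2 <- read_mutations(path, fam$alignment, fam$proteins)
  expect_identical(ds, ds2)
})

test_that("missing cancer types get the reserved label", {
  fam <- tiny_family()
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tpos\tref\tvar\tpatient\tcancer_type\tsilent\tsource",
               "g1\t5\tK\tE\tp1\t\tFALSE\tA",
               "g2\t6\tR\tQ\tp2\tLUAD\tFALSE\tA"), path)
  ds <- read_mutations(path, fam$alignment, fam$proteins)
  expect_equal(sort(ds$cancer_type), c("LUAD", "missing/other"))
})

test_that("unknown genes are skipped with a warning, bad positions error", {
  fam <- tiny_family()
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tpos\tref\tvar\tpatient\tcancer_type\tsilent\tsource",
               "gX\t5\tK\tE\tp1\tT1\tFALSE\tA",
               "g1\t5\tK\tE\tp1\tT1\tFALSE\tA"), path)
  expect_warning(ds <- read_mutations(path, fam$alignment, fam$proteins),
                 "absent from the alignment")
  expect_equal(ds$gene, "g1")
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tpos\tref\tvar\tpatient\tcancer_type\tsilent\tsource",
               "g1\tfive\tK\tE\tp1\tT1\tFALSE\tA"), bad)
  expect_error(read_mutations(bad, fam$alignment, fam$proteins),
               "malformed")
})

test_that("reference mismatches are dropped; offsets rescue shifted isoforms", {
  fam <- tiny_family()
  path <- tempfile(fileext = ".tsv")
  # g2 domain is KRDEA at protein 5..9; positions below are shifted by +2
  writeLines(c("gene\tpos\tref\tvar\tpatient\tcancer_type\tsilent\tsource",
               "g2\t3\tK\tE\tp1\tT1\tFALSE\tA",
               "g2\t4\tR\tQ\tp2\tT1\tFALSE\tA",
               "g2\t5\tD\tN\tp3\tT1\tFALSE\tA"), path)
  expect_message(ds0 <- read_mutations(path, fam$alignment, fam$proteins),
                 "dropped")
  expect_equal(nrow(ds0), 0)
  ds <- read_mutations(path, fam$alignment, fam$proteins,
                       isoform_offsets = data.frame(gene = "g2", offset = 2))
  expect_equal(nrow(ds), 3)
  expect_equal(ds$pos, c(5L, 6L, 7L))
  expect_true(all(ds$in_domain))
})

test_that("in-domain flags and columns follow the domain coordinates", {
  fam <- tiny_family()
  ds <- make_dataset(fam$alignment,
                     gene = c("g1", "g1", "g3"), pos = c(2, 5, 7),
                     ref = c("G", "K", "E"), var = c("A", "E", "K"))
  expect_equal(ds$in_domain, c(FALSE, TRUE, TRUE))
  expect_equal(ds$column, c(NA, 1L, 4L))  # g3 lacks column 2, E is col 4
})

test_that("collapse levels treat recurrence as specified", {
  fam <- tiny_family()
  # 48 identical events, plus two distinct substitutions of one residue
  d48 <- make_dataset(fam$alignment, gene = rep("g1", 48), pos = rep(5, 48),
                      ref = rep("K", 48), var = rep("E", 48),
                      patient = paste0("p", 1:48))
  expect_equal(nrow(collapse_events(d48, "mutation", 1)), 48)
  expect_equal(nrow(collapse_events(d48, "residue", 1)), 1)
  expect_equal(nrow(collapse_events(d48, "gene", 1)), 1)

  d2 <- make_dataset(fam$alignment, gene = c("g2", "g2"), pos = c(6, 6),
                     ref = c("R", "R"), var = c("Q", "W"))
  expect_equal(nrow(collapse_events(d2, "mutation", 2)), 2)
  expect_equal(nrow(collapse_events(d2, "residue", 2)), 2)
  expect_equal(nrow(collapse_events(d2, "gene", 2)), 1)

  expect_equal(nrow(collapse_events(d2, "mutation", 5)), 0)
  expect_equal(nrow(collapse_events(d2, "residue", 5)), 0)
  expect_equal(nrow(collapse_events(d2, "gene", 5)), 0)
})

test_that("column profiles agree with an independent brute-force recount", {
  fam <- tiny_family()
  aln <- fam$alignment
  ds <- make_dataset(aln,
                     gene = c("g1", "g2", "g2", "g4", "g4", "g5"),
                     pos = c(5, 5, 5, 5, 6, 5),
                     ref = c("K", "K", "K", "Q", "R", "K"),
                     var = c("E", "E", "R", "K", "Q", "K"),
                     patient = c("p1", "p2", "p3", "p1", "p2", "p4"),
                     cancer_type = c("A", "A", "B", "B", "A", "A"))
  pr <- column_profile(aln, ds, 1, level = "residue")
  # independent recount at column 1: aligned residues K,K,K,Q,K
  expect_equal(pr$n_aligned, 5)
  expect_equal(unname(pr$R_ar["K"]), 4L)
  expect_equal(unname(pr$R_ar["Q"]), 1L)
  expect_equal(sum(pr$R_ar), 5L)
  expect_equal(pr$N_a, 5)  # 5 mutation-level records at column 1
  # residue-level events: g1 K>E, g2 K>E, g2 K>R, g4 Q>K, g5 K>K
  expect_equal(sum(pr$O_ar), 5L)
  expect_equal(unname(pr$O_ar["K"]), 4L)
  expect_equal(unname(pr$O_ar["Q"]), 1L)
  expect_equal(unname(pr$O_av["E"]), 2L)
  expect_equal(unname(pr$O_av["K"]), 2L)
  expect_equal(unname(pr$O_av["R"]), 1L)
  expect_equal(pr$n_mutated_genes, 4)
  expect_setequal(names(pr$mutated_genes), c("g1", "g2", "g4", "g5"))
  # label counts are mutation-level
  expect_equal(unname(c(pr$O_patient[c("p1", "p2", "p3", "p4")])),
               c(2, 1, 1, 1))
  expect_equal(unname(c(pr$O_cancer_type[c("A", "B")])), c(3, 2))
  # an unmutated, partially gapped column
  pr4 <- column_profile(aln, ds, 4, level = "residue")
  expect_equal(pr4$N_a, 0)
  expect_equal(pr4$n_aligned, 3)
  expect_equal(pr4$n_mutated_genes, 0)
})

test_that("an all-gap column profile is all zeros", {
  fa <- write_fasta(c(a = "A-", b = "C-"))
  aln <- read_alignment(fa)
  ds <- make_dataset(aln, gene = "a", pos = 1, ref = "A", var = "C")
  pr <- column_profile(aln, ds, 2)
  expect_equal(pr$n_aligned, 0)
  expect_equal(sum(pr$R_ar), 0L)
  expect_equal(pr$N_a, 0)
})
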