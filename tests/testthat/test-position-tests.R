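test_that("the add-one empirical p-value counts ties as extreme", {
  expect_equal(empirical_p(10, rep(1, 999), "upper"), 1 / 1000)
  expect_equal(empirical_p(5, rep(5, 99), "upper"), 1)     # all ties
  expect_equal(empirical_p(3, c(1, 2, 3, 4), "upper"), 3 / 5)
  expect_equal(empirical_p(3, c(1, 2, 3, 4), "lower"), 4 / 5)
  expect_error(empirical_p(1, numeric(0)), "empty")
})

test_that("Poisson mutation-number test matches direct tail summation", {
  E_r <- setNames(rep(NA_real_, 20), smpscan:::AA20)
  E_r["K"] <- 0.4
  model <- mk_model(E_r = E_r)
  # E_a = 5 aligned K * 0.4 = 2; N_a = 5
  pr <- mk_profile(aligned = setNames(rep("K", 5), paste0("g", 1:5)),
                   N_a = 5)
  res <- test_mutation_number(pr, model)
  # oracle: 1 - sum_{x<5} e^-2 2^x / x!
  oracle <- 1 - exp(-2) * sum(2^(0:4) / factorial(0:4))
  expect_equal(res$p, oracle, tolerance = 1e-12)
  expect_equal(res$p, 0.05265302, tolerance = 1e-7)
  # N_a = 0 gives p = 1 regardless of E_a
  expect_equal(test_mutation_number(mk_profile(
    aligned = setNames("K", "g1"), N_a = 0), model)$p, 1)
  # matches Monte-Carlo Poisson sampling within 3 SE
  set.seed(1)
  mc <- mean(rpois(2e5, 2) >= 5)
  expect_lt(abs(res$p - mc), 3 * sqrt(res$p * (1 - res$p) / 2e5))
  # monotone: more mutations at fixed E_a can only shrink p
  ps <- vapply(1:10, function(n) test_mutation_number(mk_profile(
    aligned = setNames(rep("K", 5), paste0("g", 1:5)), N_a = n),
    model)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  # degenerate null
  expect_error(test_mutation_number(mk_profile(aligned = c(), N_a = 3),
                                    model), "degenerate")
})

test_that("label chi-square matches the hand-computed statistic", {
  # N=10, two classes with N_c = 5 and 5; N_a = 2, both from class 1:
  # X2 = (2-1)^2/1 + (0-1)^2/1 = 2
  model <- mk_model(patient_counts = c(a = 1, b = 1, c = 1, d = 1, e = 1,
                                       f = 5))
  pr <- mk_profile(N_a = 2, O_patient = table(c("a", "b")))
  res <- test_label_distribution(pr, model, "patient", B = 2000, seed = 3)
  expect_equal(res$statistic, 2)
  # observed proportional to N_c gives statistic zero
  pr0 <- mk_profile(N_a = 2, O_patient = table(c("a", "f")))
  expect_equal(test_label_distribution(pr0, model, "patient", B = 10,
                                       seed = 1)$statistic, 0)
  # permuting labels within a count class leaves the statistic unchanged
  pr_perm <- mk_profile(N_a = 2, O_patient = table(c("c", "e")))
  expect_equal(test_label_distribution(pr_perm, model, "patient", B = 10,
                                       seed = 1)$statistic, 2)
})

test_that("label test p matches exhaustive enumeration of weighted draws", {
  # 3-mutation column; labels fall in class 1 w.p. 1/2, class 5 w.p. 1/2
  model <- mk_model(patient_counts = c(a = 1, b = 1, c = 1, d = 1, e = 1,
                                       f = 5))
  pr <- mk_profile(N_a = 3, O_patient = table(c("a", "b", "c")))
  res <- test_label_distribution(pr, model, "patient", B = 10000, seed = 9)
  prob <- model$patient$prob
  E <- 3 * prob
  oracle <- enum_multinom_chisq_p(3, prob, E, res$statistic, "upper")
  expect_lt(abs(res$p - oracle), mc_tol(oracle, 10000))
  # seeded reproducibility: same seed identical, other seed near
  res2 <- test_label_distribution(pr, model, "patient", B = 10000, seed = 9)
  expect_identical(res$p, res2$p)
  res3 <- test_label_distribution(pr, model, "patient", B = 10000, seed = 10)
  expect_false(identical(res$p, res3$p))
  expect_lt(abs(res3$p - oracle), mc_tol(oracle, 10000))
})

test_that("single label class makes every draw equal the observed", {
  model <- mk_model(patient_counts = c(a = 2, b = 2))
  pr <- mk_profile(N_a = 2, O_patient = table(c("a", "a")))
  expect_equal(test_label_distribution(pr, model, "patient", B = 50,
                                       seed = 1)$p, 1)
})

test_that("reference-residue test matches enumeration and scales correctly", {
  E_r <- counts20(c(K = 1, R = 1)) * 0.1
  E_r[E_r == 0] <- NA_real_
  model <- mk_model(E_r = E_r)
  # equal expectations, both observed events at K: X2 = (2-1)^2 + (0-1)^2
  # over E = 1 each -> 2 (with E_{a,K} = E_{a,R} = 10 * 0.1 = 1)
  pr <- mk_profile(aligned = setNames(rep(c("K", "R"), each = 10),
                                      paste0("g", 1:20)),
                   N_a = 2, O_ar = counts20(c(K = 2)))
  res <- test_reference_residues(pr, model, B = 10000, seed = 4)
  expect_equal(res$statistic, 2)
  # exhaustive 4-outcome null: (2,0),(1,1),(0,2) w.p. .25,.5,.25; X2 >= 2
  # for the two extreme outcomes -> p = 0.5
  oracle <- enum_multinom_chisq_p(2, c(.5, .5), c(1, 1), 2, "upper")
  expect_equal(oracle, 0.5)
  expect_lt(abs(res$p - oracle), mc_tol(oracle, 10000))
  # single residue type: all draws identical
  pr1 <- mk_profile(aligned = setNames(rep("K", 5), paste0("g", 1:5)),
                    N_a = 1, O_ar = counts20(c(K = 1)))
  expect_equal(test_reference_residues(pr1, model, B = 100, seed = 1)$p, 1)
  # doubling O and E uniformly doubles the statistic
  pr2 <- mk_profile(aligned = setNames(rep(c("K", "R"), each = 20),
                                       paste0("g", 1:40)),
                    N_a = 4, O_ar = counts20(c(K = 4)))
  res2 <- test_reference_residues(pr2, model, B = 10, seed = 1)
  expect_equal(res2$statistic, 2 * res$statistic)
})

test_that("variant-residue test matches trinomial enumeration", {
  P <- matrix(0, 20, 20, dimnames = list(smpscan:::AA20, smpscan:::AA20))
  P["K", "E"] <- 0.5; P["K", "R"] <- 0.5
  E_r <- counts20(c(K = 1)) * 0.1
  model <- mk_model(E_r = E_r, P_rv = P)
  # one event: either outcome gives X2 = (1-.5)^2/.5 + (0-.5)^2/.5 = 1
  pr1 <- mk_profile(aligned = setNames("K", "g1"), N_a = 1,
                    O_ar = counts20(c(K = 1)), O_av = counts20(c(E = 1)))
  res1 <- test_variant_residues(pr1, model, B = 500, seed = 2)
  expect_equal(res1$statistic, 1)
  expect_equal(res1$p, 1)
  # three events over the two variant classes
  pr3 <- mk_profile(aligned = setNames(rep("K", 3), paste0("g", 1:3)),
                    N_a = 3, O_ar = counts20(c(K = 3)),
                    O_av = counts20(c(E = 3)))
  res3 <- test_variant_residues(pr3, model, B = 10000, seed = 5)
  E_av <- c(1.5, 1.5)
  obs_stat <- (3 - 1.5)^2 / 1.5 + (0 - 1.5)^2 / 1.5
  expect_equal(res3$statistic, obs_stat)
  oracle <- enum_multinom_chisq_p(3, c(.5, .5), E_av, obs_stat, "upper")
  expect_lt(abs(res3$p - oracle), mc_tol(oracle, 10000))
  # a point-mass spectrum matching all observations gives stat 0, p 1
  Ppoint <- matrix(0, 20, 20, dimnames = dimnames(P))
  Ppoint["K", "E"] <- 1
  mp <- mk_model(E_r = E_r, P_rv = Ppoint)
  resp <- test_variant_residues(pr3, mp, B = 100, seed = 1)
  expect_equal(resp$statistic, 0)
  expect_equal(resp$p, 1)
  # undefined substitution row errors, naming the residue
  Pna <- P; Pna["K", ] <- NA_real_
  expect_error(test_variant_residues(pr3, mk_model(E_r = E_r, P_rv = Pna),
                                     B = 10, seed = 1), "K")
})

test_that("cancer-genes test matches weighted without-replacement oracle", {
  E_r <- counts20(c(K = 1, R = 1, D = 1)) * 0.1
  model <- mk_model(E_r = E_r)
  aligned <- setNames(c("K", "R", "D"), c("gA", "gB", "gC"))
  scores <- c(gA = 1, gB = 2, gC = 3)
  pr <- mk_profile(aligned = aligned, N_a = 1,
                   mutated = aligned["gA"])
  res <- test_cancer_genes(pr, scores, model, B = 10000, seed = 6)
  expect_equal(res$statistic, 1)
  # equal weights, draw one of three genes; mean score <= 1 for one of them
  oracle <- enum_wor_p(rep(1, 3), 1, function(idx) mean(scores[idx]), 1,
                       "lower")
  expect_equal(oracle, 1 / 3)
  expect_lt(abs(res$p - oracle), mc_tol(oracle, 10000))
  # two mutated genes, unequal weights: exact successive-sampling oracle
  E_r2 <- counts20(c(K = 2, R = 1, D = 1)) * 0.1
  model2 <- mk_model(E_r = E_r2)
  pr2 <- mk_profile(aligned = aligned, N_a = 2,
                    mutated = aligned[c("gA", "gB")])
  res2 <- test_cancer_genes(pr2, scores, model2, B = 10000, seed = 7)
  w <- c(0.2, 0.1, 0.1)
  oracle2 <- enum_wor_p(w, 2, function(idx) mean(scores[idx]),
                        res2$statistic, "lower")
  expect_lt(abs(res2$p - oracle2), mc_tol(oracle2, 10000))
  # constant scores tie everywhere
  same <- c(gA = 5, gB = 5, gC = 5)
  expect_equal(test_cancer_genes(pr, same, model, B = 100, seed = 1)$p, 1)
  # shifting every score by a constant leaves p unchanged
  res_sh <- test_cancer_genes(pr, scores + 100, model, B = 10000, seed = 6)
  expect_identical(res_sh$p, res$p)
  # missing scores error, listing the gene
  expect_error(test_cancer_genes(pr, scores[-3], model, B = 10, seed = 1),
               "gC")
})

test_that("gene-relatedness test matches its enumeration oracle", {
  # 4 genes on a tree; distances from a hand-made matrix
  D <- matrix(c(0, 1, 4, 4,
                1, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4,
              dimnames = list(c("gA", "gB", "gC", "gD"),
                              c("gA", "gB", "gC", "gD")))
  E_r <- counts20(c(K = 1)) * 0.1
  model <- mk_model(E_r = E_r)
  aligned <- setNames(rep("K", 4), rownames(D))
  pr <- mk_profile(aligned = aligned, N_a = 2,
                   mutated = aligned[c("gA", "gB")])
  res <- test_gene_relatedness(pr, D, model, B = 10000, seed = 8)
  expect_equal(res$statistic, 1)  # the patristic distance of the pair
  oracle <- enum_wor_p(rep(1, 4), 2, function(idx)
    mean(D[idx, idx][upper.tri(D[idx, idx])]), 1, "lower")
  expect_lt(abs(res$p - oracle), mc_tol(oracle, 10000))
  # a single mutated gene is not applicable
  pr1 <- mk_profile(aligned = aligned, N_a = 1, mutated = aligned["gA"])
  res1 <- test_gene_relatedness(pr1, D, model, B = 10, seed = 1)
  expect_false(res1$applicable)
  expect_true(is.na(res1$p))
  # equidistant genes (star tree): every draw ties
  Dstar <- matrix(2, 4, 4, dimnames = dimnames(D)); diag(Dstar) <- 0
  expect_equal(test_gene_relatedness(pr, Dstar, model, B = 100,
                                     seed = 1)$p, 1)
})

test_that("scan filters columns by mutated-gene count and is reproducible", {
  fam <- tiny_family()
  ds <- make_dataset(fam$alignment,
                     gene = c("g1", "g2", "g2", "g4"),
                     pos = c(5, 5, 9, 5),
                     ref = c("K", "K", "A", "Q"),
                     var = c("E", "R", "V", "K"),
                     patient = c("p1", "p2", "p3", "p4"),
                     cancer_type = c("A", "B", "A", "B"))
  # need non-domain mutations for the background
  nd <- make_dataset(fam$alignment,
                     gene = rep(c("g1", "g2", "g3", "g4", "g5"), each = 2),
                     pos = rep(c(1, 2), 5),
                     ref = "G", var = "A",
                     patient = paste0("q", c(1, 1, 1, 2, 2, 3, 3, 3, 3, 4)))
  all <- rbind(ds, nd)
  class(all) <- c("smp_mutations", "data.frame")
  bg <- fit_background(all, fam$proteins, fam$alignment)
  tt <- run_all_tests(fam$alignment, all, bg,
                      control = smp_control(B = 200, seed = 42))
  # column 1 has 3 mutated genes; column 5 has 1 (g2 only) -> excluded
  expect_equal(tt$column, 1L)
  expect_equal(tt$n_mutated_genes, 3)
  tt2 <- run_all_tests(fam$alignment, all, bg,
                       control = smp_control(B = 200, seed = 42))
  expect_identical(tt, tt2)
  tt3 <- run_all_tests(fam$alignment, all, bg,
                       control = smp_control(B = 200, seed = 43))
  expect_false(identical(c(tt$patients_p, tt$cancer_types_p),
                         c(tt3$patients_p, tt3$cancer_types_p)))
})
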