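test_that("cross-validation folds partition the cohort evenly with events spread", {
  set.seed(61)
  ev <- rbinom(100, 1, 0.3)
  f <- cv_folds(ev, 3, seed = 2)
  expect_equal(sort(unique(f)), 1:3)
  expect_lte(diff(range(table(f))), 1)
  for (k in 1:3) expect_gt(sum(ev[f == k]), 0)
  expect_identical(f, cv_folds(ev, 3, seed = 2))
})

test_that("boundary propagation applies the stated closed cuts", {
  tr_mps <- setNames(c(0.9, 0.7, 0.5, 0.2, -0.3, -0.6, -0.8), paste0("t", 1:7))
  tr_lab <- setNames(c("plus", "plus", "plus", "none", "minus", "minus", "none"),
                     names(tr_mps))
  te_mps <- setNames(c(0.6, 0.5, 0.4, -0.25, -0.35, 0), paste0("u", 1:6))
  lab <- propagate_boundaries(tr_mps, tr_lab, te_mps)
  expect_identical(unname(lab[c("u1", "u2", "u3")]),
                   c("plus", "plus", "none"))     # cut 0.5, closed
  # mirrored repressed cut = -0.3 (least extreme selected negative)
  expect_identical(unname(lab[c("u4", "u5")]), c("none", "minus"))
  expect_identical(unname(lab["u6"]), "none")
  # literal rule: cut = most negative selected (-0.6) propagates less
  lab_lit <- propagate_boundaries(tr_mps, tr_lab, te_mps,
                                  repressed_rule = "literal")
  expect_identical(unname(lab_lit["u5"]), "none")
  # all-zero test scores get no labels
  expect_true(all(propagate_boundaries(tr_mps, tr_lab,
                                       setNames(rep(0, 3), letters[1:3]))
                  == "none"))
})

test_that("a planted prognostic module passes the gates and decoys do not", {
  spec <- synthetic_cohort_spec(
    n_samples = 300, n_genes = 1000,
    modules = data.frame(size = 40, act_frac = 0.2, rep_frac = 0.2,
                         shift = 2, beta = c(1.2, 0)),
    n_decoys = 8, seed = 62)
  co <- generate_cohort(spec, with_sequences = FALSE)
  dec <- discover_pcms(co$expression, co$catalog, co$outcomes,
                       sizes = 25, n_rand = 200, n_null = 200, seed = 63)
  expect_true("planted_01" %in% pcms(dec))
  expect_false(any(co$truth$decoys %in% pcms(dec)))
  # gate conjunction: failing any one gate fails the module
  row1 <- dec[dec$module == "planted_01", ]
  expect_true(all(c(row1$train_fdr_1, row1$train_fdr_2, row1$train_fdr_3) <
                    attr(dec, "alphas")["train"]))
})

test_that("training MPS are blind to test-fold expression values", {
  spec <- synthetic_cohort_spec(
    n_samples = 90, n_genes = 400,
    modules = data.frame(size = 30, act_frac = 0.25, rep_frac = 0.25,
                         shift = 2, beta = 0.8),
    n_decoys = 3, seed = 64)
  co <- generate_cohort(spec, with_sequences = FALSE)
  d1 <- discover_pcms(co$expression, co$catalog, co$outcomes, sizes = 10,
                      n_rand = 150, n_null = 150, seed = 65, details = TRUE)
  folds <- attr(d1, "folds")
  x2 <- co$expression
  te1 <- names(folds)[folds == 1]
  x2$values[, te1] <- x2$values[, te1] * 3 + 5   # corrupt test fold 1
  d2 <- discover_pcms(x2, co$catalog, co$outcomes, sizes = 10,
                      n_rand = 150, n_null = 150, seed = 65, details = TRUE)
  expect_identical(attr(d1, "folds"), attr(d2, "folds"))
  expect_identical(attr(d1, "details")$P_train[[1]]$mps,
                   attr(d2, "details")$P_train[[1]]$mps)
})

test_that("discovery is deterministic given the seed", {
  spec <- synthetic_cohort_spec(
    n_samples = 120, n_genes = 400,
    modules = data.frame(size = 30, act_frac = 0.25, rep_frac = 0.25,
                         shift = 2, beta = 1),
    n_decoys = 4, seed = 66)
  co <- generate_cohort(spec, with_sequences = FALSE)
  d1 <- discover_pcms(co$expression, co$catalog, co$outcomes, sizes = 12,
                      n_rand = 150, n_null = 150, seed = 67)
  d2 <- discover_pcms(co$expression, co$catalog, co$outcomes, sizes = 12,
                      n_rand = 150, n_null = 150, seed = 67)
  expect_identical(d1, d2)
})

test_that("stage association flags an extreme stage-polarity table", {
  set.seed(68)
  n <- 240; G <- 500
  genes <- sprintf("g%04d", 1:G); ids <- sprintf("s%03d", 1:n)
  v <- matrix(rnorm(G * n), G, n, dimnames = list(genes, ids))
  stage <- setNames(sample(c("I", "II", "III", "IV"), n, TRUE), ids)
  # plant: module activated in stage IV, repressed in stage I
  mod_genes <- genes[1:40]
  v[mod_genes, stage == "IV"] <- v[mod_genes, stage == "IV"] + 2
  v[mod_genes, stage == "I"] <- v[mod_genes, stage == "I"] - 2
  cat_ <- module_catalog(list(
    gene_module("progression", mod_genes),
    gene_module("decoy", sample(genes, 40))))
  res <- stage_association(expression_matrix(v), cat_, stage, sizes = 15,
                           n_rand = 200, seed = 69)
  prog <- res[res$module == "progression", ]
  expect_true(prog$is_progression_associated)
  expect_lt(prog$full_p, 1e-4)
  expect_false(res$is_progression_associated[res$module == "decoy"])
})

test_that("collapsed 2x2 Fisher p equals the hypergeometric tail oracle", {
  tab <- matrix(c(9, 1, 2, 8), 2)
  p_fisher <- fisher.test(tab)$p.value
  # two-sided hypergeometric: sum of outcomes no more probable than observed
  m <- sum(tab[1, ]); nn <- sum(tab[2, ]); k <- sum(tab[, 1])
  probs <- dhyper(0:min(m, k), m, nn, k)
  p_oracle <- sum(probs[probs <= dhyper(tab[1, 1], m, nn, k) + 1e-12])
  expect_equal(p_fisher, p_oracle, tolerance = 1e-10)
})
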