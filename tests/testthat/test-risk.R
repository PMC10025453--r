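test_that("risk-group size rule reproduces the hand-evaluated formula values", {
  expect_equal(risk_group_size(1061, 0.666), 350)
  expect_equal(risk_group_size(100, 0.666), 25)
  # N=257: target floor(0.666*257/50)*25 = 75; default list lacks 75 so
  # the 25-distant tie {50,100} breaks toward the smaller candidate
  expect_equal(risk_group_size(257, 0.666), 50)
  expect_equal(risk_group_size(257, 0.666,
                               candidates = c(25, 50, 75, 100)), 75)
  expect_equal(risk_group_size(100, 1), 50)  # f=1: 50, exactly N/2
  expect_warning(s <- risk_group_size(40, 1), "clipped")
  expect_equal(s, 20)
})

test_that("risk groups take the extremes of the prediction ordering", {
  pred <- setNames(c(5, 4, 3, 2, 1, 0), paste0("s", 1:6))
  lab <- risk_groups(pred, size = 2)
  expect_setequal(names(lab)[lab == "high"], c("s1", "s2"))
  expect_setequal(names(lab)[lab == "low"], c("s5", "s6"))
  expect_error(risk_groups(c(a = 1, b = NA), size = 1), "incomplete")
})

test_that("forest risk predictions track a planted risk score", {
  set.seed(91)
  n <- 160
  ids <- sprintf("s%03d", 1:n)
  risk <- rnorm(n)
  time <- rexp(n, 0.05 * exp(risk))
  cens <- rexp(n, 0.015)
  out <- data.frame(sample_id = ids, time = pmin(time, cens),
                    event = as.integer(time <= cens))
  feats <- data.frame(truth = risk, noise1 = rnorm(n), noise2 = rnorm(n),
                      row.names = ids)
  pred <- fit_risk_model(feats, out, n_trees = 200, n_folds = 5,
                         repeats = 2, seed = 92)
  expect_false(anyNA(pred))
  expect_gt(cor(pred[, 1], risk, method = "spearman"), 0.5)
  pred2 <- fit_risk_model(feats, out, n_trees = 200, n_folds = 5,
                          repeats = 2, seed = 92)
  expect_identical(pred, pred2)  # same seed, same predictions
})

test_that("feature-set comparison favors the informative model", {
  set.seed(93)
  n <- 150
  ids <- sprintf("s%03d", 1:n)
  risk <- rnorm(n)
  time <- rexp(n, 0.05 * exp(1.2 * risk))
  out <- data.frame(sample_id = ids, time = time, event = rep(1L, n))
  mk_pred <- function(signal) {
    m <- vapply(1:4, function(r) signal + rnorm(n, sd = 0.2), numeric(n))
    rownames(m) <- ids
    m
  }
  res <- compare_feature_sets(
    list(informative = mk_pred(risk), noise = mk_pred(rnorm(n))), out)
  expect_lt(res$p["informative", "noise"], 0.05)
  expect_gt(res$p["noise", "informative"], 0.5)
  expect_error(compare_feature_sets(
    list(a = mk_pred(risk)[, 1:2, drop = FALSE]), out), "repeats")
})

test_that("AUC equals the Mann-Whitney U identity including ties", {
  set.seed(94)
  for (i in 1:25) {
    pos <- sample(0:10, 12, replace = TRUE) + rnorm(12, sd = 0.01 * (i %% 2))
    neg <- sample(0:10, 17, replace = TRUE) + rnorm(17, sd = 0.01 * (i %% 2))
    u <- suppressWarnings(wilcox.test(pos, neg)$statistic)
    expect_equal(roc_auc(pos, neg), unname(u) / (12 * 17), tolerance = 1e-12)
  }
  expect_equal(roc_auc(c(2, 3), c(0, 1)), 1)
  expect_equal(roc_auc(c(1, 1), c(1, 1)), 0.5)  # midrank ties
})

test_that("external validation flags consistent, inconsistent and weak modules", {
  spec <- synthetic_cohort_spec(
    n_samples = 250, n_genes = 800,
    modules = data.frame(size = 40, act_frac = 0.25, rep_frac = 0.25,
                         shift = 2, beta = c(1.3, 0)),
    n_decoys = 3, seed = 95)
  co_ext <- generate_cohort(spec, with_sequences = FALSE)
  cat_pcm <- module_catalog(co_ext$catalog$modules[c("planted_01",
                                                     "planted_02")])
  # discovery said: activation of planted_01 is harmful (wald_z < 0)
  res <- external_validation(cat_pcm,
                             directions = c(planted_01 = -1, planted_02 = -1),
                             co_ext$expression, co_ext$outcomes,
                             sizes = 25, n_rand = 200, seed = 96)
  r1 <- res[res$module == "planted_01", ]
  expect_true(r1$prognostic)
  expect_true(r1$consistent)
  # flipping the claimed direction breaks consistency but not significance
  res_flip <- external_validation(cat_pcm,
                                  directions = c(planted_01 = 1,
                                                 planted_02 = 1),
                                  co_ext$expression, co_ext$outcomes,
                                  sizes = 25, n_rand = 200, seed = 96)
  rf <- res_flip[res_flip$module == "planted_01", ]
  expect_true(rf$prognostic)
  expect_false(rf$consistent)
  # module with most genes absent from the external universe
  cat_missing <- module_catalog(list(
    gene_module("alien", sprintf("zz%03d", 1:40))))
  res2 <- external_validation(cat_missing, c(alien = 1),
                              co_ext$expression, co_ext$outcomes,
                              sizes = 25, n_rand = 200, seed = 96)
  expect_false(res2$evaluable[1])
})

test_that("validation AUC separates real modules from randomized profiles", {
  spec <- synthetic_cohort_spec(
    n_samples = 200, n_genes = 600,
    modules = data.frame(size = 40, act_frac = 0.25, rep_frac = 0.25,
                         shift = 2, beta = 1.3),
    n_decoys = 5, seed = 97)
  co <- generate_cohort(spec, with_sequences = FALSE)
  cat_pos <- module_catalog(co$catalog$modules["planted_01"])
  aucs <- validation_auc(cat_pos, co$expression, co$outcomes, k = 25,
                         n_neg = 20, repeats = 3, n_rand = 200, seed = 98)
  expect_length(aucs, 3)
  expect_true(all(aucs >= 0.9))
})
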