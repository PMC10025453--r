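test_that("equal-population binning follows the stated tie and remainder rules", {
  b <- quantize_sample(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), Ne = 2)
  expect_equal(sum(b == 1), 5)
  expect_equal(sum(b == 2), 5)
  expect_equal(b[10], 1L)  # smallest value in lowest bin

  b11 <- quantize_sample(rnorm(11), Ne = 2)
  expect_equal(as.vector(table(b11)), c(6, 5))  # extra in the lowest bin

  ties <- quantize_sample(rep(1, 10), Ne = 5)
  expect_equal(as.vector(table(ties)), rep(2, 5))
  expect_equal(ties, rep(1:5, each = 2))        # stable input order
  expect_error(quantize_sample(1:3, Ne = 5), "exceeds")
})

test_that("mutual information matches hand values and the brute-force oracle", {
  expect_equal(mutual_information(matrix(c(2, 0, 0, 2), 2)), log(2))
  expect_equal(mutual_information(matrix(c(1, 1, 1, 1), 2)), 0)
  expect_error(mutual_information(matrix(c(-1, 1, 1, 1), 2)), "negative")
  set.seed(31)
  for (i in 1:50) {
    ct <- matrix(rpois(20, 3), nrow = 2)
    expect_equal(mutual_information(ct), mi_bruteforce(ct),
                 tolerance = 1e-12)
  }
})

test_that("MI is invariant to bin relabeling; z is log-base invariant", {
  set.seed(32)
  ct <- matrix(rpois(12, 5), nrow = 2)
  expect_equal(mutual_information(ct), mutual_information(ct[, 6:1]))
  # base change scales I, mu, sigma alike: z identical by construction
  nm <- null_model(N = 100, m = 10, Ne = 5, n_rand = 200, seed = 5)
  obs <- nm$mu + 2 * nm$sigma
  z_nats <- (obs - nm$mu) / nm$sigma
  z_bits <- (obs / log(2) - nm$mu / log(2)) / (nm$sigma / log(2))
  expect_equal(z_nats, z_bits)
})

test_that("degenerate modules give zero scores", {
  z <- toy_zscores(100, seed = 41)
  # all-ones membership: MI identically 0 under any permutation
  mod_all <- gene_module("all", names(z))
  p <- mps(mod_all, z, Ne = 5, n_rand = 100, seed = 2)
  expect_equal(p$mps, 0)
  expect_false(p$significant)
  mod_tiny <- gene_module("tiny", names(z)[1])
  expect_warning(p2 <- mps(mod_tiny, z, n_rand = 100, seed = 2), "<2")
  expect_equal(p2$mps, 0)
})

test_that("mps sign follows the Pearson correlation and flips with negation", {
  z <- sort(toy_zscores(200, seed = 42), decreasing = TRUE)
  names(z) <- sprintf("g%04d", 1:200)  # top genes first
  mod <- gene_module("up", names(z)[1:20])
  p <- mps(mod, z, Ne = 10, n_rand = 300, seed = 3)
  expect_gt(p$r, 0)
  expect_gt(p$mps, 0)
  expect_true(p$significant)
  pneg <- mps(mod, -z, Ne = 10, n_rand = 300, seed = 3)
  expect_lt(pneg$mps, 0)
  expect_equal(abs(pneg$mps), abs(p$mps))   # MI invariant, sign flips
})

test_that("a strongly planted shift is significant across seeds", {
  set.seed(43)
  hits <- vapply(1:20, function(s) {
    z <- toy_zscores(300)
    z[1:25] <- z[1:25] + 3
    mod <- gene_module("m", names(z)[1:25])
    mps(mod, z, Ne = 10, n_rand = 300, seed = s)$significant
  }, TRUE)
  expect_gte(mean(hits), 0.99)
})

test_that("score_cohort reduces to mps() and is sample-order equivariant", {
  set.seed(44)
  x <- expression_matrix(matrix(rnorm(200 * 6), 200, 6,
                                dimnames = list(sprintf("g%04d", 1:200),
                                                paste0("s", 1:6))))
  z <- standardize(x)
  cat1 <- module_catalog(list(gene_module("m", sprintf("g%04d", 1:20))))
  P <- score_cohort(cat1, z, Ne = 10, n_rand = 200, seed = 5)
  single <- mps(cat1$modules$m, z$values[, 1], Ne = 10, n_rand = 200,
                null = null_model(200, 20, 10, 200,
                                  seed = derive_seed(5, 7919L, 20)))
  expect_equal(unname(P$mps["m", 1]), single$mps)
  zp <- subset_expression(z, samples = c(4, 2, 6, 1, 3, 5))
  Pp <- score_cohort(cat1, zp, Ne = 10, n_rand = 200, seed = 5)
  expect_equal(Pp$mps, P$mps[, colnames(zp$values), drop = FALSE])
})

test_that("planted activation at +2 SD labels the activated samples MPS+", {
  spec <- synthetic_cohort_spec(
    n_samples = 100, n_genes = 1000,
    modules = data.frame(size = 50, act_frac = 0.3, rep_frac = 0,
                         shift = 2, beta = 0),
    n_decoys = 2, seed = 17)
  co <- generate_cohort(spec, with_sequences = FALSE)
  P <- score_cohort(co$catalog, standardize(co$expression),
                    Ne = 10, n_rand = 300, seed = 7)
  activated <- names(which(co$truth$activation[1, ] == 1))
  expect_gte(mean(P$mps["planted_01", activated] > 0), 0.9)
})

test_that("cohort-specific selection equals a brute-force quantile filter", {
  set.seed(46)
  n_mod <- 50; n_smp <- 40
  mpsm <- matrix(rnorm(n_mod * n_smp) * rbinom(n_mod * n_smp, 1, 0.4),
                 n_mod, n_smp,
                 dimnames = list(sprintf("m%02d", 1:n_mod),
                                 sprintf("s%02d", 1:n_smp)))
  mpsm["m01", ] <- 2            # constant strong activation
  mpsm["m02", ] <- 0            # silent
  P <- list(mps = mpsm)
  class(P) <- "PerturbationMatrix"
  got <- cohort_specific_modules(P, 0.5, 0.4)
  oracle <- function(v, mq, vq) {
    mu <- rowMeans(v); va <- apply(v, 1, var); act <- mu > 0
    rownames(v)[act &
      mu >= quantile(mu[act], 1 - mq) & va <= quantile(va[act], vq)]
  }
  want <- union(oracle(pmax(mpsm, 0), 0.5, 0.4),
                oracle(pmax(-mpsm, 0), 0.5, 0.4))
  expect_setequal(got, want)
  expect_true("m01" %in% got)
  expect_false("m02" %in% got)
  expect_error(cohort_specific_modules(P, 0, 0.4), "quantiles")
})

test_that("tissue-specific selection requires significant opposite signs", {
  mk <- function(mps, sig) {
    P <- list(mps = mps, significant = sig)
    class(P) <- "PerturbationMatrix"
    P
  }
  ids <- paste0("p", 1:8)
  m_t <- matrix(1, 2, 8, dimnames = list(c("a", "b"), ids))
  m_n <- matrix(-1, 2, 8, dimnames = list(c("a", "b"), ids))
  s <- matrix(TRUE, 2, 8, dimnames = list(c("a", "b"), ids))
  expect_setequal(tissue_specific_modules(mk(m_t, s), mk(m_n, s)),
                  c("a", "b"))
  # module significant in tumor only: product not < 0
  m_n0 <- m_n; m_n0["a", ] <- 0
  expect_identical(tissue_specific_modules(mk(m_t, s), mk(m_n0, s)), "b")
  # brute-force pair counting on random matrices
  set.seed(47)
  for (i in 1:10) {
    mt <- matrix(sample(c(-2, 0, 1, 3), 40, replace = TRUE), 5, 8,
                 dimnames = list(letters[1:5], ids))
    mn <- matrix(sample(c(-1, 0, 2), 40, replace = TRUE), 5, 8,
                 dimnames = list(letters[1:5], ids))
    st <- mt != 0; sn <- mn != 0
    got <- tissue_specific_modules(mk(mt, st), mk(mn, sn), frac = 0.5)
    want <- letters[1:5][rowMeans(mt * mn < 0 & st & sn) >= 0.5]
    expect_setequal(got, want)
  }
})
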