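#' Assign cross-validation folds, stratified by a factor
#'
#' Samples are shuffled within strata (typically event status, so every
#' fold carries events) and folds dealt round-robin, keeping fold sizes
#' within one of each other overall.
#'
#' @param strata per-sample factor (e.g. event indicator); a single
#'   integer is treated as an unstratified sample count
#' @param n_folds number of folds (default 3)
#' @param seed integer seed
#' @return integer vector of fold assignments in 1..n_folds
#' @export
cv_folds <- function(strata, n_folds = 3, seed = 1) {
  if (length(strata) == 1L && is.numeric(strata))
    strata <- rep(1L, strata)
  n <- length(strata)
  strata <- as.factor(strata)
  ord <- with_seed(seed, {
    unlist(lapply(levels(strata), function(l) {
      idx <- which(strata == l)
      idx[sample.int(length(idx))]
    }), use.names = FALSE)
  })
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(n_folds), n)
  folds
}

#' Propagate training-arm MPS boundaries to test samples
#'
#' The activated cut is the least positive MPS among the selected
#' training MPS+ samples; test samples at or above it are labeled
#' `"plus"`. The repressed cut defaults to the mirrored rule (the
#' least-extreme selected negative value; test samples at or below it
#' are `"minus"`). `repressed_rule = "literal"` uses the most negative
#' selected value instead. Boundaries are closed.
#'
#' @param train_mps named training MPS vector
#' @param train_labels named training labels from [stratify_by_mps()]
#' @param test_mps named test MPS vector
#' @param repressed_rule `"mirror"` (default) or `"literal"`
#' @return named character labels for the test samples
#' @export
propagate_boundaries <- function(train_mps, train_labels, test_mps,
                                 repressed_rule = c("mirror", "literal")) {
  repressed_rule <- match.arg(repressed_rule)
  plus_vals <- train_mps[names(train_labels)[train_labels == "plus"]]
  minus_vals <- train_mps[names(train_labels)[train_labels == "minus"]]
  lab <- stats::setNames(rep("none", length(test_mps)), names(test_mps))
  if (length(plus_vals)) {
    plus_cut <- min(plus_vals)
    lab[test_mps >= plus_cut & test_mps > 0] <- "plus"
  }
  if (length(minus_vals)) {
    minus_cut <- if (repressed_rule == "mirror") max(minus_vals)
                 else min(minus_vals)
    lab[test_mps <= minus_cut & test_mps < 0] <- "minus"
  }
  lab
}

# Re-form fixed-size arms from propagated labels: among labeled plus
# samples take the k largest MPS, among labeled minus the k most
# negative. Returns NULL when either arm is empty.
reform_arms <- function(labels, mps_vals, k) {
  plus <- names(labels)[labels == "plus"]
  minus <- names(labels)[labels == "minus"]
  if (!length(plus) || !length(minus)) return(NULL)
  k_use <- min(k, length(plus), length(minus))
  plus <- plus[order(-mps_vals[plus])][seq_len(k_use)]
  minus <- minus[order(mps_vals[minus])][seq_len(k_use)]
  lab <- stats::setNames(rep("none", length(mps_vals)), names(mps_vals))
  lab[plus] <- "plus"
  lab[minus] <- "minus"
  attr(lab, "k_used") <- k_use
  lab
}

# Shared null log-rank p-values, cached per (context, k) inside one
# discovery run — the resampling null does not depend on the module.
get_logrank_null <- function(cache, outcomes, k, n_null, seed, tag) {
  key <- sprintf("%s_k%d", tag, k)
  if (!is.null(cache[[key]])) return(cache[[key]])
  ps <- logrank_null_pvals(outcomes, k, n_null,
                           derive_seed(seed, 104729L, k, nchar(tag)))
  cache[[key]] <- ps
  ps
}

#' Discover prognostic cancer modules under 3-fold cross-validation
#'
#' For each fold, the training two-thirds are standardized stand-alone
#' and the held-out third z-scored with the training means and SDs; MPS
#' are computed per fold, fixed-size MPS+/MPS- arms are selected on
#' training, their boundary cuts are propagated to the test fold, the
#' three labeled test folds are concatenated, and arms are re-formed at
#' the same fixed size. A module is a PCM at a group size when the
#' empirical log-rank FDR is below `alpha_train` in all three training
#' folds, below `alpha_test` on the concatenated propagated test labels,
#' and, on the full cohort without a split, below `alpha_full` with a
#' Cox p below `alpha_cox`.
#'
#' @param x `ExpressionMatrix` (raw-normalized; standardization is done
#'   internally per fold and on the full cohort)
#' @param catalog a [module_catalog()]
#' @param outcomes data.frame with `sample_id`, `time`, `event`
#' @param sizes integer vector of per-arm group sizes to test
#' @param Ne,n_rand,sig_level,magnitude scoring parameters, see
#'   [score_cohort()]
#' @param n_null resamples for the empirical FDR (default 1000)
#' @param alpha_train,alpha_test,alpha_full,alpha_cox gate thresholds
#'   (defaults 0.05 / 0.01 / 0.01 / 0.05)
#' @param n_folds folds (default 3)
#' @param seed integer seed covering folds, nulls and scoring
#' @param repressed_rule see [propagate_boundaries()]
#' @param min_test_arm smallest acceptable re-formed test arm when fewer
#'   than `k` labels propagate (default 10)
#' @param min_size minimum in-universe module size (default 5)
#' @param details logical; attach per-fold scoring objects for audit
#' @return data.frame of class `pcm_decisions`, one row per evaluated
#'   (module, group size): training/test/full FDRs, full-cohort Cox p,
#'   Wald z, log2 HR, and `is_pcm`
#' @export
discover_pcms <- function(x, catalog, outcomes, sizes,
                          Ne = 10, n_rand = 1000, n_null = 1000,
                          sig_level = 0.01,
                          magnitude = "gated_z",
                          alpha_train = 0.05, alpha_test = 0.01,
                          alpha_full = 0.01, alpha_cox = 0.05,
                          n_folds = 3, seed = 1,
                          repressed_rule = "mirror",
                          min_test_arm = 10, min_size = 5,
                          details = FALSE) {
  samples <- intersect(x$sample_ids, outcomes$sample_id)
  if (length(samples) < 3L * n_folds) stop("too few samples with outcomes")
  x <- subset_expression(x, samples = samples)
  outcomes <- outcomes[match(samples, outcomes$sample_id), , drop = FALSE]
  folds <- cv_folds(outcomes$event, n_folds, derive_seed(seed, 11L))

  null_cache <- new.env(parent = emptyenv())  # MI permutation nulls
  lr_cache <- new.env(parent = emptyenv())    # log-rank resampling nulls

  P_full <- score_cohort(catalog, standardize(x), Ne = Ne, n_rand = n_rand,
                         seed = seed, sig_level = sig_level,
                         magnitude = magnitude, min_size = min_size,
                         null_cache = null_cache)
  P_tr <- vector("list", n_folds)
  P_te <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr_ids <- samples[folds != f]
    te_ids <- samples[folds == f]
    x_tr <- subset_expression(x, samples = tr_ids)
    mu <- rowMeans(x_tr$values, na.rm = TRUE)
    sdv <- apply(x_tr$values, 1L, stats::sd, na.rm = TRUE)
    P_tr[[f]] <- score_cohort(catalog, standardize(x_tr), Ne = Ne,
                              n_rand = n_rand, seed = seed,
                              sig_level = sig_level, magnitude = magnitude,
                              min_size = min_size, null_cache = null_cache)
    x_te <- standardize(subset_expression(x, samples = te_ids),
                        ref_means = mu, ref_sds = sdv)
    P_te[[f]] <- score_cohort(catalog, x_te, Ne = Ne, n_rand = n_rand,
                              seed = seed, sig_level = sig_level,
                              magnitude = magnitude, min_size = min_size,
                              null_cache = null_cache)
  }

  mods <- rownames(P_full$mps)
  rows <- list()
  for (k in sizes) {
    for (mod in mods) {
      rec <- list(module = mod, group_size = k,
                  train_fdr_1 = NA_real_, train_fdr_2 = NA_real_,
                  train_fdr_3 = NA_real_, test_fdr = NA_real_,
                  test_k = NA_integer_, full_fdr = NA_real_,
                  full_cox_p = NA_real_, full_wald_z = NA_real_,
                  full_log2_hr = NA_real_, is_pcm = FALSE,
                  skipped = FALSE, reason = "")
      prop_labels <- character(0)
      ok <- TRUE
      for (f in seq_len(n_folds)) {
        tr_out <- outcomes[folds != f, , drop = FALSE]
        mrow <- P_tr[[f]]$mps[mod, ]
        lab <- stratify_by_mps(mrow, k)
        if (is.null(lab)) {
          rec$skipped <- TRUE
          rec$reason <- sprintf("fold %d: fewer than %d nonzero MPS per arm", f, k)
          ok <- FALSE
          break
        }
        cmp <- compare_survival(lab, tr_out)
        nul <- get_logrank_null(lr_cache, tr_out, k, n_null, seed,
                                sprintf("train%d", f))
        rec[[sprintf("train_fdr_%d", f)]] <-
          empirical_fdr(cmp$logrank_p, null_p = nul)
        te_lab <- propagate_boundaries(mrow, lab, P_te[[f]]$mps[mod, ],
                                       repressed_rule = repressed_rule)
        prop_labels <- c(prop_labels, te_lab)
      }
      if (!ok) { rows[[length(rows) + 1L]] <- rec; next }

      # concatenated test folds = full cohort with propagated labels
      te_mps <- stats::setNames(numeric(length(samples)), samples)
      for (f in seq_len(n_folds))
        te_mps[colnames(P_te[[f]]$mps)] <- P_te[[f]]$mps[mod, ]
      te_lab_all <- prop_labels[samples]
      names(te_lab_all) <- samples
      te_arms <- reform_arms(te_lab_all, te_mps, k)
      if (is.null(te_arms) || attr(te_arms, "k_used") < min(k, min_test_arm) ||
          (attr(te_arms, "k_used") < k &&
           attr(te_arms, "k_used") < min_test_arm)) {
        rec$skipped <- TRUE
        rec$reason <- "insufficient propagated test labels"
        rows[[length(rows) + 1L]] <- rec
        next
      }
      k_test <- attr(te_arms, "k_used")
      rec$test_k <- k_test
      cmp_te <- compare_survival(te_arms, outcomes)
      nul_te <- get_logrank_null(lr_cache, outcomes, k_test, n_null, seed,
                                 "test")
      rec$test_fdr <- empirical_fdr(cmp_te$logrank_p, null_p = nul_te)

      lab_full <- stratify_by_mps(P_full$mps[mod, ], k)
      if (is.null(lab_full)) {
        rec$skipped <- TRUE
        rec$reason <- "full cohort: insufficient nonzero MPS"
        rows[[length(rows) + 1L]] <- rec
        next
      }
      cmp_full <- compare_survival(lab_full, outcomes)
      nul_full <- get_logrank_null(lr_cache, outcomes, k, n_null, seed,
                                   "full")
      rec$full_fdr <- empirical_fdr(cmp_full$logrank_p, null_p = nul_full)
      rec$full_cox_p <- cmp_full$cox_p
      rec$full_wald_z <- cmp_full$wald_z
      rec$full_log2_hr <- cmp_full$log2_hr
      rec$is_pcm <-
        all(c(rec$train_fdr_1, rec$train_fdr_2, rec$train_fdr_3) <
              alpha_train) &&
        isTRUE(rec$test_fdr < alpha_test) &&
        isTRUE(rec$full_fdr < alpha_full) &&
        isTRUE(rec$full_cox_p < alpha_cox)
      rows[[length(rows) + 1L]] <- rec
    }
  }
  res <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  class(res) <- c("pcm_decisions", "data.frame")
  attr(res, "alphas") <- c(train = alpha_train, test = alpha_test,
                           full = alpha_full, cox = alpha_cox)
  attr(res, "folds") <- stats::setNames(folds, samples)
  if (details)
    attr(res, "details") <- list(P_full = P_full, P_train = P_tr,
                                 P_test = P_te)
  res
}

#' Modules that pass the PCM gates
#' @param decisions a `pcm_decisions` data.frame
#' @return character vector of module names with at least one passing
#'   group size
#' @export
pcms <- function(decisions) unique(decisions$module[decisions$is_pcm])

#' Modules associated with cancer stage
#'
#' The PCM cross-validation protocol with the survival gates replaced by
#' Fisher exact tests on the stage x {MPS+, MPS-} contingency table
#' (4 rows when all four discretized stages are present). Gates: p <
#' `alpha_train` in all training folds, p < `alpha_test` on the
#' concatenated propagated test labels, p < `alpha_full` on the full
#' cohort. Large tables fall back to a seeded Monte-Carlo p
#' (`simulate.p.value`, 10,000 draws).
#'
#' @param x `ExpressionMatrix` (raw-normalized)
#' @param catalog a [module_catalog()]
#' @param stages named per-sample factor/character with levels I..IV
#' @param sizes per-arm group sizes to test
#' @param Ne,n_rand,sig_level scoring parameters
#' @param alpha_train,alpha_test,alpha_full Fisher gates
#'   (defaults 0.05 / 0.01 / 0.01)
#' @param n_folds,seed,repressed_rule,min_test_arm,min_size as in
#'   [discover_pcms()]
#' @return data.frame, one row per evaluated (module, size), with the
#'   three training p-values, test and full p-values and
#'   `is_progression_associated`
#' @export
stage_association <- function(x, catalog, stages, sizes,
                              Ne = 10, n_rand = 1000, sig_level = 0.01,
                              alpha_train = 0.05, alpha_test = 0.01,
                              alpha_full = 0.01, n_folds = 3, seed = 1,
                              repressed_rule = "mirror",
                              min_test_arm = 10, min_size = 5) {
  samples <- intersect(x$sample_ids, names(stages))
  if (length(samples) < 3L * n_folds) stop("too few staged samples")
  x <- subset_expression(x, samples = samples)
  stages <- factor(stages[samples])
  if (nlevels(droplevels(stages)) < 2L) stop("need >= 2 distinct stages")
  folds <- cv_folds(stages, n_folds, derive_seed(seed, 13L))
  null_cache <- new.env(parent = emptyenv())

  fisher_p <- function(lab, seed_mc) {
    keep <- lab %in% c("plus", "minus")
    tab <- table(stage = stages[names(lab)[keep]], arm = lab[keep])
    p <- tryCatch(stats::fisher.test(tab)$p.value, error = function(e) NULL)
    if (is.null(p))
      p <- with_seed(seed_mc,
        stats::fisher.test(tab, simulate.p.value = TRUE, B = 10000)$p.value)
    p
  }

  P_full <- score_cohort(catalog, standardize(x), Ne = Ne, n_rand = n_rand,
                         seed = seed, sig_level = sig_level,
                         min_size = min_size, null_cache = null_cache)
  P_tr <- vector("list", n_folds); P_te <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr_ids <- samples[folds != f]; te_ids <- samples[folds == f]
    x_tr <- subset_expression(x, samples = tr_ids)
    mu <- rowMeans(x_tr$values, na.rm = TRUE)
    sdv <- apply(x_tr$values, 1L, stats::sd, na.rm = TRUE)
    P_tr[[f]] <- score_cohort(catalog, standardize(x_tr), Ne = Ne,
                              n_rand = n_rand, seed = seed,
                              sig_level = sig_level, min_size = min_size,
                              null_cache = null_cache)
    P_te[[f]] <- score_cohort(catalog,
                              standardize(subset_expression(x, samples = te_ids),
                                          ref_means = mu, ref_sds = sdv),
                              Ne = Ne, n_rand = n_rand, seed = seed,
                              sig_level = sig_level, min_size = min_size,
                              null_cache = null_cache)
  }

  rows <- list()
  for (k in sizes) for (mod in rownames(P_full$mps)) {
    rec <- list(module = mod, group_size = k,
                train_p_1 = NA_real_, train_p_2 = NA_real_,
                train_p_3 = NA_real_, test_p = NA_real_,
                full_p = NA_real_, is_progression_associated = FALSE,
                skipped = FALSE)
    prop <- character(0); ok <- TRUE
    for (f in seq_len(n_folds)) {
      mrow <- P_tr[[f]]$mps[mod, ]
      lab <- stratify_by_mps(mrow, k)
      if (is.null(lab)) { rec$skipped <- TRUE; ok <- FALSE; break }
      rec[[sprintf("train_p_%d", f)]] <-
        fisher_p(lab, derive_seed(seed, 17L, f, k))
      prop <- c(prop, propagate_boundaries(mrow, lab, P_te[[f]]$mps[mod, ],
                                           repressed_rule = repressed_rule))
    }
    if (!ok) { rows[[length(rows) + 1L]] <- rec; next }
    te_mps <- stats::setNames(numeric(length(samples)), samples)
    for (f in seq_len(n_folds))
      te_mps[colnames(P_te[[f]]$mps)] <- P_te[[f]]$mps[mod, ]
    te_lab <- prop[samples]; names(te_lab) <- samples
    arms <- reform_arms(te_lab, te_mps, k)
    if (is.null(arms) || attr(arms, "k_used") < min(k, min_test_arm)) {
      rec$skipped <- TRUE; rows[[length(rows) + 1L]] <- rec; next
    }
    rec$test_p <- fisher_p(arms, derive_seed(seed, 19L, k))
    lab_full <- stratify_by_mps(P_full$mps[mod, ], k)
    if (is.null(lab_full)) {
      rec$skipped <- TRUE; rows[[length(rows) + 1L]] <- rec; next
    }
    rec$full_p <- fisher_p(lab_full, derive_seed(seed, 23L, k))
    rec$is_progression_associated <-
      all(c(rec$train_p_1, rec$train_p_2, rec$train_p_3) < alpha_train) &&
      isTRUE(rec$test_p < alpha_test) && isTRUE(rec$full_p < alpha_full)
    rows[[length(rows) + 1L]] <- rec
  }
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}
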