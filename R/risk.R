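#' Cross-validated random survival forest risk predictions
#'
#' Fits right-censored survival forests (via [ranger::ranger()],
#' log-rank splitting) under `n_folds`-fold cross-validation repeated
#' `repeats` times, and collates per-repeat out-of-fold risk predictions
#' (the row sums of the cumulative hazard function, so larger = higher
#' risk). Defaults follow the analysis design: 1000 trees, terminal node
#' size 15, mtry = ceiling(ln(#features)). Folds are stratified by event
#' status so no training fold is all-censored. Deterministic given
#' `seed`.
#'
#' @param features data.frame or matrix, one row per sample (rownames =
#'   sample ids); character/factor columns are expanded to indicators
#' @param outcomes data.frame with `sample_id`, `time`, `event`
#' @param n_trees trees per forest (default 1000)
#' @param node_size minimal terminal node size (default 15)
#' @param n_folds CV folds (default 10)
#' @param repeats CV repetitions (default 10)
#' @param seed integer seed
#' @return matrix of class `risk_predictions`, samples x repeats
#' @export
fit_risk_model <- function(features, outcomes, n_trees = 1000,
                           node_size = 15, n_folds = 10, repeats = 10,
                           seed = 1) {
  features <- as.data.frame(features)
  ids <- rownames(features)
  if (is.null(ids)) stop("`features` needs sample-id rownames")
  ids <- intersect(ids, outcomes$sample_id)
  features <- features[ids, , drop = FALSE]
  out <- outcomes[match(ids, outcomes$sample_id), ]
  if (sum(out$event) < 50)
    warning("fewer than 50 events; forest risk estimates will be unstable")
  X <- as.data.frame(stats::model.matrix(~ . - 1, data = features))
  names(X) <- make.names(names(X), unique = TRUE)
  mtry <- max(1L, ceiling(log(ncol(X))))
  n <- nrow(X)
  pred <- matrix(NA_real_, n, repeats, dimnames = list(ids, NULL))
  for (r in seq_len(repeats)) {
    folds <- cv_folds(out$event, n_folds, derive_seed(seed, 29L, r))
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      dtr <- cbind(time = out$time[tr], event = out$event[tr],
                   X[tr, , drop = FALSE])
      fit <- ranger::ranger(
        survival::Surv(time, event) ~ ., data = dtr,
        num.trees = n_trees, mtry = mtry, min.node.size = node_size,
        splitrule = "logrank", seed = derive_seed(seed, 31L, r, f),
        num.threads = 1)
      chf <- stats::predict(fit, data = X[!tr, , drop = FALSE],
                            num.threads = 1)$chf
      pred[!tr, r] <- rowSums(chf)
    }
  }
  class(pred) <- c("risk_predictions", class(pred))
  pred
}

#' Per-arm risk-group size from cohort size
#'
#' Evaluates floor(f * N / 50) * 25 and snaps it to the nearest
#' candidate size (ties toward the smaller candidate); the result is
#' clipped to floor(N / 2) with a warning when necessary.
#'
#' @param N cohort size
#' @param f fraction in (0, 1] (default 0.666)
#' @param candidates candidate per-arm sizes
#' @return chosen per-arm size
#' @export
risk_group_size <- function(N, f = 0.666,
                            candidates = c(25, 50, 100, 150, 200, 250,
                                           300, 350, 400, 450, 500)) {
  target <- floor(f * N / 50) * 25
  d <- abs(target - candidates)
  best <- candidates[d == min(d)]
  size <- min(best)                      # tie toward the smaller candidate
  if (size > N %/% 2) {
    warning("chosen size ", size, " exceeds N/2; clipped")
    size <- N %/% 2
  }
  size
}

#' Label high- and low-risk groups from collated predictions
#'
#' @param pred named per-sample risk vector (one repeat)
#' @param size per-arm size; computed from `f` via [risk_group_size()]
#'   when missing
#' @param f fraction passed to [risk_group_size()] (default 0.666)
#' @param ... further arguments to [risk_group_size()]
#' @return named character vector: `"high"`, `"low"`, `"none"`
#' @export
risk_groups <- function(pred, size = NULL, f = 0.666, ...) {
  if (any(is.na(pred))) stop("predictions incomplete")
  N <- length(pred)
  size <- size %||% risk_group_size(N, f, ...)
  if (size > N %/% 2) {
    warning("size exceeds N/2; clipped")
    size <- N %/% 2
  }
  ord <- order(-pred)
  lab <- stats::setNames(rep("none", N), names(pred))
  lab[ord[seq_len(size)]] <- "high"
  lab[rev(ord)[seq_len(size)]] <- "low"
  lab
}

# |log2 HR| of the high-vs-low risk split for one repeat.
risk_split_strength <- function(pred, outcomes, size) {
  rg <- risk_groups(pred, size = size)
  lab <- stats::setNames(rep("none", length(rg)), names(rg))
  lab[rg == "high"] <- "plus"
  lab[rg == "low"] <- "minus"
  cmp <- compare_survival(lab, outcomes)
  abs(cmp$log2_hr)
}

#' Compare feature-set models by risk-split strength
#'
#' For each model and CV repeat, the cohort is split into equal high-
#' and low-risk groups (size from the [risk_group_size()] rule) and the
#' absolute log2 hazard ratio of the split recorded; models are then
#' compared pairwise with one-sided Mann-Whitney tests on these
#' per-repeat strengths (row model stronger than column model).
#'
#' @param preds_by_model named list of `risk_predictions` matrices over
#'   the same samples
#' @param outcomes data.frame with `sample_id`, `time`, `event`
#' @param f group-size fraction (default 0.666)
#' @param ... further arguments to [risk_group_size()]
#' @return list with `strength` (repeats x models) and `p` (models x
#'   models one-sided p-values)
#' @export
compare_feature_sets <- function(preds_by_model, outcomes, f = 0.666,
                                 ...) {
  reps <- vapply(preds_by_model, ncol, 0L)
  if (any(reps < 3L)) stop("need >= 3 repeats per model")
  N <- nrow(preds_by_model[[1L]])
  size <- risk_group_size(N, f, ...)
  strength <- vapply(preds_by_model, function(P)
    vapply(seq_len(ncol(P)), function(r)
      risk_split_strength(P[, r], outcomes, size), 0),
    numeric(ncol(preds_by_model[[1L]])))
  m <- length(preds_by_model)
  pmat <- matrix(NA_real_, m, m,
                 dimnames = list(names(preds_by_model),
                                 names(preds_by_model)))
  for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
    pmat[i, j] <- suppressWarnings(
      stats::wilcox.test(strength[, i], strength[, j],
                         alternative = "greater")$p.value)
  list(strength = strength, p = pmat, group_size = size)
}

#' Validate PCMs on an external cohort
#'
#' Recomputes MPS on the external cohort and stratifies at the listed
#' group sizes. A module is prognostic externally when any size gives a
#' log-rank p below `p_cut` or an |log2 HR| above `lhr_cut`; it is
#' consistent when, in addition, the effect direction (sign of the Wald
#' z) matches the discovery cohort. Modules with under half their genes
#' in the external universe are flagged not evaluable. Optionally, the
#' enrichment of PCMs among externally prognostic modules is assessed by
#' resampling equally many non-PCM modules.
#'
#' @param catalog catalog restricted to the PCMs under validation
#' @param directions named sign vector (+1/-1) of the discovery-cohort
#'   effect (e.g. `sign(full_wald_z)` from [discover_pcms()])
#' @param x_ext external `ExpressionMatrix` (raw; standardized
#'   internally)
#' @param outcomes_ext external outcomes
#' @param sizes per-arm group sizes (>= 20 each enforced by the caller's
#'   schedule)
#' @param Ne,n_rand,sig_level,seed scoring parameters
#' @param p_cut,lhr_cut external prognostic thresholds (0.05, 0.4)
#' @param non_pcm_pool optional catalog of non-PCM modules for the
#'   enrichment resampling null
#' @param n_resample resamples for the enrichment test (default 1000)
#' @return data.frame per module: `evaluable`, `prognostic`,
#'   `consistent`, `best_p`, `best_log2_hr`; enrichment p (when
#'   computed) in `attr(, "enrichment_p")`
#' @export
external_validation <- function(catalog, directions, x_ext, outcomes_ext,
                                sizes, Ne = 10, n_rand = 1000,
                                sig_level = 0.01, seed = 1,
                                p_cut = 0.05, lhr_cut = 0.4,
                                non_pcm_pool = NULL, n_resample = 1000) {
  xz <- standardize(x_ext)
  eval_catalog <- function(cat, P) {
    vapply(module_names(cat), function(mod) {
      if (!mod %in% rownames(P$mps)) return(c(0, NA, NA, NA))
      best <- list(p = Inf, lhr = 0, z = NA_real_)
      for (k in sizes) {
        lab <- stratify_by_mps(P$mps[mod, ], k)
        if (is.null(lab)) next
        cmp <- compare_survival(lab, outcomes_ext)
        if (!is.na(cmp$logrank_p) && cmp$logrank_p < best$p)
          best <- list(p = cmp$logrank_p, lhr = cmp$log2_hr, z = cmp$wald_z)
      }
      prog <- is.finite(best$p) &&
        (best$p < p_cut || (!is.na(best$lhr) && abs(best$lhr) > lhr_cut))
      c(as.numeric(prog), best$p, best$lhr, best$z)
    }, numeric(4))
  }

  coverage <- vapply(catalog$modules, function(m)
    mean(m$genes %in% x_ext$gene_ids), 0)
  evaluable <- coverage >= 0.5
  if (any(evaluable)) {
    cat_ok <- module_catalog(unname(catalog$modules[evaluable]))
    P <- score_cohort(cat_ok, xz, Ne = Ne, n_rand = n_rand, seed = seed,
                      sig_level = sig_level)
    stats_ <- matrix(c(0, NA, NA, NA), 4, length(catalog$modules),
                     dimnames = list(NULL, module_names(catalog)))
    stats_[, module_names(cat_ok)] <- eval_catalog(cat_ok, P)
  } else {
    stats_ <- matrix(c(0, NA, NA, NA), 4, length(catalog$modules))
  }
  res <- data.frame(
    module = module_names(catalog),
    evaluable = evaluable,
    coverage = coverage,
    prognostic = evaluable & (stats_[1, ] > 0),
    best_p = stats_[2, ],
    best_log2_hr = stats_[3, ],
    external_z = stats_[4, ],
    row.names = NULL)
  dir_ref <- directions[res$module]
  res$consistent <- res$prognostic &
    !is.na(res$external_z) & sign(res$external_z) == sign(dir_ref)

  if (!is.null(non_pcm_pool)) {
    P_pool <- score_cohort(non_pcm_pool, xz, Ne = Ne, n_rand = n_rand,
                           seed = seed, sig_level = sig_level)
    pool_prog <- eval_catalog(non_pcm_pool, P_pool)[1, ] > 0
    n_pick <- sum(res$evaluable)
    obs <- sum(res$prognostic)
    null_counts <- with_seed(derive_seed(seed, 37L), {
      vapply(seq_len(n_resample), function(i)
        sum(sample(pool_prog, n_pick, replace = n_pick > length(pool_prog))),
        0)
    })
    attr(res, "enrichment_p") <-
      (1 + sum(null_counts >= obs)) / (n_resample + 1)
  }
  res
}

#' Mid-rank ROC AUC of positive vs negative scores
#'
#' The Mann-Whitney form: AUC = U / (n_pos * n_neg) with mid-ranks on
#' ties.
#'
#' @param pos,neg numeric score vectors
#' @return AUC in [0, 1]
#' @export
roc_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos)
  nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' AUC of external prognostic validation against randomized profiles
#'
#' Positives are the given modules scored by the significance of their
#' external survival stratification (-log10 log-rank p at the group
#' size). Negatives are built per repeat by randomizing each sample's
#' transcriptomic profile (shuffling the z-scores within every sample,
#' which destroys module coherence but preserves each sample's score
#' distribution) and putting `n_neg` modules through the identical
#' scoring procedure on the randomized matrix. Returns one mid-rank AUC
#' per repeat.
#'
#' @param catalog positive modules
#' @param x_ext external `ExpressionMatrix` (raw)
#' @param outcomes_ext external outcomes
#' @param k per-arm group size for the stratifications
#' @param n_neg negatives per repeat (default 100)
#' @param repeats repetitions (default 10)
#' @param Ne,n_rand,sig_level,seed scoring parameters
#' @return numeric vector of AUCs, length `repeats`
#' @export
validation_auc <- function(catalog, x_ext, outcomes_ext, k,
                           n_neg = 100, repeats = 10,
                           Ne = 10, n_rand = 1000, sig_level = 0.01,
                           seed = 1) {
  if (n_neg < 10) stop("n_neg must be >= 10")
  xz <- standardize(x_ext)
  cache <- new.env(parent = emptyenv())
  score_matrix <- function(P) {
    apply(P$mps, 1L, function(v) {
      lab <- stratify_by_mps(v, k)
      if (is.null(lab)) return(0)
      p <- compare_survival(lab, outcomes_ext)$logrank_p
      if (is.na(p)) 0 else -log10(p)
    })
  }
  P <- score_cohort(catalog, xz, Ne = Ne, n_rand = n_rand, seed = seed,
                    sig_level = sig_level, null_cache = cache)
  pos <- score_matrix(P)
  # negative modules: the positives recycled up to n_neg
  neg_mods <- with_seed(derive_seed(seed, 43L), {
    idx <- sample(rep_len(seq_along(catalog$modules), n_neg))
    mods <- catalog$modules[idx]
    lapply(seq_along(mods), function(i)
      gene_module(sprintf("neg_%03d", i), mods[[i]]$genes,
                  category = mods[[i]]$category))
  })
  neg_cat <- module_catalog(neg_mods)
  vapply(seq_len(repeats), function(rp) {
    vperm <- with_seed(derive_seed(seed, 41L, rp), {
      apply(xz$values, 2L, sample)       # shuffle genes within sample
    })
    dimnames(vperm) <- dimnames(xz$values)
    xp <- expression_matrix(vperm, standardized = TRUE)
    Pn <- score_cohort(neg_cat, xp, Ne = Ne, n_rand = n_rand, seed = seed,
                       sig_level = sig_level, null_cache = cache)
    neg <- score_matrix(Pn)
    roc_auc(pos, neg)
  }, 0)
}
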