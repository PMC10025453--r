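#' Stratify a cohort by one module's perturbation scores
#'
#' The MPS+ arm is the `k` samples with the largest positive scores and
#' the MPS- arm the `k` most negative; every other sample is `"none"`.
#' Requires at least `k` samples of each polarity, otherwise the
#' (module, k) combination is skipped (`NULL` returned). Ties are broken
#' by sample order.
#'
#' @param mps_row named per-sample numeric vector of MPS values
#' @param k per-arm group size
#' @return named character vector of labels, or `NULL` when skipped
#' @export
stratify_by_mps <- function(mps_row, k) {
  if (k <= 0) stop("k must be positive")
  ids <- names(mps_row)
  if (is.null(ids)) stop("`mps_row` must be named by sample id")
  pos <- which(mps_row > 0)
  neg <- which(mps_row < 0)
  if (length(pos) < k || length(neg) < k) return(NULL)
  plus <- pos[order(-mps_row[pos], pos)][seq_len(k)]
  minus <- neg[order(mps_row[neg], neg)][seq_len(k)]
  lab <- stats::setNames(rep("none", length(mps_row)), ids)
  lab[plus] <- "plus"
  lab[minus] <- "minus"
  lab
}

#' Compare survival between the plus and minus arms
#'
#' Log-rank test (two-group) and a Cox proportional-hazards fit on the
#' arm indicator (Efron ties). Orientation: `log2_hr > 0` (and
#' `wald_z > 0`) mean the plus arm survives longer, i.e. `log2_hr` is
#' minus the log2 Cox hazard ratio of plus relative to minus. Kaplan-Meier
#' medians that are never reached are reported as `NA`.
#'
#' @param labels named character vector with values `"plus"`, `"minus"`,
#'   `"none"`
#' @param outcomes data.frame with `sample_id`, `time`, `event`
#' @return list of class `survival_comparison`: `logrank_p`, `cox_p`,
#'   `wald_z`, `log2_hr`, `median_plus`, `median_minus`, `n_plus`,
#'   `n_minus`, `n_events`, `defined`
#' @export
compare_survival <- function(labels, outcomes) {
  idx <- match(names(labels), outcomes$sample_id)
  keep <- labels %in% c("plus", "minus") & !is.na(idx)
  arm <- factor(labels[keep], levels = c("minus", "plus"))
  time <- outcomes$time[idx[keep]]
  event <- outcomes$event[idx[keep]]
  out <- list(logrank_p = NA_real_, cox_p = NA_real_, wald_z = NA_real_,
              log2_hr = NA_real_, median_plus = NA_real_,
              median_minus = NA_real_,
              n_plus = sum(arm == "plus"), n_minus = sum(arm == "minus"),
              n_events = sum(event), defined = FALSE)
  class(out) <- "survival_comparison"
  if (out$n_plus == 0L || out$n_minus == 0L || out$n_events == 0L)
    return(out)
  sv <- survival::Surv(time, event)
  sd_ <- survival::survdiff(sv ~ arm)
  out$logrank_p <- stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
  # complete separation between arms drives the Cox coefficient to the
  # boundary; routine in extreme strata, so the monotone-likelihood
  # warning is absorbed (the guarded Wald summaries below still apply)
  cx <- tryCatch(
    withCallingHandlers(
      survival::coxph(sv ~ arm, ties = "efron",
                      control = survival::coxph.control(eps = 1e-7)),
      warning = function(w) {
        if (grepl("Loglik converged before variable", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (!is.null(cx)) {
    sm <- summary(cx)$coefficients
    beta <- sm[1L, "coef"]         # log hazard of plus relative to minus
    if (is.finite(beta)) {
      out$log2_hr <- -beta / log(2)
      out$wald_z <- -sm[1L, "z"]
      out$cox_p <- sm[1L, "Pr(>|z|)"]
    }
  }
  sf <- survival::survfit(sv ~ arm)
  med <- summary(sf)$table[, "median"]
  out$median_minus <- unname(med[1L])
  out$median_plus <- unname(med[2L])
  out$defined <- TRUE
  out
}

# Log-rank p for a prelabeled two-group split; minimal fast path used by
# the resampling null.
logrank_p <- function(time, event, grp) {
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
}

# Null distribution of log-rank p for random disjoint k/k arms drawn
# from `outcomes`. Sorted ascending. Used by empirical_fdr and shared
# across modules inside discover_pcms.
logrank_null_pvals <- function(outcomes, k, n_null, seed) {
  n <- nrow(outcomes)
  if (2 * k > n) stop("2k exceeds cohort size")
  time <- outcomes$time
  event <- outcomes$event
  ps <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      idx <- sample.int(n, 2L * k)
      grp <- rep(c(0L, 1L), each = k)
      logrank_p(time[idx], event[idx], grp)
    }, 0)
  })
  sort(ps)
}

#' Empirical FDR of an observed log-rank p against a resampling null
#'
#' Draws `n_null` random disjoint patient-arm pairs of size `k` from the
#' cohort, computes the log-rank p of each, and reports the fraction of
#' null p-values at or below the observed one (the exceedance fraction
#' the source analysis labels FDR). `method = "label_switch"` instead
#' permutes the observed arm labels among the labeled patients. A
#' pseudo-count variant `(1 + #null <= p) / (1 + n_null)` guards exact
#' zeros; default off.
#'
#' @param observed_p observed log-rank p-value
#' @param outcomes data.frame with `sample_id`, `time`, `event`
#' @param k per-arm size
#' @param n_null number of null resamples (>= 100)
#' @param seed integer seed
#' @param method `"random_arms"` (default) or `"label_switch"`
#' @param labels labels vector, required for `"label_switch"`
#' @param pseudo_count logical; add-one correction (default `FALSE`)
#' @param null_p optional precomputed sorted null p-values (overrides the
#'   resampling; used to share one null across modules)
#' @return FDR in [0, 1]
#' @export
empirical_fdr <- function(observed_p, outcomes, k, n_null = 1000, seed = 1,
                          method = c("random_arms", "label_switch"),
                          labels = NULL, pseudo_count = FALSE,
                          null_p = NULL) {
  method <- match.arg(method)
  if (is.null(null_p)) {
    if (n_null < 100) stop("n_null must be >= 100")
    if (method == "random_arms") {
      null_p <- logrank_null_pvals(outcomes, k, n_null, seed)
    } else {
      if (is.null(labels)) stop("label_switch needs `labels`")
      idx <- match(names(labels), outcomes$sample_id)
      keep <- labels %in% c("plus", "minus") & !is.na(idx)
      time <- outcomes$time[idx[keep]]
      event <- outcomes$event[idx[keep]]
      g0 <- labels[keep]
      null_p <- with_seed(seed, {
        sort(vapply(seq_len(n_null), function(i)
          logrank_p(time, event, sample(g0)), 0))
      })
    }
  }
  n <- length(null_p)
  hits <- sum(null_p <= observed_p)
  if (pseudo_count) (1 + hits) / (1 + n) else hits / n
}

#' Prognosis of a single-locus measurement
#'
#' Stratifies the cohort on one gene-level feature: mutant vs wild-type
#' (`mode = "mutation"`, binary input), relative amplification vs
#' deletion (`"cna"`, split at 0), or relative activation vs repression
#' (`"expression"`, z-scores split at 0). The comparison is made only
#' when both arms hold more than `min_arm` patients; a Cox p below 0.05
#' flags the locus prognostic. The plus arm is mutant / amplified /
#' activated.
#'
#' @param feature named per-sample numeric vector
#' @param mode `"mutation"`, `"cna"`, or `"expression"`
#' @param outcomes data.frame with `sample_id`, `time`, `event`
#' @param min_arm minimum patients per arm, exclusive (default 15)
#' @return list with `skipped`, and when evaluated a
#'   `survival_comparison` under `$comparison` plus `prognostic`
#' @export
single_locus_prognosis <- function(feature,
                                   mode = c("mutation", "cna", "expression"),
                                   outcomes, min_arm = 15) {
  mode <- match.arg(mode)
  if (is.null(names(feature))) stop("`feature` must be named by sample id")
  if (mode == "mutation") {
    vals <- feature[!is.na(feature)]
    if (!all(vals %in% c(0, 1)))
      stop("mutation mode expects a binary 0/1 vector")
    lab <- ifelse(feature == 1, "plus", "minus")
  } else {
    lab <- rep("none", length(feature))
    lab[feature > 0] <- "plus"
    lab[feature < 0] <- "minus"
  }
  names(lab) <- names(feature)
  lab[is.na(feature)] <- "none"
  n_plus <- sum(lab == "plus")
  n_minus <- sum(lab == "minus")
  if (n_plus <= min_arm || n_minus <= min_arm)
    return(list(skipped = TRUE, n_plus = n_plus, n_minus = n_minus))
  cmp <- compare_survival(lab, outcomes)
  list(skipped = FALSE, mode = mode, comparison = cmp,
       prognostic = isTRUE(cmp$cox_p < 0.05),
       n_plus = n_plus, n_minus = n_minus)
}

#' Combine Wald z-statistics by Stouffer's method
#'
#' @param wald_zs numeric vector of z-statistics
#' @return sum(z) / sqrt(k)
#' @export
stouffer_combine <- function(wald_zs) {
  if (length(wald_zs) == 0L) stop("no z-statistics to combine")
  sum(wald_zs) / sqrt(length(wald_zs))
}

#' Module-vs-locus prognostic strength ratio
#'
#' log2 of the absolute Stouffer-combined module Wald z over the best
#' absolute single-locus Wald z (strongest of the expression, copy-number
#' and mutation stratifications).
#'
#' @param module_zs Wald z-statistics of the driver's modules
#' @param locus_zs Wald z-statistics of the locus stratifications
#' @return log2 ratio; `Inf` (with a warning) on a zero denominator
#' @export
module_vs_locus_ratio <- function(module_zs, locus_zs) {
  if (!length(module_zs) || !length(locus_zs))
    stop("need at least one module and one locus statistic")
  num <- abs(stouffer_combine(module_zs))
  den <- max(abs(locus_zs))
  if (den == 0) {
    warning("zero locus statistic; ratio is infinite")
    return(Inf)
  }
  log2(num / den)
}

#' Multivariate Cox model: MPS arm plus clinical confounders
#'
#' Fits arm + covariates jointly; rows with missing covariates are
#' dropped (count reported). Covariates collinear with the design (NA
#' coefficients) are flagged.
#'
#' @param labels named `"plus"`/`"minus"`/`"none"` vector
#' @param outcomes data.frame with `sample_id`, `time`, `event`
#' @param covariates data.frame keyed by `sample_id`
#' @return data.frame of per-term `hr`, `p`, `singular`, with attributes
#'   `arm_significant` (arm term p < 0.05) and `n_dropped`
#' @export
multivariate_cox <- function(labels, outcomes, covariates) {
  idx <- match(names(labels), outcomes$sample_id)
  keep <- labels %in% c("plus", "minus") & !is.na(idx)
  df <- data.frame(time = outcomes$time[idx[keep]],
                   event = outcomes$event[idx[keep]],
                   arm = factor(labels[keep], levels = c("minus", "plus")))
  cv <- covariates[match(names(labels)[keep], covariates$sample_id),
                   setdiff(names(covariates), "sample_id"), drop = FALSE]
  cv[] <- lapply(cv, function(col)
    if (is.character(col)) factor(col) else col)
  df <- cbind(df, cv)
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  fit <- survival::coxph(survival::Surv(time, event) ~ .,
                         data = df, ties = "efron",
                         control = survival::coxph.control(eps = 1e-7))
  sm <- summary(fit)$coefficients
  res <- data.frame(term = rownames(sm),
                    hr = exp(sm[, "coef"]),
                    p = sm[, "Pr(>|z|)"],
                    singular = !is.finite(sm[, "coef"]) |
                      !is.finite(sm[, "se(coef)"]),
                    row.names = NULL)
  # terms dropped entirely by coxph (aliased) are singular too
  aliased <- setdiff(names(stats::coef(fit))[is.na(stats::coef(fit))],
                     res$term)
  if (length(aliased))
    res <- rbind(res, data.frame(term = aliased, hr = NA, p = NA,
                                 singular = TRUE))
  arm_row <- grep("^armplus$", res$term)
  attr(res, "arm_significant") <-
    length(arm_row) == 1L && isTRUE(res$p[arm_row] < 0.05)
  attr(res, "n_dropped") <- n_dropped
  if (n_dropped > 0) message(n_dropped, " row(s) with missing covariates dropped")
  res
}
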