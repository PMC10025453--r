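#' Quantize a sample's z-scores into equally populated bins
#'
#' Bins are contiguous in rank order; sizes differ by at most one, with
#' the extra elements in the lowest-index (lowest-expression) bins. Ties
#' are broken by stable input order.
#'
#' @param z_values per-gene numeric vector
#' @param Ne number of bins (>= 2)
#' @return integer vector of bin indices in 1..Ne (1 = lowest expression)
#' @export
quantize_sample <- function(z_values, Ne) {
  n <- length(z_values)
  if (Ne < 2L) stop("Ne must be >= 2")
  if (Ne > n) stop("Ne exceeds the number of genes")
  ord <- order(z_values, seq_len(n))  # stable: ties by input index
  bins <- integer(n)
  bins[ord] <- rep.int(seq_len(Ne), bin_sizes(n, Ne))
  bins
}

# Equal-population bin-size profile: extras go to the lowest bins.
bin_sizes <- function(n, Ne) {
  base <- n %/% Ne
  rem <- n %% Ne
  sizes <- rep.int(base, Ne)
  if (rem > 0L) sizes[seq_len(rem)] <- base + 1L
  sizes
}

#' Mutual information of a 2 x Ne joint-counts table
#'
#' I = sum_ij P(i,j) log( P(i,j) / (P(i) P(j)) ) in nats, with 0*log(0)
#' terms contributing 0. Row i is module membership (0/1), column j the
#' expression bin.
#'
#' @param counts non-negative integer matrix with 2 rows
#' @return mutual information in nats (>= 0)
#' @export
mutual_information <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != 2L)
    stop("`counts` must be a 2 x Ne matrix")
  if (any(counts < 0)) stop("negative counts")
  n <- sum(counts)
  if (n <= 0) stop("empty table")
  p <- counts / n
  pi_ <- rowSums(p)
  pj <- colSums(p)
  e <- outer(pi_, pj)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

# MI for module-in-bin count vectors, vectorized over columns of `cmat`.
# cmat: Ne x k matrix of module-gene counts per bin; b: bin sizes; m:
# module size; N: total genes. Returns k MI values (nats). Uses
# I = sum_j xlx(p1j) + xlx(p0j) - sum_j xlx(pj) - xlx(q1) - xlx(q0)
# with xlx(x) = x log x (0 at 0); every bin is non-empty so pj > 0.
mi_from_counts <- function(cmat, b, m, N) {
  cmat <- as.matrix(cmat)
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  p1 <- cmat / N
  p0 <- (b - cmat) / N
  pj <- b / N
  q1 <- m / N
  colSums(xlx(p1)) + colSums(xlx(p0)) -
    sum(xlx(pj)) - xlx(q1) - xlx(1 - q1)
}

#' Permutation null model for module-vs-expression mutual information
#'
#' Each null draw permutes the membership vector uniformly at random
#' against the fixed equal-population binning (equivalently, permutes the
#' expression vector) and recomputes MI. Because the bin-size profile is
#' a function of (N, Ne) only, the null depends on the data only through
#' (N, Ne, module size), so one model serves every sample and module of
#' that size.
#'
#' Significance of an observed MI is the add-one empirical p-value
#' `(1 + #null >= obs) / (n_rand + 1) <= sig_level` — the standard
#' estimator of "within the top 1% of the null" that keeps the false-call
#' rate at or below `sig_level` for any `n_rand`.
#'
#' @param N number of genes in the universe
#' @param m module size within the universe
#' @param Ne number of expression bins
#' @param n_rand number of randomizations (>= 100; default 1000)
#' @param seed integer seed
#' @param sig_level empirical-p threshold (default 0.01, i.e. top 1%)
#' @return an object of class `NullModel` with fields `mu`, `sigma`,
#'   `top_quantile_cut` (the order statistic the gate corresponds to),
#'   `null_sorted`, `n_randomizations`, `seed`
#' @export
null_model <- function(N, m, Ne = 10, n_rand = 1000, seed = 1,
                       sig_level = 0.01) {
  if (n_rand < 100) stop("n_rand must be >= 100")
  if (m > N) stop("module size exceeds universe")
  b <- bin_sizes(N, Ne)
  bl <- rep.int(seq_len(Ne), b)
  draws <- with_seed(seed, {
    vapply(seq_len(n_rand), function(i)
      tabulate(bl[sample.int(N, m)], Ne), numeric(Ne))
  })
  null_mi <- mi_from_counts(matrix(draws, nrow = Ne), b, m, N)
  ns <- sort(null_mi)
  # largest k with (1 + #null >= obs)/(n_rand + 1) > sig_level boundary
  k_allow <- floor(sig_level * (n_rand + 1)) - 1  # max #null >= obs
  cut <- if (k_allow < 0) Inf else ns[n_rand - k_allow]
  structure(list(mu = mean(null_mi), sigma = stats::sd(null_mi),
                 top_quantile_cut = cut, null_sorted = ns,
                 n_randomizations = n_rand, sig_level = sig_level,
                 seed = seed, N = N, m = m, Ne = Ne),
            class = "NullModel")
}

# Significance gate: add-one empirical p <= sig_level (vectorized in obs).
null_significant <- function(nm, obs) {
  n_ge <- vapply(obs, function(o) sum(nm$null_sorted >= o), 0)
  (1 + n_ge) / (nm$n_randomizations + 1) <= nm$sig_level
}

# z-score of observed MI against the null; clipped at 0; 0 when sigma = 0.
null_z <- function(nm, obs) {
  if (!is.finite(nm$sigma) || nm$sigma <= 0) return(rep(0, length(obs)))
  pmax(0, (obs - nm$mu) / nm$sigma)
}

# Fetch (or build) a cached null model keyed by (N, Ne, m, n_rand).
# Seeds are derived from (seed, m) so module order never matters.
get_null <- function(cache, N, m, Ne, n_rand, seed, sig_level) {
  key <- sprintf("N%d_e%d_m%d_r%d_s%g", N, Ne, m, n_rand, sig_level)
  if (!is.null(cache[[key]])) return(cache[[key]])
  nm <- null_model(N, m, Ne = Ne, n_rand = n_rand,
                   seed = derive_seed(seed, 7919L, m), sig_level = sig_level)
  cache[[key]] <- nm
  nm
}

#' Module perturbation score for one module against one sample
#'
#' MPS = sgn(r) * max(0, (I - mu)/sigma) * [MI in the null's top 1%],
#' where I is the mutual information between module membership and the
#' binned z-scores, (mu, sigma) summarize the permutation null, and r is
#' the Pearson correlation between the membership vector and the raw
#' z-scores. A positive score means the module's genes are relatively
#' up-regulated in this sample (activation); negative means repression.
#' With `magnitude = "heaviside"` the magnitude is the 0/1 gate itself
#' rather than the clipped z.
#'
#' @param module a [gene_module()]
#' @param z_values named per-gene z-score vector for one sample (the gene
#'   universe)
#' @param Ne bins (default 10)
#' @param n_rand randomizations (default 1000)
#' @param seed integer seed
#' @param sig_level significance level of the gate (default 0.01)
#' @param magnitude `"gated_z"` (default) or `"heaviside"`
#' @param null optional pre-built [null_model()] for this (N, m, Ne)
#' @return an object of class `ModulePerturbation` with fields `mi`, `z`,
#'   `r`, `significant`, `mps`
#' @export
mps <- function(module, z_values, Ne = 10, n_rand = 1000, seed = 1,
                sig_level = 0.01, magnitude = c("gated_z", "heaviside"),
                null = NULL) {
  magnitude <- match.arg(magnitude)
  genes <- names(z_values)
  if (is.null(genes)) stop("`z_values` must be named by gene id")
  member <- genes %in% module$genes
  m <- sum(member)
  N <- length(z_values)
  if (m < 2L) {
    warning("module '", module$name, "' has <2 genes in universe; mps = 0")
    return(structure(list(mi = NA_real_, z = 0, r = NA_real_,
                          significant = FALSE, mps = 0),
                     class = "ModulePerturbation"))
  }
  bins <- quantize_sample(z_values, Ne)
  b <- bin_sizes(N, Ne)
  cvec <- tabulate(bins[member], Ne)
  mi <- mi_from_counts(matrix(cvec, ncol = 1), b, m, N)
  nm <- null %||% null_model(N, m, Ne = Ne, n_rand = n_rand,
                             seed = derive_seed(seed, 7919L, m),
                             sig_level = sig_level)
  z <- null_z(nm, mi)
  sig <- null_significant(nm, mi)
  r <- suppressWarnings(stats::cor(as.numeric(member), z_values))
  if (is.na(r)) r <- 0
  mag <- if (magnitude == "gated_z") z else as.numeric(z > 0)
  structure(list(mi = mi, z = z, r = r, significant = sig,
                 mps = sign(r) * mag * as.numeric(sig)),
            class = "ModulePerturbation")
}

#' Score a whole catalog against a whole cohort
#'
#' Vectorized [mps()] over modules x samples. Modules with fewer than
#' `min_size` genes in the expression universe are skipped with a
#' warning. Null models are shared across samples and across modules of
#' equal size (exact; see [null_model()]).
#'
#' @param catalog a [module_catalog()]
#' @param x standardized `ExpressionMatrix`
#' @param Ne bins (default 10)
#' @param n_rand randomizations per null (default 1000)
#' @param seed integer seed
#' @param sig_level gate level (default 0.01)
#' @param magnitude `"gated_z"` or `"heaviside"`
#' @param min_size minimum in-universe module size (default 5)
#' @param null_cache optional environment reused across calls (e.g. CV
#'   folds over the same gene universe) to share null models
#' @return an object of class `PerturbationMatrix`: list with `mps`,
#'   `significant`, `z`, `r`, `mi` (modules x samples matrices) plus the
#'   scoring parameters
#' @export
score_cohort <- function(catalog, x, Ne = 10, n_rand = 1000, seed = 1,
                         sig_level = 0.01,
                         magnitude = c("gated_z", "heaviside"),
                         min_size = 5, null_cache = NULL) {
  magnitude <- match.arg(magnitude)
  if (!x$standardized)
    stop("score_cohort expects standardized expression; call standardize()")
  v <- x$values
  N <- nrow(v)
  S <- ncol(v)
  cache <- null_cache %||% new.env(parent = emptyenv())
  sizes <- vapply(catalog$modules, function(m)
    sum(m$genes %in% x$gene_ids), 0L)
  small <- sizes < min_size
  if (any(small))
    warning(sum(small), " module(s) below min_size in universe skipped: ",
            paste(utils::head(names(catalog$modules)[small], 5),
                  collapse = ", "),
            if (sum(small) > 5) ", ...")
  keep <- names(catalog$modules)[!small]
  if (!length(keep)) stop("no scorable modules")

  bins <- apply(v, 2L, quantize_sample, Ne = Ne)      # N x S
  b <- bin_sizes(N, Ne)
  # per-sample moments for fast Pearson r against binary membership
  zsum <- colSums(v)
  zss <- colSums(v * v)
  z_mean <- zsum / N
  z_var <- (zss - N * z_mean^2) / (N - 1)

  mk_mat <- function() matrix(NA_real_, length(keep), S,
                              dimnames = list(keep, x$sample_ids))
  M_mi <- mk_mat(); M_z <- mk_mat(); M_r <- mk_mat()
  M_sig <- matrix(FALSE, length(keep), S,
                  dimnames = list(keep, x$sample_ids))
  for (nm_i in keep) {
    mod <- catalog$modules[[nm_i]]
    member_idx <- which(x$gene_ids %in% mod$genes)
    m <- length(member_idx)
    bm <- bins[member_idx, , drop = FALSE]
    cmat <- vapply(seq_len(Ne), function(j) colSums(bm == j),
                   numeric(S))                         # S x Ne
    mi <- mi_from_counts(t(cmat), b, m, N)
    nullm <- get_null(cache, N, m, Ne, n_rand, seed, sig_level)
    M_mi[nm_i, ] <- mi
    M_z[nm_i, ] <- null_z(nullm, mi)
    M_sig[nm_i, ] <- null_significant(nullm, mi)
    # cov(member, z) per sample = (sum_member z)/ (N-1) - m*z_mean/(N-1)*...
    msum <- colSums(v[member_idx, , drop = FALSE])
    covv <- (msum - m * z_mean) / (N - 1)
    sd_mem <- sqrt(m / N * (1 - m / N) * N / (N - 1))
    r <- covv / (sd_mem * sqrt(z_var))
    r[!is.finite(r)] <- 0
    M_r[nm_i, ] <- r
  }
  mag <- if (magnitude == "gated_z") M_z else (M_z > 0) * 1
  structure(list(mps = sign(M_r) * mag * M_sig,
                 significant = M_sig, z = M_z, r = M_r, mi = M_mi,
                 Ne = Ne, n_rand = n_rand, seed = seed,
                 sig_level = sig_level, magnitude = magnitude),
            class = "PerturbationMatrix")
}

#' @export
print.PerturbationMatrix <- function(x, ...) {
  cat(sprintf(
    "PerturbationMatrix: %d modules x %d samples (Ne=%d, n_rand=%d); %.2f%% significant\n",
    nrow(x$mps), ncol(x$mps), x$Ne, x$n_rand, 100 * mean(x$significant)))
  invisible(x)
}

#' Per-sample MPS labels for one module
#'
#' @param P a `PerturbationMatrix`
#' @return character matrix of `"plus"`, `"minus"`, `"none"`
#' @export
mps_labels <- function(P) {
  lab <- matrix("none", nrow(P$mps), ncol(P$mps), dimnames = dimnames(P$mps))
  lab[P$mps > 0] <- "plus"
  lab[P$mps < 0] <- "minus"
  lab
}

#' Cohort-specific modules: strong, stable perturbation
#'
#' Selects modules with high mean absolute MPS (top `mean_quantile`) and
#' low variance (bottom `var_quantile`) within a cohort, treating the
#' activation (MPS+) and repression (MPS-) streams separately and
#' returning the union.
#'
#' @param P a `PerturbationMatrix`
#' @param mean_quantile top fraction by mean |MPS| (default 0.5)
#' @param var_quantile bottom fraction by variance (default 0.4)
#' @return character vector of module names
#' @export
cohort_specific_modules <- function(P, mean_quantile = 0.5,
                                    var_quantile = 0.4) {
  if (mean_quantile <= 0 || mean_quantile > 1 ||
      var_quantile <= 0 || var_quantile > 1)
    stop("quantiles must be in (0, 1]")
  pick_stream <- function(v) {           # v: modules x samples, >= 0
    mu <- rowMeans(v)
    va <- apply(v, 1L, stats::var)
    active <- mu > 0
    if (!any(active)) return(character())
    mu_cut <- stats::quantile(mu[active], 1 - mean_quantile, names = FALSE)
    va_cut <- stats::quantile(va[active], var_quantile, names = FALSE)
    rownames(v)[active & mu >= mu_cut & va <= va_cut]
  }
  union(pick_stream(pmax(P$mps, 0)), pick_stream(pmax(-P$mps, 0)))
}

#' Tissue-specific modules: tumor vs matched normal polarity flips
#'
#' A module is selected when, in at least `frac` of patient-matched
#' (tumor, normal) pairs, both scores are significant and of opposite
#' sign (MPS_tumor * MPS_normal < 0).
#'
#' @param P_tumor,P_normal `PerturbationMatrix` objects whose columns
#'   share patient ids
#' @param frac required fraction of discordant pairs (default 0.75)
#' @return character vector of module names
#' @export
tissue_specific_modules <- function(P_tumor, P_normal, frac = 0.75) {
  pts <- intersect(colnames(P_tumor$mps), colnames(P_normal$mps))
  if (length(pts) < 1L) stop("no matched patient pairs")
  mods <- intersect(rownames(P_tumor$mps), rownames(P_normal$mps))
  mt <- P_tumor$mps[mods, pts, drop = FALSE]
  mn <- P_normal$mps[mods, pts, drop = FALSE]
  ok <- (mt * mn < 0) &
    P_tumor$significant[mods, pts, drop = FALSE] &
    P_normal$significant[mods, pts, drop = FALSE]
  mods[rowMeans(ok) >= frac]
}
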