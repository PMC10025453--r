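#' Collapse AJCC sub-stages to the four discretized stages
#'
#' I/IA/IB -> I, II/IIA/IIB/IIC -> II, III/IIIA-C -> III, IV/IVA-C -> IV.
#' Unrecognized values become `NA`.
#'
#' @param stage character vector of AJCC stages
#' @return factor with levels I, II, III, IV
#' @export
collapse_stage <- function(stage) {
  s <- toupper(trimws(as.character(stage)))
  s <- sub("^STAGE\\s*", "", s)
  out <- rep(NA_character_, length(s))
  out[grepl("^IV", s)] <- "IV"
  out[grepl("^III", s) & is.na(out)] <- "III"
  out[grepl("^II", s) & is.na(out)] <- "II"
  out[grepl("^I", s) & is.na(out)] <- "I"
  factor(out, levels = c("I", "II", "III", "IV"))
}

# Age buckets used for sub-cohorts and clinical features.
age_bins <- function(age) {
  cut(age, breaks = c(-Inf, 30, 60, Inf),
      labels = c("<30", "30-60", ">60"), right = FALSE)
}

#' Select prominently mutated genes
#'
#' Keeps genes mutated in at least `min_frac` of patients, ranks them by
#' mutation count per base pair of coding sequence, and returns the top
#' `top_k` after exclusions (TTN by default). Candidates without a
#' coding length are skipped with a warning.
#'
#' @param snv binary genes x samples mutation matrix
#' @param coding_lengths named per-gene coding lengths (bp, > 0)
#' @param min_frac minimum mutated fraction (default 0.05)
#' @param top_k genes to return (default 3)
#' @param exclude gene ids never returned (default `"TTN"`)
#' @return character vector of gene ids, highest density first
#' @export
select_mutated_genes <- function(snv, coding_lengths, min_frac = 0.05,
                                 top_k = 3, exclude = "TTN") {
  frac <- rowMeans(snv > 0)
  cand <- setdiff(rownames(snv)[frac >= min_frac], exclude)
  no_len <- cand[!cand %in% names(coding_lengths) |
                   is.na(coding_lengths[cand])]
  if (length(no_len)) {
    warning("no coding length for: ", paste(no_len, collapse = ", "),
            "; skipped")
    cand <- setdiff(cand, no_len)
  }
  if (!length(cand)) return(character())
  density <- rowSums(snv[cand, , drop = FALSE] > 0) / coding_lengths[cand]
  cand[order(-density)][seq_len(min(top_k, length(cand)))]
}

#' Categorize per-sample copy-number values
#'
#' Within the positive values, the top `deep_quantile` fraction are
#' `deep_amplified` and the rest `amplified`; mirrored for the non-zero
#' negative values (`deep_deleted` / `deleted`). Zeros stay
#' uncategorized (`NA`).
#'
#' @param values named per-sample numeric CNA vector
#' @param deep_quantile fraction in (0, 0.5] (0.25 for sub-cohorts,
#'   0.33 for risk-model features)
#' @return named factor with the four categories
#' @export
categorize_cna <- function(values, deep_quantile = 0.25) {
  if (deep_quantile <= 0 || deep_quantile > 0.5)
    stop("deep_quantile must be in (0, 0.5]")
  out <- rep(NA_character_, length(values))
  pos <- which(values > 0)
  neg <- which(values < 0)
  if (length(pos)) {
    cut_hi <- stats::quantile(values[pos], 1 - deep_quantile, names = FALSE)
    out[pos] <- ifelse(values[pos] >= cut_hi, "deep_amplified", "amplified")
  }
  if (length(neg)) {
    cut_lo <- stats::quantile(values[neg], deep_quantile, names = FALSE)
    out[neg] <- ifelse(values[neg] <= cut_lo, "deep_deleted", "deleted")
  }
  stats::setNames(
    factor(out, levels = c("deep_amplified", "amplified",
                           "deleted", "deep_deleted")),
    names(values))
}

#' Select prominent copy-number genes by rank product
#'
#' RP(g) is the product of the gene's ascending ranks by absolute median
#' CNA and by CNA standard deviation across samples. From the
#' `pool_size` genes with the highest RP (optionally filtered to a
#' cancer-gene whitelist), genes are picked greedily by RP while
#' discarding candidates whose CNA profiles correlate with an already
#' picked gene beyond `corr_cut` in absolute value.
#'
#' @param cna genes x samples numeric matrix
#' @param whitelist optional gene ids to restrict the pool to
#' @param corr_cut redundancy threshold on |Pearson r| (default 0.5)
#' @param top_k genes to return (default 3)
#' @param pool_size size of the initial high-RP pool (default 1000)
#' @return character vector of selected gene ids
#' @export
rank_product_cna <- function(cna, whitelist = NULL, corr_cut = 0.5,
                             top_k = 3, pool_size = 1000) {
  if (nrow(cna) < 2L) stop("need at least 2 genes")
  med <- abs(apply(cna, 1L, stats::median))
  sdv <- apply(cna, 1L, stats::sd)
  rp <- rank(med) * rank(sdv)
  pool <- rownames(cna)[order(-rp)][seq_len(min(pool_size, nrow(cna)))]
  if (!is.null(whitelist)) pool <- pool[pool %in% whitelist]
  if (!length(pool)) {
    warning("empty candidate pool after filtering")
    return(character())
  }
  picked <- character()
  while (length(pool) && length(picked) < top_k) {
    g <- pool[1L]
    picked <- c(picked, g)
    if (length(pool) > 1L) {
      cors <- abs(stats::cor(cna[g, ], t(cna[pool[-1L], , drop = FALSE])))
      cors[is.na(cors)] <- 0
      pool <- pool[-1L][cors <= corr_cut]
    } else pool <- character()
  }
  picked
}

#' Partition a cohort into clinically and molecularly defined sub-groups
#'
#' Emits one sub-cohort per value of each clinical attribute (stage
#' values collapsed to I-IV, ages binned <30 / 30-60 / >60), per
#' mutation status of the prominently mutated genes, and per
#' copy-number category of the high-rank-product genes. Sub-cohorts are
#' kept only when they include more than `min_size` samples.
#'
#' @param clinical data.frame keyed by `sample_id`; columns named
#'   `stage` and `age` get the special treatment above
#' @param cna optional genes x samples CNA matrix
#' @param snv optional binary genes x samples mutation matrix
#' @param coding_lengths per-gene coding lengths (needed with `snv`)
#' @param cna_whitelist optional cancer-gene whitelist for the CNA pick
#' @param min_size strict minimum sub-cohort size (default 20)
#' @param deep_quantile see [categorize_cna()]
#' @return list of sub-cohort specs: `attribute`, `value`, `samples`
#' @export
partition_cohort <- function(clinical, cna = NULL, snv = NULL,
                             coding_lengths = NULL, cna_whitelist = NULL,
                             min_size = 20, deep_quantile = 0.25) {
  if (!"sample_id" %in% names(clinical))
    stop("clinical table needs a sample_id column")
  ids <- clinical$sample_id
  specs <- list()
  add <- function(attribute, value, samples) {
    if (length(samples) > min_size)
      specs[[length(specs) + 1L]] <<- list(attribute = attribute,
                                           value = value,
                                           samples = samples)
  }
  for (col in setdiff(names(clinical), "sample_id")) {
    v <- clinical[[col]]
    if (identical(col, "stage")) v <- collapse_stage(v)
    else if (identical(col, "age")) v <- age_bins(v)
    v <- as.factor(v)
    for (lev in levels(droplevels(v)))
      add(col, lev, ids[!is.na(v) & v == lev])
  }
  if (!is.null(snv)) {
    if (is.null(coding_lengths)) stop("snv partitioning needs coding_lengths")
    common <- intersect(colnames(snv), ids)
    for (g in select_mutated_genes(snv[, common, drop = FALSE],
                                   coding_lengths)) {
      mut <- common[snv[g, common] > 0]
      add(paste0(g, "_mutation"), "mutant", mut)
      add(paste0(g, "_mutation"), "wildtype", setdiff(common, mut))
    }
  }
  if (!is.null(cna)) {
    common <- intersect(colnames(cna), ids)
    for (g in rank_product_cna(cna[, common, drop = FALSE],
                               whitelist = cna_whitelist)) {
      cats <- categorize_cna(cna[g, common], deep_quantile)
      for (lev in levels(cats))
        add(paste0(g, "_cna"), lev, common[!is.na(cats) & cats == lev])
    }
  }
  specs
}
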