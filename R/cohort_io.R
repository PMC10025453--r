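#' Read a genes x samples expression TSV
#'
#' Expects a header row of sample ids and a first column of gene ids (or
#' the transposed layout with `transpose = TRUE`). Empty cells and `NA`
#' become explicit missing values.
#'
#' @param path TSV file path
#' @param transpose logical; `TRUE` when the file is samples x genes
#' @return an [expression_matrix()] (unstandardized)
#' @export
read_expression <- function(path, transpose = FALSE) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged TSV: line %d has %d fields, expected %d",
                 bad, nf[bad], nf[1L]))
  }
  df <- utils::read.delim(path, check.names = FALSE, row.names = NULL,
                          na.strings = c("NA", ""), quote = "",
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate row ids in ", basename(path), ": ",
         paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (transpose) m <- t(m)
  expression_matrix(m, standardized = FALSE)
}

#' Write an expression matrix as TSV
#' @param x an `ExpressionMatrix`
#' @param path output path
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = x$gene_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Standardize expression per gene (cohort z-scores)
#'
#' z = (x - mean) / sd per gene row, using cohort statistics or supplied
#' reference statistics (e.g. test-fold samples standardized by
#' training-fold means/SDs). The sample-SD convention (n - 1 denominator)
#' is used and recorded in the output metadata. Zero-variance genes give
#' an all-zero row, and any z that is NA (missing input or sd = 0) is set
#' to 0 so downstream binning sees a complete vector.
#'
#' @param x an `ExpressionMatrix`
#' @param ref_means,ref_sds optional per-gene numeric vectors, aligned to
#'   `x$gene_ids` (same length/order, or named)
#' @return a standardized `ExpressionMatrix`
#' @export
standardize <- function(x, ref_means = NULL, ref_sds = NULL) {
  v <- x$values
  ng <- nrow(v)
  align_ref <- function(r, what) {
    if (length(r) != ng) {
      if (!is.null(names(r)) && all(x$gene_ids %in% names(r)))
        return(unname(r[x$gene_ids]))
      stop(sprintf("`%s` has length %d, expected %d", what, length(r), ng))
    }
    unname(r)
  }
  if (is.null(ref_means) != is.null(ref_sds))
    stop("supply both or neither of `ref_means`, `ref_sds`")
  if (is.null(ref_means)) {
    mu <- rowMeans(v, na.rm = TRUE)
    sdv <- apply(v, 1L, stats::sd, na.rm = TRUE)
  } else {
    mu <- align_ref(ref_means, "ref_means")
    sdv <- align_ref(ref_sds, "ref_sds")
  }
  z <- (v - mu) / sdv
  z[!is.finite(z)] <- 0
  z[is.na(z)] <- 0
  meta <- x$meta
  meta$sd_convention <- "sample (n-1)"
  expression_matrix(z, standardized = TRUE, meta = meta)
}

#' Filter lowly-expressed genes against a sampled background percentile
#'
#' Keeps genes whose mean expression exceeds the given percentile of
#' `n_draws` values sampled uniformly with replacement from the whole
#' (non-missing) matrix. Deterministic given `seed`.
#'
#' @param x unstandardized `ExpressionMatrix`
#' @param n_draws number of background draws (default 1e5)
#' @param percentile fraction in [0, 1); 0 retains every gene
#' @param seed integer seed
#' @return a filtered `ExpressionMatrix`
#' @export
filter_low_expression <- function(x, n_draws = 1e5, percentile = 0.1,
                                  seed = 1) {
  if (x$standardized) stop("filter_low_expression expects raw expression")
  if (percentile < 0 || percentile >= 1)
    stop("`percentile` must be in [0, 1)")
  pool <- x$values[!is.na(x$values)]
  thr <- if (percentile == 0) -Inf else with_seed(seed, {
    stats::quantile(sample(pool, n_draws, replace = TRUE),
                    percentile, names = FALSE)
  })
  keep <- rowMeans(x$values, na.rm = TRUE) > thr
  subset_expression(x, genes = which(keep))
}

#' Read a GMT gene-set file into a module catalog
#'
#' Standard GMT: per line a set name, a description, then tab-separated
#' gene ids. Duplicate genes within a line are deduplicated (reported).
#'
#' @param path GMT file path
#' @param category category assigned to all modules in the file
#' @return a [module_catalog()]
#' @export
read_gmt <- function(path, category = "other") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  mods <- vector("list", length(lines))
  n_dup <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and at least one gene",
                   i, length(f)))
    genes <- f[-(1:2)]
    n_dup <- n_dup + sum(duplicated(genes))
    mods[[i]] <- gene_module(f[[1L]], genes, category = category,
                             source = f[[2L]])
  }
  if (n_dup > 0L)
    message("read_gmt: deduplicated ", n_dup, " repeated gene entries")
  module_catalog(mods)
}

#' Write a module catalog as GMT
#' @param catalog a `ModuleCatalog`
#' @param path output path
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(catalog$modules, function(m) {
    src <- if (nzchar(m$source)) m$source else m$category
    paste(c(m$name, src, m$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical/survival TSV
#'
#' Expects columns `sample_id`, `time`, `event` plus any covariates;
#' `event` may be 0/1 or logical. One record per (sample, endpoint).
#'
#' @param path TSV path
#' @return a data.frame
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$time < 0, na.rm = TRUE)) stop("negative survival times")
  df$event <- as.integer(as.logical(df$event))
  df
}
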