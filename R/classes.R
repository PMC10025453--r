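#' Cohort expression matrix
#'
#' Thin container for a genes x samples matrix of expression values, either
#' raw normalized abundance or per-gene cohort z-scores. Gene and sample
#' identifiers are carried in the dimnames and must be unique; missing
#' values stay explicit (`NA`) and are counted.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   complete dimnames
#' @param standardized logical; `TRUE` when rows are cohort z-scores
#' @param meta optional named list of provenance notes (e.g. the SD
#'   convention used for standardization)
#' @return an object of class `ExpressionMatrix`
#' @export
expression_matrix <- function(values, standardized = FALSE, meta = list()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("`values` must carry gene rownames and sample colnames")
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g))
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  structure(
    list(values = values, gene_ids = genes, sample_ids = samples,
         standardized = isTRUE(standardized),
         n_missing = sum(is.na(values)), meta = meta),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s%s)\n",
              length(x$gene_ids), length(x$sample_ids),
              if (x$standardized) "standardized" else "raw",
              if (x$n_missing) sprintf(", %d missing", x$n_missing) else ""))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# Subset an ExpressionMatrix by gene and/or sample ids (or indices).
#' Subset an expression matrix
#' @param x an `ExpressionMatrix`
#' @param genes,samples character ids or indices; `NULL` keeps all
#' @return an `ExpressionMatrix`
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, standardized = x$standardized, meta = x$meta)
}

module_categories <- c("pathway", "ontology", "regulator", "dna_motif",
                       "rna_motif_linear", "rna_motif_structural",
                       "oncogenic_signature", "other")

#' Construct a gene module
#'
#' A named gene set with a category label. Gene identifiers are opaque
#' strings; no symbol mapping is performed.
#'
#' @param name module name, unique within a catalog
#' @param genes character vector of gene ids (deduplicated)
#' @param category one of `r paste(module_categories, collapse=", ")`
#' @param source free-text provenance
#' @return an object of class `GeneModule`
#' @export
gene_module <- function(name, genes, category = "other", source = "") {
  category <- match.arg(category, module_categories)
  genes <- unique(as.character(genes))
  structure(list(name = name, category = category,
                 genes = genes, source = source),
            class = "GeneModule")
}

#' @export
print.GeneModule <- function(x, ...) {
  cat(sprintf("GeneModule '%s' [%s]: %d genes\n",
              x$name, x$category, length(x$genes)))
  invisible(x)
}

#' Construct a module catalog
#'
#' @param modules list of [gene_module()] objects with unique names
#' @param universe optional character vector of gene ids against which
#'   module membership is evaluated
#' @return an object of class `ModuleCatalog`
#' @export
module_catalog <- function(modules, universe = NULL) {
  stopifnot(all(vapply(modules, inherits, TRUE, "GeneModule")))
  nm <- vapply(modules, `[[`, "", "name")
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate module names: ", paste(dup, collapse = ", "))
  names(modules) <- nm
  structure(list(modules = modules,
                 universe = if (is.null(universe)) NULL
                            else unique(as.character(universe))),
            class = "ModuleCatalog")
}

#' @export
print.ModuleCatalog <- function(x, ...) {
  cat(sprintf("ModuleCatalog: %d modules%s\n", length(x$modules),
              if (is.null(x$universe)) ""
              else sprintf(" (universe of %d genes)", length(x$universe))))
  invisible(x)
}

#' @export
length.ModuleCatalog <- function(x) length(x$modules)

#' Names of the modules in a catalog
#' @param catalog a `ModuleCatalog`
#' @export
module_names <- function(catalog) names(catalog$modules)

#' Drop empty modules from a catalog
#'
#' Modules with no genes (e.g. a motif regulon with zero matches) are
#' removed before scoring; the removal is reported.
#' @param catalog a `ModuleCatalog`
#' @return a `ModuleCatalog`
#' @export
drop_empty_modules <- function(catalog) {
  sizes <- vapply(catalog$modules, function(m) length(m$genes), 0L)
  if (any(sizes == 0L)) {
    message("dropping ", sum(sizes == 0L), " empty module(s): ",
            paste(names(catalog$modules)[sizes == 0L], collapse = ", "))
    catalog$modules <- catalog$modules[sizes > 0L]
  }
  catalog
}
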