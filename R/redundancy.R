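#' Modified-Jaccard similarity matrix between modules
#'
#' S(A, B) = |G_A intersect G_B| / min(|G_A|, |G_B|): overlap normalized
#' by the smaller set, so a module nested inside another scores 1.
#' Memberships are evaluated against the catalog's universe when one is
#' set.
#'
#' @param catalog a [module_catalog()] with >= 2 modules
#' @return symmetric numeric matrix with unit diagonal
#' @export
similarity_matrix <- function(catalog) {
  mods <- catalog$modules
  if (length(mods) < 2L) stop("need >= 2 modules")
  sets <- lapply(mods, function(m) {
    g <- m$genes
    if (!is.null(catalog$universe)) g <- intersect(g, catalog$universe)
    if (!length(g)) stop("module '", m$name,
                         "' is empty (after universe restriction)")
    g
  })
  n <- length(sets)
  S <- matrix(1, n, n, dimnames = list(names(mods), names(mods)))
  sizes <- lengths(sets)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- length(intersect(sets[[i]], sets[[j]])) / min(sizes[i], sizes[j])
    S[i, j] <- s
    S[j, i] <- s
  }
  S
}

#' Exemplar clustering of modules by affinity propagation
#'
#' Standard affinity-propagation message passing (responsibilities and
#' availabilities with damping) on a similarity matrix; the preference
#' (self-similarity) defaults to the median off-diagonal similarity.
#' Deterministic: no noise is added and ties resolve by index. If no
#' stable exemplar set emerges within `max_iter`, the function falls
#' back to greedy leader clustering at similarity threshold 0.5 and
#' flags the result (`converged = FALSE`).
#'
#' @param S square symmetric similarity matrix
#' @param damping message damping in [0.5, 1) (default 0.9)
#' @param max_iter iteration cap (default 1000)
#' @param conv_window iterations of unchanged exemplars declaring
#'   convergence (default 100)
#' @param preference exemplar preference; scalar or per-point vector
#' @param seed seed for the tiny degeneracy-breaking jitter added to the
#'   similarities (overlap matrices are full of exact ties, which stall
#'   the message passing); the jitter is orders of magnitude below any
#'   meaningful similarity difference
#' @return list of class `exemplar_clustering`: `cluster` (exemplar name
#'   per module), `exemplars`, `converged`, `iterations`, `method`
#' @export
cluster_exemplars <- function(S, damping = 0.9, max_iter = 1000,
                              conv_window = 100, preference = NULL,
                              seed = 1) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("S must be square")
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  n <- nrow(S)
  nms <- rownames(S) %||% as.character(seq_len(n))
  if (n == 1L)
    return(structure(list(cluster = stats::setNames(nms, nms),
                          exemplars = nms, converged = TRUE,
                          iterations = 0L, method = "affinity_propagation"),
                     class = "exemplar_clustering"))
  off <- S[row(S) != col(S)]
  pref <- preference %||% stats::median(off)
  diag(S) <- pref
  scale_ <- max(diff(range(S)), 1e-6)
  S <- S + with_seed(seed, matrix(stats::runif(n * n), n, n)) *
    1e-9 * scale_
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  last <- NULL
  stable <- 0L
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    AS <- A + S
    # responsibilities: r(i,k) = s(i,k) - max_{k' != k} as(i,k')
    max1_idx <- max.col(AS, ties.method = "first")
    max1 <- AS[cbind(seq_len(n), max1_idx)]
    AS2 <- AS
    AS2[cbind(seq_len(n), max1_idx)] <- -Inf
    max2 <- apply(AS2, 1L, max)
    Rn <- S - max1
    Rn[cbind(seq_len(n), max1_idx)] <- S[cbind(seq_len(n), max1_idx)] - max2
    R <- damping * R + (1 - damping) * Rn
    # availabilities: a(i,k) = min(0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k)))
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    An <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(An)                        # sum_{i' != k} max(0, r(i',k))
    An <- pmin(An, 0)
    diag(An) <- dA
    A <- damping * A + (1 - damping) * An
    ex <- which(diag(A + R) > 0)
    if (identical(ex, last)) stable <- stable + 1L else stable <- 0L
    last <- ex
    if (stable >= conv_window && length(ex) > 0L) break
  }
  if (stable < conv_window || length(last) == 0L) {
    cl <- leader_clusters(S, nms, threshold = 0.5)
    warning("affinity propagation did not converge; greedy leader fallback")
    return(structure(list(cluster = cl$cluster, exemplars = cl$exemplars,
                          converged = FALSE, iterations = it,
                          method = "leader"),
                     class = "exemplar_clustering"))
  }
  assign_idx <- apply(S[, last, drop = FALSE], 1L, which.max)
  cluster <- nms[last][assign_idx]
  cluster[last] <- nms[last]              # exemplars own themselves
  structure(list(cluster = stats::setNames(cluster, nms),
                 exemplars = nms[last], converged = TRUE,
                 iterations = it, method = "affinity_propagation"),
            class = "exemplar_clustering")
}

# Greedy leader clustering: scan in index order, join the first leader
# with similarity above the threshold, else found a new cluster.
leader_clusters <- function(S, nms, threshold = 0.5) {
  n <- nrow(S)
  leaders <- integer()
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    for (l in leaders) if (S[i, l] > threshold) { hit <- l; break }
    if (hit == 0L) { leaders <- c(leaders, i); hit <- i }
    assign[i] <- hit
  }
  list(cluster = stats::setNames(nms[assign], nms),
       exemplars = nms[leaders])
}

#' @export
print.exemplar_clustering <- function(x, ...) {
  cat(sprintf("exemplar_clustering: %d modules -> %d clusters (%s%s)\n",
              length(x$cluster), length(x$exemplars), x$method,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Cluster a catalog within module categories
#'
#' Runs [cluster_exemplars()] separately inside each module category
#' (DNA motifs, linear RNA motifs, structural RNA motifs,
#' ontology/pathway, ...), as redundancy is only meaningful within a
#' category.
#'
#' @param catalog a [module_catalog()]
#' @param ... passed to [cluster_exemplars()]
#' @return named list of `exemplar_clustering` objects, one per category
#'   present (singleton categories map to themselves)
#' @export
cluster_modules_by_category <- function(catalog, ...) {
  cats <- vapply(catalog$modules, `[[`, "", "category")
  out <- list()
  for (cc in unique(cats)) {
    sub <- module_catalog(unname(catalog$modules[cats == cc]),
                          universe = catalog$universe)
    out[[cc]] <- if (length(sub) < 2L) {
      nm <- module_names(sub)
      structure(list(cluster = stats::setNames(nm, nm), exemplars = nm,
                     converged = TRUE, iterations = 0L,
                     method = "singleton"),
                class = "exemplar_clustering")
    } else cluster_exemplars(similarity_matrix(sub), ...)
  }
  out
}
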