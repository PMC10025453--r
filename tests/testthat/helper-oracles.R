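# Independent oracles and small fixture builders used across the suite.

# Brute-force mutual information: literal double sum over the 2 x Ne
# table, term by term.
mi_bruteforce <- function(counts) {
  N <- sum(counts)
  acc <- 0
  for (i in 1:2) for (j in seq_len(ncol(counts))) {
    pij <- counts[i, j] / N
    if (pij > 0) {
      pi_ <- sum(counts[i, ]) / N
      pj <- sum(counts[, j]) / N
      acc <- acc + pij * log(pij / (pi_ * pj))
    }
  }
  acc
}

# IUPAC -> regular expression oracle for motif scanning.
iupac_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]",
           M = "[AC]", B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
           N = "[ACGT]")
  paste(map[strsplit(toupper(pattern), "")[[1]]], collapse = "")
}

# Exact vectorized two-group log-rank statistic (hypergeometric
# variance), independent reimplementation used as the permutation
# oracle. gmat: n x B matrix of 0/1 group-1 indicators.
logrank_stat_matrix <- function(time, event, gmat) {
  n <- length(time)
  ord <- order(time)
  ev <- event[ord] == 1
  risk <- n - seq_len(n) + 1
  g <- gmat[ord, , drop = FALSE]
  n1risk <- apply(g, 2, function(cc) rev(cumsum(rev(cc))))
  E <- n1risk / risk
  V <- n1risk * (risk - n1risk) / risk^2
  num <- colSums((g - E)[ev, , drop = FALSE])
  den <- colSums(V[ev, , drop = FALSE])
  num^2 / den
}

perm_logrank_p <- function(time, event, grp, B = 10000) {
  obs <- logrank_stat_matrix(time, event, matrix(grp, ncol = 1))
  perms <- vapply(seq_len(B), function(i) sample(grp), numeric(length(grp)))
  mean(logrank_stat_matrix(time, event, perms) >= obs)
}

# Tiny cohort with named samples, exponential times.
toy_outcomes <- function(n, event_p = 0.8, rate = 0.1,
                         ids = sprintf("s%03d", seq_len(n))) {
  data.frame(sample_id = ids,
             time = stats::rexp(n, rate),
             event = stats::rbinom(n, 1, event_p),
             stringsAsFactors = FALSE)
}

# Named z-score vector over a synthetic gene universe.
toy_zscores <- function(n_genes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::setNames(stats::rnorm(n_genes), sprintf("g%04d", seq_len(n_genes)))
}
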