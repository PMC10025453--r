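#' Specification for a synthetic cancer cohort
#'
#' Defines the generative model behind every testable stage of the
#' pipeline: i.i.d. standard-normal baseline expression with planted
#' gene modules coherently shifted in patient subsets, exponential
#' survival whose hazard follows the signed module activations (and
#' optionally stage), independent exponential censoring, clinical
#' covariates, sparse CNA/SNV matrices and promoter windows with
#' planted motif instances. Defaults encode the reference study
#' conditions used throughout the test suite: 600 patients, 2000 genes,
#' five planted modules of 50 genes shifted by 2 SD in 15% activated +
#' 15% repressed patients with a log-hazard-ratio ladder of
#' 0.3/0.6/0.9/1.2/1.5, and 50 random decoy modules.
#'
#' @param n_samples,n_genes cohort dimensions
#' @param modules data.frame with columns `size`, `act_frac`,
#'   `rep_frac`, `shift`, `beta` (one row per planted module); `NULL`
#'   plants the default ladder
#' @param n_decoys random decoy modules (default 50)
#' @param decoy_size_range inclusive size range for decoys
#' @param baseline_hazard exponential baseline hazard per time unit
#'   (months; default 0.02)
#' @param censoring target censoring fraction at baseline hazard
#'   (default 0.3)
#' @param stage_probs sampling probabilities of stages I..IV
#' @param stage_gamma per-stage-step log hazard increment (default 0)
#' @param motif_patterns IUPAC motif planted per module (recycled)
#' @param gc background GC content of generated sequences
#' @param seq_length window length (default 1000)
#' @param n_background_seqs non-module sequences emitted
#' @param seed master seed
#' @return list of class `SyntheticCohortSpec`
#' @export
synthetic_cohort_spec <- function(
    n_samples = 600, n_genes = 2000,
    modules = NULL, n_decoys = 50, decoy_size_range = c(20, 60),
    baseline_hazard = 0.02, censoring = 0.3,
    stage_probs = c(I = 0.3, II = 0.3, III = 0.25, IV = 0.15),
    stage_gamma = 0,
    motif_patterns = c("TGACGTCA", "CACGTG", "GGGACTTTCC",
                       "TTGCGCAA", "SCGGAAGY"),
    gc = 0.41, seq_length = 1000, n_background_seqs = 200,
    seed = 1) {
  if (is.null(modules))
    modules <- data.frame(size = 50, act_frac = 0.15, rep_frac = 0.15,
                          shift = 2, beta = c(0.3, 0.6, 0.9, 1.2, 1.5))
  stopifnot(all(modules$act_frac + modules$rep_frac < 1),
            all(modules$act_frac > 0 | modules$beta == 0),
            sum(modules$size) <= n_genes)
  structure(as.list(environment()), class = "SyntheticCohortSpec")
}

#' Generate a synthetic cohort with ground truth
#'
#' See [synthetic_cohort_spec()] for the generative model. Planted
#' modules occupy disjoint gene blocks; each activated (repressed)
#' patient has the module's genes shifted by +shift (-shift) SD;
#' survival times are exponential with hazard
#' `h0 * exp(sum_m beta_m * a_mp + gamma * stage)` where `a` is the
#' signed activation; censoring is exponential with rate
#' `h0 * censoring / (1 - censoring)` so the baseline event fraction
#' matches `1 - censoring`. Byte-identical outputs for equal
#' (spec, seed).
#'
#' @param spec a `SyntheticCohortSpec`
#' @param with_sequences emit promoter windows with planted motifs
#'   (default `TRUE`)
#' @return list of class `SyntheticCohort`: `expression` (raw
#'   `ExpressionMatrix`), `catalog` (planted + decoys), `outcomes`,
#'   `clinical`, `cna`, `snv`, `coding_lengths`, `sequences`, `truth`
#' @export
generate_cohort <- function(spec, with_sequences = TRUE) {
  stopifnot(inherits(spec, "SyntheticCohortSpec"))
  n <- spec$n_samples
  G <- spec$n_genes
  genes <- sprintf("g%04d", seq_len(G))
  ids <- sprintf("s%04d", seq_len(n))
  nmod <- nrow(spec$modules)

  with_seed(derive_seed(spec$seed, 1L), {
    v <- matrix(stats::rnorm(G * n), G, n, dimnames = list(genes, ids))

    # planted modules on disjoint leading gene blocks
    act <- matrix(0L, nmod, n,
                  dimnames = list(sprintf("planted_%02d", seq_len(nmod)),
                                  ids))
    mod_genes <- vector("list", nmod)
    offset <- 0L
    for (m in seq_len(nmod)) {
      sz <- spec$modules$size[m]
      mod_genes[[m]] <- genes[offset + seq_len(sz)]
      offset <- offset + sz
      n_act <- round(spec$modules$act_frac[m] * n)
      n_rep <- round(spec$modules$rep_frac[m] * n)
      pick <- sample.int(n, n_act + n_rep)
      act[m, pick[seq_len(n_act)]] <- 1L
      if (n_rep > 0)
        act[m, pick[n_act + seq_len(n_rep)]] <- -1L
      v[mod_genes[[m]], ] <- v[mod_genes[[m]], ] +
        spec$modules$shift[m] * rep(act[m, ], each = sz)
    }

    # clinical covariates
    stage <- factor(sample(names(spec$stage_probs), n, replace = TRUE,
                           prob = spec$stage_probs),
                    levels = names(spec$stage_probs))
    age <- round(pmin(pmax(stats::rnorm(n, 63, 12), 25), 90))
    sex <- sample(c("female", "male"), n, replace = TRUE)

    # survival: exponential event and censoring times
    lp <- as.numeric(t(act) %*% spec$modules$beta) +
      spec$stage_gamma * (as.integer(stage) - 1L)
    h <- spec$baseline_hazard * exp(lp)
    c_rate <- spec$baseline_hazard * spec$censoring / (1 - spec$censoring)
    t_event <- stats::rexp(n, h)
    t_cens <- stats::rexp(n, c_rate)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    # module catalog: planted blocks + random decoys
    planted <- lapply(seq_len(nmod), function(m)
      gene_module(rownames(act)[m], mod_genes[[m]], category = "pathway",
                  source = "planted"))
    decoys <- lapply(seq_len(spec$n_decoys), function(d) {
      sz <- sample(seq(spec$decoy_size_range[1], spec$decoy_size_range[2]),
                   1L)
      gene_module(sprintf("decoy_%03d", d), sample(genes, sz),
                  category = "pathway", source = "decoy")
    })
    catalog <- module_catalog(c(planted, decoys), universe = genes)

    # sparse CNA: noisy background + a few prominent genes
    n_cna_bg <- min(200L, G)
    n_cna_hot <- 5L
    cna_genes <- c(sprintf("cna_hot_%02d", seq_len(n_cna_hot)),
                   sample(genes, n_cna_bg))
    cna <- matrix(0, length(cna_genes), n,
                  dimnames = list(cna_genes, ids))
    bg <- (n_cna_hot + 1):length(cna_genes)
    nz <- matrix(stats::runif(length(bg) * n) < 0.3, length(bg), n)
    cna[bg, ][nz] <- stats::rnorm(sum(nz), 0, 0.15)
    for (gidx in seq_len(n_cna_hot)) {
      mu <- sample(c(-1, 1), 1L) * stats::runif(1, 0.5, 1.5)
      cna[gidx, ] <- stats::rnorm(n, mu, 0.6)
    }

    # SNV: per-gene prevalence, a few above the 5% selection bar
    n_snv <- 30L
    snv_genes <- sprintf("mut_%02d", seq_len(n_snv))
    prev <- stats::runif(n_snv, 0.01, 0.06)
    prev[seq_len(5L)] <- stats::runif(5L, 0.08, 0.25)
    snv <- matrix(stats::rbinom(n_snv * n, 1L, rep(prev, n)),
                  n_snv, n, dimnames = list(snv_genes, ids))
    coding_lengths <- stats::setNames(
      round(stats::runif(n_snv, 1000, 10000)), snv_genes)

    sequences <- NULL
    motif_placed <- NULL
    if (isTRUE(with_sequences)) {
      pats <- rep_len(spec$motif_patterns, nmod)
      seq_ids <- unique(c(unlist(mod_genes),
                          sample(genes, min(spec$n_background_seqs, G))))
      sequences <- vapply(seq_ids, function(g)
        random_dna(spec$seq_length, spec$gc), "")
      motif_placed <- data.frame(module = character(), gene = character(),
                                 position = integer(), instance = character(),
                                 stringsAsFactors = FALSE)
      for (m in seq_len(nmod)) {
        for (g in mod_genes[[m]]) {
          inst <- sample_iupac_instance(pats[m])
          pos <- sample.int(spec$seq_length - nchar(inst) + 1L, 1L)
          substr(sequences[g], pos, pos + nchar(inst) - 1L) <- inst
          motif_placed <- rbind(motif_placed, data.frame(
            module = rownames(act)[m], gene = g, position = pos,
            instance = inst, stringsAsFactors = FALSE))
        }
      }
    }

    truth <- list(
      planted = rownames(act), decoys = sprintf("decoy_%03d",
                                                seq_len(spec$n_decoys)),
      activation = act, beta = stats::setNames(spec$modules$beta,
                                               rownames(act)),
      module_genes = stats::setNames(mod_genes, rownames(act)),
      motifs = if (with_sequences)
        stats::setNames(rep_len(spec$motif_patterns, nmod), rownames(act))
        else NULL,
      motif_placements = motif_placed,
      expected_event_fraction = mean(h / (h + c_rate)))

    structure(list(
      expression = expression_matrix(v, standardized = FALSE),
      catalog = catalog,
      outcomes = data.frame(sample_id = ids, time = time, event = event,
                            endpoint = "overall",
                            stringsAsFactors = FALSE),
      clinical = data.frame(sample_id = ids, stage = as.character(stage),
                            age = age, sex = sex,
                            stringsAsFactors = FALSE),
      cna = cna, snv = snv, coding_lengths = coding_lengths,
      sequences = sequences, truth = truth, spec = spec),
      class = "SyntheticCohort")
  })
}

# Uniform random DNA with the given GC content.
random_dna <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

iupac_expand <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
                  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT",
                  M = "AC", B = "CGT", D = "AGT", H = "ACT", V = "ACG",
                  N = "ACGT")

# Draw one concrete instance of an IUPAC pattern.
sample_iupac_instance <- function(pattern) {
  paste(vapply(strsplit(toupper(pattern), "")[[1L]], function(ch) {
    opts <- strsplit(iupac_expand[[ch]], "")[[1L]]
    opts[sample.int(length(opts), 1L)]
  }, ""), collapse = "")
}

#' Write a synthetic cohort to disk in standard formats
#'
#' Expression/clinical/CNA/SNV as TSV, the module catalog as GMT, and
#' the sequences as FASTA.
#'
#' @param cohort a `SyntheticCohort`
#' @param dir output directory (created)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$outcomes, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("cna", "snv")) {
    df <- data.frame(gene_id = rownames(cohort[[nm]]), cohort[[nm]],
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_gmt(cohort$catalog, file.path(dir, "modules.gmt"))
  if (!is.null(cohort$sequences)) {
    writeLines(paste0(">", names(cohort$sequences), "\n",
                      cohort$sequences),
               file.path(dir, "promoters.fa"))
  }
  invisible(dir)
}

#' Recovery report: pipeline output against the ground-truth registry
#'
#' @param truth the `$truth` element of a `SyntheticCohort`
#' @param decisions a `pcm_decisions` table from [discover_pcms()]
#' @return list: `sensitivity` (fraction of planted modules detected),
#'   `decoy_pass_rate`, `detected`, per-planted-module best absolute
#'   Wald z, and `beta_wald_spearman` (rank correlation of the planted
#'   log-HR with the observed |Wald z|)
#' @export
recoverability_report <- function(truth, decisions) {
  if (!all(truth$planted %in% decisions$module) &&
      !any(truth$planted %in% decisions$module))
    stop("decision table does not cover the ground-truth registry")
  detected <- pcms(decisions)
  best_z <- vapply(truth$planted, function(m) {
    z <- decisions$full_wald_z[decisions$module == m]
    if (all(is.na(z))) NA_real_ else max(abs(z), na.rm = TRUE)
  }, 0)
  sp <- if (sum(!is.na(best_z)) >= 3)
    suppressWarnings(stats::cor(truth$beta[names(best_z)], best_z,
                                method = "spearman",
                                use = "complete.obs"))
    else NA_real_
  list(sensitivity = mean(truth$planted %in% detected),
       decoy_pass_rate = mean(truth$decoys %in% detected),
       detected = detected,
       planted_wald_z = best_z,
       beta_wald_spearman = sp)
}
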