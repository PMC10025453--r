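iupac_codes <- c("A","C","G","T","U","R","Y","S","W","K","M",
                 "B","D","H","V","N")

#' Construct an IUPAC motif
#'
#' A degenerate DNA/RNA pattern whose instances in pre-extracted 1 kb
#' promoter or 3'UTR windows define a regulon.
#'
#' @param pattern string over the IUPAC alphabet, length >= 4
#' @param region search window the sequences came from:
#'   `"promoter_1kb"` or `"utr3_1kb"`
#' @param kind `"dna"` or `"rna_linear"`
#' @return an object of class `IupacMotif`
#' @export
iupac_motif <- function(pattern, region = c("promoter_1kb", "utr3_1kb"),
                        kind = c("dna", "rna_linear")) {
  region <- match.arg(region)
  kind <- match.arg(kind)
  pattern <- toupper(pattern)
  if (nchar(pattern) < 4L) stop("motif pattern must have length >= 4")
  chars <- strsplit(pattern, "")[[1L]]
  bad <- which(!chars %in% iupac_codes)
  if (length(bad))
    stop(sprintf("invalid IUPAC character '%s' at position %d",
                 chars[bad[1L]], bad[1L]))
  structure(list(pattern = pattern, region = region, kind = kind),
            class = "IupacMotif")
}

#' Scan sequences for a motif and build its regulon module
#'
#' Every gene whose sequence carries at least one match of the IUPAC
#' pattern (on the provided strand only) joins the module. Sequences are
#' the pre-extracted windows; RNA patterns/sequences are handled on the
#' DNA alphabet (U -> T). Matching is delegated to
#' [Biostrings::vcountPattern()] with `fixed = FALSE`.
#'
#' @param motif an [iupac_motif()]
#' @param sequences a named character vector, a
#'   [Biostrings::DNAStringSet], or a FASTA file path; names are
#'   gene/transcript ids
#' @return a [gene_module()] named after the pattern; empty with a
#'   warning when the motif matches nothing
#' @export
scan_motif <- function(motif, sequences) {
  stopifnot(inherits(motif, "IupacMotif"))
  if (length(sequences) == 0L) stop("empty FASTA / sequence set")
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences) && is.null(names(sequences))) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  if (is.character(sequences)) {
    if (is.null(names(sequences)))
      stop("sequences must be named by gene/transcript id")
    sequences <- Biostrings::DNAStringSet(gsub("U", "T",
                                               toupper(sequences)))
  }
  if (length(sequences) == 0L) stop("empty FASTA / sequence set")
  pat <- gsub("U", "T", motif$pattern)
  hits <- Biostrings::vcountPattern(pat, sequences, fixed = FALSE)
  genes <- names(sequences)[hits > 0L]
  category <- switch(motif$kind, dna = "dna_motif",
                     rna_linear = "rna_motif_linear")
  if (length(genes) == 0L)
    warning("motif ", motif$pattern, " matched no sequence; empty regulon")
  gene_module(motif$pattern, genes, category = category,
              source = motif$region)
}
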