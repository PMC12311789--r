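## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats dnorm pnorm rnorm runif rbeta rgamma rmultinom rpois
#'   quantile median sd cor cor.test fisher.test p.adjust kmeans setNames
#'   aggregate coef
#' @importFrom graphics hist
#' @importFrom utils head read.delim write.table
NULL

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## Reverse complement of a plain character string (coding-strand arithmetic
## elsewhere relies on this being exact, so it is kept free of any Biostrings
## class round trip).
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  paste(rev(COMPLEMENT[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

## Codon table from the standard genetic code.
GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

STOP_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == "*"]

translate_cds <- function(dna) {
  stopifnot(nchar(dna) %% 3 == 0)
  codons <- substring(dna, seq(1, nchar(dna), by = 3), seq(3, nchar(dna), by = 3))
  paste(GENETIC_CODE_TABLE[codons], collapse = "")
}

## Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## Variant identifier in the field's usual RefPosAlt form, e.g. "K271E".
variant_id <- function(ref_aa, aa_pos, alt_aa) paste0(ref_aa, aa_pos, alt_aa)

## Phred+33 encode/decode for quality strings.
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(q) intToUtf8(q + 33L)

## Map a spacer position (1 = PAM-distal 5' end) to a 1-based coordinate on
## the coding strand. For '-' strand guides cdna_start indexes the reverse
## complement of the CDS.
spacer_to_cds_pos <- function(spacer_pos, strand, cdna_start, cds_length) {
  if (strand == "+") {
    cdna_start + spacer_pos - 1L
  } else {
    cds_length - (cdna_start + spacer_pos - 1L) + 1L
  }
}

## Interval of coding-strand positions covered by spacer window [a, b].
window_cds_interval <- function(window, strand, cdna_start, cds_length) {
  p <- vapply(window, spacer_to_cds_pos,
              numeric(1), strand = strand,
              cdna_start = cdna_start, cds_length = cds_length)
  c(min(p), max(p))
}

## Draw from a symmetric Dirichlet; concentration = Inf gives exact uniform.
rdirichlet_sym <- function(n, concentration) {
  if (is.infinite(concentration)) return(rep(1 / n, n))
  g <- rgamma(n, shape = concentration, rate = 1)
  g / sum(g)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}
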