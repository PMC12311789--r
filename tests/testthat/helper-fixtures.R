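# Shared fixtures and independent oracles used across the suite.
# Everything is built in code at test time; seeds are fixed.

fixture_reference <- function(orf_length_aa = 80, seed = 1) {
  generate_reference(orf_length_aa, seed = seed)
}

fixture_landscape <- function(ref = fixture_reference(), seed = 2, ...) {
  generate_fitness_landscape(ref$protein, seed = seed, ...)
}

# Independent codon translation using a hand-entered table (not the
# package's Biostrings-backed path).
oracle_translate <- function(dna) {
  tab <- c(TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
           ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
           TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
           ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
           TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
           AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
           TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
           AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  n <- nchar(dna)
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  paste(tab[codons], collapse = "")
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Brute-force protospacer scan: every 23-mer window on both strands,
# keeping those whose 22nd base is G (NGN PAM).
oracle_protospacers <- function(cds) {
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") cds else oracle_revcomp(cds)
    for (i in seq_len(nchar(s) - 22)) {
      win <- substr(s, i, i + 22)
      if (substr(win, 22, 22) == "G")
        hits[[length(hits) + 1]] <- data.frame(
          spacer = substr(win, 1, 20), strand = strand, cdna_start = i,
          stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, hits)
}

# Brute-force window edit enumeration for a spacer: source-base positions
# inside the window, and all non-empty subsets.
oracle_window_edits <- function(spacer, window, source_base = "A") {
  s <- strsplit(spacer, "")[[1]]
  pos <- which(s == source_base)
  pos <- pos[pos >= window[1] & pos <= window[2]]
  subsets <- list()
  if (length(pos) > 0) {
    for (m in 1:(2^length(pos) - 1)) {
      sel <- pos[bitwAnd(m, 2^(seq_along(pos) - 1)) > 0]
      subsets[[length(subsets) + 1]] <- sel
    }
  }
  list(positions = pos, subsets = subsets)
}

random_spacer <- function() paste(sample(c("A", "C", "G", "T"), 20,
                                         replace = TRUE), collapse = "")
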