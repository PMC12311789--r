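## Synthetic screen generator.
##
## Every input the analysis consumes can be generated here with known ground
## truth: a reference coding sequence, a bimodal fitness landscape over all
## single amino-acid substitutions, pooled screen count tables propagated by
## exponential growth and sampled multinomially, per-guide editing outcomes
## under an independent-position (product) bystander model, and paired or
## UMI-tagged amplicon reads with per-base qualities and substitution errors.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a random reference coding sequence
#'
#' Produces an open reading frame of the requested length: an ATG start
#' codon followed by codons drawn uniformly from the 61 sense codons, so the
#' translation contains no internal stop.
#'
#' @param orf_length_aa number of amino acids (>= 25 so that guides can be
#'   tiled across the sequence).
#' @param seed integer seed; the same seed always yields the same sequence.
#' @return A list with elements \code{dna} (the coding sequence, length
#'   \code{3 * orf_length_aa}) and \code{protein} (its translation).
#' @export
generate_reference <- function(orf_length_aa, seed = NULL) {
  stop_if_not_scalar_number(orf_length_aa, "orf_length_aa")
  if (orf_length_aa < 25)
    stop("orf_length_aa must be >= 25 (too short to tile guides)")
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(names(GENETIC_CODE_TABLE), STOP_CODONS)
  codons <- c("ATG", sample(sense, orf_length_aa - 1, replace = TRUE))
  dna <- paste(codons, collapse = "")
  list(dna = dna, protein = translate_cds(dna))
}

#' Generate a bimodal fitness landscape over single amino-acid substitutions
#'
#' Each variant's growth rate is drawn from a two-component skew-normal
#' mixture: a deleterious component (default mean 0.02 h^-1) and a WT-like
#' component centred at the wild-type growth rate (default 0.055 h^-1).
#' Components are specified on the moment scale (mean, sd, shape).
#'
#' @param protein reference protein sequence (single string).
#' @param aa_range integer vector of positions to mutagenise; default all
#'   positions except the initiator methionine.
#' @param deleterious_weight fraction of variants drawn from the deleterious
#'   component (default 0.56).
#' @param wt_rate wild-type growth rate in h^-1 (default 0.055).
#' @param deleterious,wt_like lists with \code{mean}, \code{sd}, \code{alpha}
#'   giving each component's moments and skewness.
#' @param seed optional integer seed.
#' @return Data frame with columns \code{variant_id}, \code{aa_pos},
#'   \code{ref_aa}, \code{alt_aa}, \code{class}, \code{true_rate}.
#' @export
generate_fitness_landscape <- function(protein,
                                       aa_range = NULL,
                                       deleterious_weight = 0.56,
                                       wt_rate = 0.055,
                                       deleterious = list(mean = 0.02,
                                                          sd = 0.006,
                                                          alpha = 2),
                                       wt_like = list(mean = wt_rate,
                                                      sd = 0.004,
                                                      alpha = -2),
                                       seed = NULL) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (deleterious_weight < 0 || deleterious_weight > 1)
    stop("deleterious_weight must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  aa <- chars(protein)
  if (is.null(aa_range)) aa_range <- seq(2L, length(aa))
  if (any(aa_range < 1L | aa_range > length(aa)))
    stop("aa_range outside the protein")

  ref_aa <- aa[aa_range]
  grid <- do.call(rbind, lapply(seq_along(aa_range), function(i) {
    alts <- setdiff(AA_ALPHABET, ref_aa[i])
    data.frame(aa_pos = aa_range[i], ref_aa = ref_aa[i], alt_aa = alts,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(grid)
  is_del <- runif(n) < deleterious_weight
  par_d <- skewnorm_from_moments(deleterious$mean, deleterious$sd,
                                 deleterious$alpha)
  par_w <- skewnorm_from_moments(wt_like$mean, wt_like$sd, wt_like$alpha)
  rate <- numeric(n)
  rate[is_del] <- rskewnorm(sum(is_del), par_d$xi, par_d$omega, par_d$alpha)
  rate[!is_del] <- rskewnorm(sum(!is_del), par_w$xi, par_w$omega, par_w$alpha)
  data.frame(
    variant_id = variant_id(grid$ref_aa, grid$aa_pos, grid$alt_aa),
    aa_pos = grid$aa_pos,
    ref_aa = grid$ref_aa,
    alt_aa = grid$alt_aa,
    class = ifelse(is_del, "deleterious", "wt_like"),
    true_rate = rate,
    stringsAsFactors = FALSE
  )
}

#' Simulate pooled screen count tables
#'
#' Propagates starting frequencies by exponential growth,
#' \eqn{f_t \propto f_0 e^{r t}}, tracks the total viable-cell count, and
#' draws sequencing counts multinomially at the configured depth. With
#' \code{noiseless = TRUE} the expected (non-integer) counts are returned,
#' so the two-timepoint growth-rate estimator inverts the simulation
#' exactly.
#'
#' @param rates data frame with columns \code{id} and \code{rate} (h^-1).
#' @param depth sequencing depth per sample (>= 1).
#' @param count0 starting viable-cell count.
#' @param timepoints hours at which samples are taken; the first entry is
#'   the baseline. Must be strictly increasing.
#' @param replicates number of replicates.
#' @param concentration symmetric Dirichlet concentration for the baseline
#'   library composition; \code{Inf} (default) gives an exactly even
#'   library.
#' @param noiseless if TRUE, return expected counts instead of multinomial
#'   draws.
#' @param seed optional integer seed.
#' @return List with \code{counts} (long data frame: id, timepoint_h,
#'   replicate, count), \code{pop} (viable cells per timepoint/replicate),
#'   \code{depth}, and \code{f0} (baseline frequency matrix, one column per
#'   replicate).
#' @export
simulate_screen_counts <- function(rates, depth = 1e6, count0 = 5e6,
                                   timepoints = c(0, 144), replicates = 2,
                                   concentration = Inf, noiseless = FALSE,
                                   seed = NULL) {
  stopifnot(is.data.frame(rates), all(c("id", "rate") %in% names(rates)))
  if (!all(is.finite(rates$rate))) stop("all rates must be finite")
  if (depth <= 0) stop("depth must be positive")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(rates)
  f0 <- matrix(0, n, replicates,
               dimnames = list(rates$id, NULL))
  counts <- vector("list", replicates * length(timepoints))
  pop <- vector("list", replicates * length(timepoints))
  k <- 0L
  for (r in seq_len(replicates)) {
    f0r <- rdirichlet_sym(n, concentration)
    f0[, r] <- f0r
    for (t in timepoints) {
      k <- k + 1L
      w <- f0r * exp(rates$rate * (t - timepoints[1]))
      ft <- w / sum(w)
      cells <- count0 * sum(w)
      cnt <- if (noiseless) depth * ft else as.numeric(rmultinom(1, depth, ft))
      counts[[k]] <- data.frame(id = rates$id, timepoint_h = t,
                                replicate = r, count = cnt,
                                stringsAsFactors = FALSE)
      pop[[k]] <- data.frame(timepoint_h = t, replicate = r, cells = cells)
    }
  }
  list(counts = do.call(rbind, counts),
       pop = do.call(rbind, pop),
       depth = depth,
       f0 = f0)
}

#' Enumerate editing outcomes of a guide under the product bystander model
#'
#' Each editable position (a source base of the editor inside the active
#' part of the positional-efficiency profile) is edited independently with
#' probability \code{profile$p[pos] * efficiency}. Outcome proportions are
#' products over positions and sum to one including the unedited outcome
#' (the empty set).
#'
#' @param spacer 20-nt spacer sequence.
#' @param profile an \code{\link{editor_profile}}.
#' @param efficiency per-guide efficiency scalar in [0, 1] multiplying the
#'   positional probabilities.
#' @param max_editable maximum number of editable positions (outcome count
#'   is 2^k; more than 8 is refused).
#' @return Data frame with columns \code{positions} (comma-separated spacer
#'   positions, \code{""} for unedited), \code{n_edits}, \code{proportion}.
#' @export
simulate_editing_outcomes <- function(spacer, profile, efficiency = 1,
                                      max_editable = 8) {
  stopifnot(nchar(spacer) == 20)
  if (efficiency < 0 || efficiency > 1) stop("efficiency must be in [0, 1]")
  sp <- chars(spacer)
  pos <- which(sp == profile$source_base & profile$p > 0)
  p <- profile$p[pos] * efficiency
  k <- length(pos)
  if (k > max_editable)
    stop(sprintf("guide has %d editable positions (cap %d)", k, max_editable))
  if (k == 0L)
    return(data.frame(positions = "", n_edits = 0L, proportion = 1,
                      stringsAsFactors = FALSE))
  subsets <- 0:(2^k - 1)
  out <- lapply(subsets, function(s) {
    on <- bitwAnd(s, 2^(seq_len(k) - 1)) > 0
    data.frame(
      positions = paste(pos[on], collapse = ","),
      n_edits = sum(on),
      proportion = prod(ifelse(on, p, 1 - p)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Simulate paired amplicon reads with per-base qualities
#'
#' Reads are drawn from a weighted set of allele sequences (the reference
#' with edits applied). Both mates carry the molecule's true edits at high
#' quality; substitution errors are injected independently per mate at
#' \code{error_rate} and carry low qualities from \code{q_err}. Read starts
#' emulate a randomised stagger: mate 1 loses up to \code{max_stagger}
#' bases from the amplicon 5' end, mate 2 from the 3' end, so the mates'
#' overlap covers the rest. Mate 2 is returned reverse-complemented, as
#' sequenced.
#'
#' @param alleles character vector of full-length allele sequences (equal
#'   width, first typically the unedited reference).
#' @param proportions sampling weights for the alleles (summing to 1).
#' @param n_pairs number of read pairs.
#' @param error_rate per-base substitution error rate in [0, 0.05].
#' @param max_stagger maximum stagger in nt (default 7).
#' @param q_true Phred quality assigned to correctly sequenced bases.
#' @param q_err integer range \code{c(lo, hi)} of qualities assigned to
#'   error bases.
#' @param seed optional integer seed.
#' @return List with data frames \code{r1} and \code{r2} (columns
#'   \code{id}, \code{seq}, \code{qual}), \code{truth} (read id and allele
#'   index) and \code{errors} (read id, mate, amplicon position, quality).
#' @export
simulate_paired_reads <- function(alleles, proportions, n_pairs,
                                  error_rate = 0.003, max_stagger = 7,
                                  q_true = 37, q_err = c(3, 20),
                                  seed = NULL) {
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must be in [0, 0.05]")
  widths <- nchar(alleles)
  if (length(unique(widths)) != 1L) stop("alleles must have equal width")
  L <- widths[1]
  if (!is.null(seed)) set.seed(seed)

  amat <- t(vapply(alleles, function(s) match(chars(s), BASES),
                   integer(L)))
  idx <- sample.int(length(alleles), n_pairs, replace = TRUE,
                    prob = proportions)
  mol <- amat[idx, , drop = FALSE]

  inject <- function(mol) {
    seqm <- mol
    qm <- matrix(q_true, nrow(mol), ncol(mol))
    err <- which(matrix(runif(length(mol)) < error_rate,
                        nrow(mol)), arr.ind = TRUE)
    if (nrow(err) > 0) {
      cur <- seqm[err]
      shift <- sample.int(3, nrow(err), replace = TRUE)
      seqm[err] <- ((cur - 1L + shift) %% 4L) + 1L
      qm[err] <- sample(seq(q_err[1], q_err[2]), nrow(err), replace = TRUE)
    }
    list(seq = seqm, qual = qm, err = err)
  }
  m1 <- inject(mol)
  m2 <- inject(mol)

  base_codes <- utf8ToInt(paste(BASES, collapse = ""))
  to_str <- function(m) {
    cm <- matrix(base_codes[m], nrow(m), ncol(m))
    vapply(seq_len(nrow(cm)), function(i) intToUtf8(cm[i, ]), character(1))
  }
  qual_str <- function(m)
    vapply(seq_len(nrow(m)), function(i) intToUtf8(m[i, ] + 33L),
           character(1))

  s1 <- sample(0:max_stagger, n_pairs, replace = TRUE)
  s2 <- sample(0:max_stagger, n_pairs, replace = TRUE)
  ids <- sprintf("pair%06d", seq_len(n_pairs))

  full1 <- to_str(m1$seq); fq1 <- qual_str(m1$qual)
  full2 <- to_str(m2$seq); fq2 <- qual_str(m2$qual)

  r1_seq <- substring(full1, s1 + 1, L)
  r1_qual <- substring(fq1, s1 + 1, L)
  r2_fwd_seq <- substring(full2, 1, L - s2)
  r2_fwd_qual <- substring(fq2, 1, L - s2)
  r2_seq <- vapply(r2_fwd_seq, revcomp, character(1), USE.NAMES = FALSE)
  r2_qual <- vapply(r2_fwd_qual,
                    function(q) intToUtf8(rev(utf8ToInt(q))),
                    character(1), USE.NAMES = FALSE)

  err_df <- function(e, mate) {
    if (nrow(e) == 0)
      return(data.frame(id = character(0), mate = integer(0),
                        pos = integer(0), q = integer(0)))
    data.frame(id = ids[e[, 1]], mate = mate, pos = as.integer(e[, 2]),
               q = if (mate == 1) m1$qual[e] else m2$qual[e],
               stringsAsFactors = FALSE)
  }
  list(
    r1 = data.frame(id = ids, seq = r1_seq, qual = r1_qual,
                    stringsAsFactors = FALSE),
    r2 = data.frame(id = ids, seq = r2_seq, qual = r2_qual,
                    stringsAsFactors = FALSE),
    truth = data.frame(id = ids, allele_index = idx,
                       stringsAsFactors = FALSE),
    errors = rbind(err_df(m1$err, 1L), err_df(m2$err, 2L))
  )
}

#' Simulate UMI-tagged amplicon reads
#'
#' Molecules are drawn from the allele set; each molecule receives a random
#' UMI and a family of reads with independent substitution errors. Used to
#' exercise UMI consensus building and variant calling.
#'
#' @inheritParams simulate_paired_reads
#' @param n_molecules number of template molecules.
#' @param family_size_lambda Poisson mean of (family size - 1); families
#'   always have at least one read.
#' @param umi_length UMI length in nt.
#' @return List with \code{reads} (data frame: umi, seq, qual) and
#'   \code{truth} (umi, allele index, family size).
#' @export
simulate_umi_reads <- function(alleles, proportions, n_molecules,
                               family_size_lambda = 3, umi_length = 12,
                               error_rate = 0.003, q_true = 37,
                               q_err = c(3, 20), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(alleles[1])
  amat <- t(vapply(alleles, function(s) match(chars(s), BASES), integer(L)))
  idx <- sample.int(length(alleles), n_molecules, replace = TRUE,
                    prob = proportions)
  fam <- 1L + stats::rpois(n_molecules, family_size_lambda)
  umis <- vapply(seq_len(n_molecules), function(i)
    paste(sample(BASES, umi_length, replace = TRUE), collapse = ""),
    character(1))
  if (anyDuplicated(umis))
    umis <- paste0(umis, "_", seq_len(n_molecules))

  rows <- rep(seq_len(n_molecules), fam)
  seqm <- amat[idx[rows], , drop = FALSE]
  qm <- matrix(q_true, nrow(seqm), ncol(seqm))
  err <- which(matrix(runif(length(seqm)) < error_rate, nrow(seqm)),
               arr.ind = TRUE)
  if (nrow(err) > 0) {
    cur <- seqm[err]
    shift <- sample.int(3, nrow(err), replace = TRUE)
    seqm[err] <- ((cur - 1L + shift) %% 4L) + 1L
    qm[err] <- sample(seq(q_err[1], q_err[2]), nrow(err), replace = TRUE)
  }
  seqs <- apply(seqm, 1, function(r) paste(BASES[r], collapse = ""))
  quals <- apply(qm, 1, function(r) int_to_phred(r))
  list(
    reads = data.frame(umi = umis[rows], seq = seqs, qual = quals,
                       stringsAsFactors = FALSE),
    truth = data.frame(umi = umis, allele_index = idx, family_size = fam,
                       stringsAsFactors = FALSE)
  )
}

#' Simulate guide-amplicon reads from known counts
#'
#' Produces reads of the form 5' context + spacer + scaffold, one read per
#' unit of count, in shuffled order. Used to exercise guide counting.
#'
#' @param counts data frame with columns \code{guide_id} and \code{count}.
#' @param library guide library with columns \code{guide_id}, \code{spacer}.
#' @param context5 fixed 5' context preceding the spacer.
#' @param scaffold fixed 3' scaffold following the spacer.
#' @param seed optional integer seed.
#' @return Character vector of reads.
#' @export
simulate_guide_reads <- function(counts, library, context5 = "ACCG",
                                 scaffold = "GTTTTAGAGCTAGAA", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spacer <- library$spacer[match(counts$guide_id, library$guide_id)]
  reads <- rep(paste0(context5, spacer, scaffold), counts$count)
  sample(reads)
}

#' Apply spacer-position edits to a coding sequence
#'
#' Writes a guide's edits (given as spacer positions) into the coding
#' strand, honouring strand: for '+' guides the editor's source base is
#' replaced by the target base; for '-' guides the complementary change is
#' written.
#'
#' @param cds coding sequence.
#' @param guide one-row guide record (spacer, strand, cdna_start).
#' @param positions integer vector of spacer positions to edit.
#' @param profile an \code{\link{editor_profile}}.
#' @return The edited coding sequence.
#' @export
apply_edits_to_cds <- function(cds, guide, positions, profile) {
  if (length(positions) == 0) return(cds)
  s <- chars(cds)
  for (p in positions) {
    cp <- spacer_to_cds_pos(p, guide$strand, guide$cdna_start, nchar(cds))
    if (guide$strand == "+") {
      stopifnot(s[cp] == profile$source_base)
      s[cp] <- profile$target_base
    } else {
      stopifnot(s[cp] == COMPLEMENT[profile$source_base])
      s[cp] <- COMPLEMENT[profile$target_base]
    }
  }
  paste(s, collapse = "")
}
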