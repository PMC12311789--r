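## Verification-screen arm: direct edit calling from paired amplicon reads
## with quality gating, cis grouping, background thresholds from negative
## controls, WT-anchored edit growth rates, and guide linkage with
## major-edit identification.

## Align a batch of equal-width reads to the reference by anchored offset:
## tries every allowed start within the stagger range and keeps the one
## with the fewest mismatches (reads are gapless by construction).
anchor_offset <- function(seq_mat, ref_codes, max_stagger) {
  w <- ncol(seq_mat)
  L <- length(ref_codes)
  starts <- which(seq_len(L - w + 1) <= max_stagger + 1)
  if (length(starts) == 0)
    stop("read length incompatible with reference beyond the stagger range")
  mm <- vapply(starts, function(s) {
    ref <- matrix(ref_codes[s:(s + w - 1)], nrow(seq_mat), w, byrow = TRUE)
    rowSums(seq_mat != ref)
  }, numeric(nrow(seq_mat)))
  mm <- matrix(mm, nrow = nrow(seq_mat))
  starts[max.col(-mm, ties.method = "first")]
}

#' Call cis edit alleles from paired reads with quality gating
#'
#' Aligns each mate gaplessly to the reference amplicon (anchored offset
#' within the stagger range), then keeps a mismatch as a bona fide edit
#' only where both mates cover the position, agree on the substituted
#' base, and both base calls exceed \code{min_q}. All kept mismatches on a
#' pair form one cis allele; pairs with no kept mismatch count as wild
#' type. Mate 2 is expected reverse-complemented (as sequenced).
#'
#' @param r1,r2 data frames with columns \code{seq} and \code{qual}
#'   (Phred+33), one row per pair, in matching order.
#' @param reference amplicon reference sequence.
#' @param min_q minimum Phred quality, exclusive (default 20).
#' @param max_stagger maximum read-start stagger in nt (default 7).
#' @return List with \code{alleles} (data frame: \code{allele}
#'   ("pos:ref>alt" comma-joined), \code{count}), \code{wt_count},
#'   \code{n_pairs}, and \code{per_pair} (character vector of allele
#'   strings, \code{""} = WT).
#' @export
call_edits_paired <- function(r1, r2, reference, min_q = 20,
                              max_stagger = 7) {
  stopifnot(nrow(r1) == nrow(r2))
  L <- nchar(reference)
  ref_codes <- match(chars(reference), BASES)
  n <- nrow(r1)
  if (n == 0)
    return(list(alleles = data.frame(allele = character(0),
                                     count = integer(0),
                                     stringsAsFactors = FALSE),
                wt_count = 0L, n_pairs = 0L, per_pair = character(0)))
  if (any(nchar(r1$seq) > L) || any(nchar(r2$seq) > L))
    stop("read longer than the reference")

  ## Expand each mate into (n x L) base-code and quality matrices on
  ## reference coordinates, NA outside the covered range.
  expand_mate <- function(seqs, quals, orient_rev) {
    base_m <- matrix(NA_integer_, n, L)
    qual_m <- matrix(NA_integer_, n, L)
    code2idx <- integer(128)
    code2idx[utf8ToInt(paste(BASES, collapse = ""))] <- 1:4
    for (w in unique(nchar(seqs))) {
      sel <- which(nchar(seqs) == w)
      sm <- matrix(code2idx[utf8ToInt(paste(seqs[sel], collapse = ""))],
                   length(sel), w, byrow = TRUE)
      qm <- matrix(utf8ToInt(paste(quals[sel], collapse = "")) - 33L,
                   length(sel), w, byrow = TRUE)
      if (orient_rev) {          # un-reverse-complement mate 2
        sm <- 5L - sm[, rev(seq_len(w)), drop = FALSE]
        qm <- qm[, rev(seq_len(w)), drop = FALSE]
        ## mate 2 covers a prefix of the amplicon
        starts <- rep(1L, length(sel))
        ends <- rep(w, length(sel))
        if (w < L - max_stagger)
          stop("read length incompatible with reference beyond the stagger")
      } else {
        ## mate 1 covers a suffix; find its start by anchored alignment
        starts <- anchor_offset(sm, ref_codes, max_stagger)
        ends <- starts + w - 1L
      }
      for (st in unique(starts)) {
        kk <- which(starts == st)
        cols <- st:(st + w - 1L)
        base_m[sel[kk], cols] <- sm[kk, , drop = FALSE]
        qual_m[sel[kk], cols] <- qm[kk, , drop = FALSE]
      }
    }
    list(base = base_m, qual = qual_m)
  }
  ## base complement in code space: A=1,C=2,G=3,T=4 -> 5 - code
  m1 <- expand_mate(r1$seq, r1$qual, orient_rev = FALSE)
  m2 <- expand_mate(r2$seq, r2$qual, orient_rev = TRUE)

  refm <- matrix(ref_codes, n, L, byrow = TRUE)
  keep <- !is.na(m1$base) & !is.na(m2$base) &
    m1$base != refm & m2$base != refm &
    m1$base == m2$base &
    m1$qual > min_q & m2$qual > min_q
  hits <- which(keep, arr.ind = TRUE)
  per_pair <- rep("", n)
  if (nrow(hits) > 0) {
    ord <- order(hits[, 1], hits[, 2])
    hits <- hits[ord, , drop = FALSE]
    lab <- sprintf("%d:%s>%s", hits[, 2],
                   BASES[ref_codes[hits[, 2]]],
                   BASES[m1$base[hits]])
    grouped <- vapply(split(lab, hits[, 1]), paste, character(1),
                      collapse = ",")
    per_pair[as.integer(names(grouped))] <- grouped
  }
  wt_count <- sum(per_pair == "")
  tab <- table(per_pair[per_pair != ""])
  list(
    alleles = data.frame(allele = names(tab), count = as.integer(tab),
                         stringsAsFactors = FALSE, row.names = NULL),
    wt_count = wt_count,
    n_pairs = n,
    per_pair = per_pair
  )
}

#' Background mutation-frequency threshold from negative controls
#'
#' Per replicate, takes the given percentile of the per-position mutant
#' frequencies observed in a negative-control library; the threshold is
#' the mean of the replicate percentiles.
#'
#' @param control_freqs list of numeric vectors (one per replicate) of
#'   per-position mutant frequencies, or a matrix with one column per
#'   replicate.
#' @param pct percentile (default 95).
#' @return List with \code{threshold} and \code{method}.
#' @export
background_threshold <- function(control_freqs, pct = 95) {
  if (is.matrix(control_freqs))
    control_freqs <- lapply(seq_len(ncol(control_freqs)),
                            function(j) control_freqs[, j])
  if (length(control_freqs) == 0 || all(lengths(control_freqs) == 0))
    stop("no control frequencies supplied")
  per_rep <- vapply(control_freqs, function(f)
    unname(quantile(f, pct / 100)), numeric(1))
  list(threshold = mean(per_rep), method = sprintf("p%g_negative_control", pct))
}

#' Growth rates of observed edit alleles anchored to wild-type reads
#'
#' The wild-type (no-mismatch) read fraction anchors the growth-rate
#' scale: an allele tracking WT exactly grows at the wild-type rate, and
#' \deqn{r_i = r_{WT} + \ln\left[(f_{i1}/f_{WT,1}) / (f_{i0}/f_{WT,0})\right]
#'   / \Delta t.}
#' Alleles are filtered against a frequency threshold before estimation
#' (permissive background threshold or the stringent 1\% mode).
#'
#' @param allele_counts long data frame: \code{allele},
#'   \code{timepoint_h}, \code{replicate}, \code{count}.
#' @param wt_counts data frame: \code{timepoint_h}, \code{replicate},
#'   \code{count} of no-mismatch pairs, plus \code{total} pairs per
#'   sample.
#' @param freq_min frequency threshold; alleles whose mean baseline
#'   frequency falls below it are dropped (e.g. the permissive 0.00015 or
#'   stringent 0.01).
#' @param wt_rate wild-type growth rate in h^-1 (default 0.055).
#' @param pseudo_count substituted for zero counts (default 0.5), flagged.
#' @return Data frame: \code{allele}, \code{freq_t0}, \code{rate},
#'   \code{n_replicates}, \code{floored}.
#' @export
edit_growth_rates <- function(allele_counts, wt_counts, freq_min = 0,
                              wt_rate = 0.055, pseudo_count = 0.5) {
  t0 <- min(allele_counts$timepoint_h)
  t1 <- max(allele_counts$timepoint_h)
  if (t1 <= t0) stop("two timepoints are required")
  dt <- t1 - t0
  wt_key <- paste(wt_counts$timepoint_h, wt_counts$replicate)
  if (any(wt_counts$count <= 0))
    stop("WT (no-mismatch) counts must be positive at every sample")

  ## baseline frequency per allele (mean over replicates, over total pairs)
  base <- allele_counts[allele_counts$timepoint_h == t0, ]
  tot0 <- wt_counts$total[match(paste(t0, base$replicate), wt_key)]
  f0 <- tapply(base$count / tot0, base$allele, mean)

  keep <- names(f0)[f0 >= freq_min]
  out <- lapply(keep, function(a) {
    sub <- allele_counts[allele_counts$allele == a, ]
    reps <- sort(unique(sub$replicate))
    rr <- vapply(reps, function(r) {
      c0 <- sub$count[sub$timepoint_h == t0 & sub$replicate == r]
      c1 <- sub$count[sub$timepoint_h == t1 & sub$replicate == r]
      c0 <- if (length(c0)) c0 else 0
      c1 <- if (length(c1)) c1 else 0
      w0 <- wt_counts$count[match(paste(t0, r), wt_key)]
      w1 <- wt_counts$count[match(paste(t1, r), wt_key)]
      floored <- c0 == 0 || c1 == 0
      c0 <- max(c0, pseudo_count)
      c1 <- max(c1, pseudo_count)
      c(rate = wt_rate + log((c1 / w1) / (c0 / w0)) / dt,
        floored = as.numeric(floored))
    }, numeric(2))
    data.frame(allele = a, freq_t0 = unname(f0[a]),
               rate = mean(rr["rate", ]),
               n_replicates = length(reps),
               floored = any(rr["floored", ] > 0),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(allele = character(0), freq_t0 = numeric(0),
                      rate = numeric(0), n_replicates = integer(0),
                      floored = logical(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Link observed alleles to guides and identify each guide's major edit
#'
#' An allele is linked to a guide if and only if every edited position
#' falls inside that guide's editing-window interval on the coding strand.
#' Alleles linkable to more than one guide are flagged ambiguous and
#' excluded from per-guide statistics. The major edit is the allele whose
#' frequency exceeds half the summed edited-allele frequency of its guide
#' (strictly; an exact tie yields no major edit).
#'
#' @param alleles data frame with columns \code{allele} (cis edit string,
#'   "pos:ref>alt" comma-joined), \code{freq} (frequency used for the
#'   major-edit share) and optionally \code{rate}.
#' @param guide_windows data frame: \code{guide_id}, \code{win_start},
#'   \code{win_end} (coding-strand interval of the editing window).
#' @return List with \code{linked} (alleles plus \code{guide_id},
#'   \code{share}, \code{is_major}) and \code{ambiguous} (alleles linked
#'   to several guides, excluded).
#' @export
link_and_major_edit <- function(alleles, guide_windows) {
  if (nrow(alleles) == 0)
    return(list(linked = cbind(alleles,
                               data.frame(guide_id = character(0),
                                          share = numeric(0),
                                          is_major = logical(0))),
                ambiguous = alleles[0, , drop = FALSE]))
  pos_list <- lapply(strsplit(alleles$allele, ",", fixed = TRUE),
                     function(parts)
                       as.integer(sub(":.*$", "", parts)))
  links <- lapply(pos_list, function(p) {
    which(vapply(seq_len(nrow(guide_windows)), function(i)
      all(p >= guide_windows$win_start[i] & p <= guide_windows$win_end[i]),
      logical(1)))
  })
  n_links <- lengths(links)
  ambiguous <- alleles[n_links > 1, , drop = FALSE]
  linked <- alleles[n_links == 1, , drop = FALSE]
  linked$guide_id <- guide_windows$guide_id[unlist(links[n_links == 1])]
  unlinked <- alleles[n_links == 0, , drop = FALSE]

  if (nrow(linked) > 0) {
    tot <- tapply(linked$freq, linked$guide_id, sum)
    linked$share <- linked$freq / unname(tot[linked$guide_id])
    linked$is_major <- linked$share > 0.5
  } else {
    linked$share <- numeric(0)
    linked$is_major <- logical(0)
  }
  list(linked = linked, ambiguous = ambiguous, unlinked = unlinked)
}
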