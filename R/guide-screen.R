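## Guide-screen arm: sgRNA counting, median-of-ratios normalisation and
## log2 fold changes, conversion to growth rates, negative-control Z-score
## hit calling, and the sliding-window essentiality profile.

#' Count sgRNA reads against a guide library
#'
#' Removes a fixed-width 5' context, extracts the 20-nt spacer, and counts
#' exact matches to the library. Optionally rescues reads whose spacer has
#' exactly one mismatch to a unique library spacer (off by default).
#'
#' @param reads character vector of reads (5' context + spacer + scaffold).
#' @param library guide library with columns \code{guide_id},
#'   \code{spacer}; spacers must be unique.
#' @param context5_width number of fixed bases preceding the spacer.
#' @param rescue_1mm if TRUE, assign unmatched reads with exactly one
#'   spacer mismatch to their unique closest guide.
#' @return List with \code{counts} (data frame: guide_id, count, covering
#'   every library guide) and \code{n_unmatched}.
#' @export
count_guides <- function(reads, library, context5_width = 4,
                         rescue_1mm = FALSE) {
  if (anyDuplicated(library$spacer))
    stop("duplicate spacers in library")
  spacers <- substring(reads, context5_width + 1, context5_width + 20)
  idx <- match(spacers, library$spacer)
  unmatched <- spacers[is.na(idx)]
  if (rescue_1mm && length(unmatched) > 0) {
    lib_mat <- do.call(rbind, strsplit(library$spacer, "", fixed = TRUE))
    rescue <- vapply(unique(unmatched), function(s) {
      sm <- chars(s)
      if (length(sm) != 20) return(NA_integer_)
      d <- rowSums(lib_mat != matrix(sm, nrow(lib_mat), 20, byrow = TRUE))
      hit <- which(d == 1)
      if (length(hit) == 1) hit else NA_integer_
    }, integer(1))
    idx[is.na(idx)] <- rescue[unmatched]
  }
  tab <- table(factor(library$guide_id[idx], levels = library$guide_id))
  list(
    counts = data.frame(guide_id = library$guide_id,
                        count = as.integer(tab),
                        stringsAsFactors = FALSE),
    n_unmatched = sum(is.na(idx))
  )
}

#' Log2 fold changes between timepoints with median-of-ratios normalisation
#'
#' Computes per-sample size factors by the median-of-ratios method (each
#' sample's counts divided by the per-guide geometric mean across samples;
#' the size factor is the median of those ratios over guides), normalises,
#' and reports the log2 fold change of mean normalised counts between the
#' two timepoints with a pseudocount. P-values come from a normal test on
#' the per-replicate log2 ratios, Benjamini-Hochberg adjusted.
#'
#' @param counts long data frame: \code{guide_id} (or \code{id}),
#'   \code{timepoint_h}, \code{replicate}, \code{count}.
#' @param t0,t1 timepoints to compare; default the smallest and largest.
#' @param pseudocount added to normalised means before the log2 (default
#'   0.5).
#' @return Data frame: \code{guide_id}, \code{mean_t0}, \code{mean_t1}
#'   (normalised), \code{log2_fc}, \code{p_value}, \code{adj_p}.
#' @export
estimate_log2fc <- function(counts, t0 = NULL, t1 = NULL, pseudocount = 0.5) {
  if ("id" %in% names(counts) && !("guide_id" %in% names(counts)))
    names(counts)[names(counts) == "id"] <- "guide_id"
  if (is.null(t0)) t0 <- min(counts$timepoint_h)
  if (is.null(t1)) t1 <- max(counts$timepoint_h)
  counts <- counts[counts$timepoint_h %in% c(t0, t1), ]
  counts$sample <- paste0("t", counts$timepoint_h, "_r", counts$replicate)
  guides <- unique(counts$guide_id)
  m <- matrix(0, length(guides), length(unique(counts$sample)),
              dimnames = list(guides, unique(counts$sample)))
  m[cbind(match(counts$guide_id, guides),
          match(counts$sample, colnames(m)))] <- counts$count
  if (any(colSums(m) == 0)) stop("a sample has zero total counts")

  log_geo <- rowMeans(log(m + ifelse(m == 0, NA, 0)), na.rm = FALSE)
  ok <- is.finite(log_geo)
  if (!any(ok)) stop("no guide has nonzero counts in every sample")
  sf <- apply(m[ok, , drop = FALSE], 2, function(col)
    median(col / exp(log_geo[ok])))
  norm <- sweep(m, 2, sf, "/")

  s0 <- grepl(paste0("^t", t0, "_"), colnames(norm))
  s1 <- grepl(paste0("^t", t1, "_"), colnames(norm))
  mean_t0 <- rowMeans(norm[, s0, drop = FALSE])
  mean_t1 <- rowMeans(norm[, s1, drop = FALSE])
  log2_fc <- log2((mean_t1 + pseudocount) / (mean_t0 + pseudocount))

  n0 <- sum(s0); n1 <- sum(s1)
  nrep <- max(n0, n1)
  i0 <- rep(which(s0), length.out = nrep)
  i1 <- rep(which(s1), length.out = nrep)
  lr <- log2((norm[, i1, drop = FALSE] + pseudocount) /
               (norm[, i0, drop = FALSE] + pseudocount))
  if (nrep >= 2) {
    mu <- rowMeans(lr)
    se <- apply(lr, 1, sd) / sqrt(nrep)
    z <- mu / se
    p <- 2 * pnorm(-abs(z))
    p[se == 0 & mu != 0] <- 0
    p[se == 0 & mu == 0] <- 1
  } else {
    p <- rep(NA_real_, length(mean_t0))
  }
  data.frame(guide_id = guides, mean_t0 = mean_t0, mean_t1 = mean_t1,
             log2_fc = unname(log2_fc), p_value = unname(p),
             adj_p = unname(p.adjust(p, "BH")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Convert log2 fold changes to growth rates
#'
#' Interprets the (control-centred) frequency fold change of a guide
#' against a background population growing at the wild-type rate:
#' \deqn{r = r_{WT} + (log2FC - \bar{c}) \cdot \ln 2 / \Delta t,}
#' where \eqn{\bar{c}} is the mean log2 fold change of designated control
#' guides (0 when none are given).
#'
#' @param log2_fc numeric vector of log2 fold changes.
#' @param delta_t elapsed time between the timepoints, in hours (> 0).
#' @param wt_rate wild-type growth rate in h^-1 (default 0.055).
#' @param control_lfc log2 fold changes of control guides used for
#'   centring (optional).
#' @return Growth rates in h^-1.
#' @export
guide_growth_rate <- function(log2_fc, delta_t, wt_rate = 0.055,
                              control_lfc = NULL) {
  if (delta_t <= 0) stop("delta_t must be > 0")
  centre <- if (is.null(control_lfc)) 0 else mean(control_lfc)
  wt_rate + (log2_fc - centre) * log(2) / delta_t
}

#' Call depleting guides against negative controls
#'
#' Two hit definitions are emitted: a Z-score call, where each guide's
#' growth rate is standardised against the negative-control rate
#' distribution and hits fall below \code{z_cutoff}; and a fold-change
#' call (depleting guides), requiring log2 fold change below zero and
#' adjusted p below 0.05.
#'
#' @param stats data frame with columns \code{guide_id}, \code{rate},
#'   \code{log2_fc}, \code{adj_p}.
#' @param control_ids guide ids of the negative controls (>= 20 required
#'   for the Z mode).
#' @param z_cutoff Z-score threshold (default -2).
#' @return The input with added columns \code{z_score}, \code{is_hit}
#'   (Z call) and \code{is_depleting} (fold-change call).
#' @export
call_guide_hits <- function(stats, control_ids, z_cutoff = -2) {
  ctrl <- stats$rate[stats$guide_id %in% control_ids]
  if (length(ctrl) < 20)
    stop("at least 20 negative controls are required for Z-score calling")
  mu <- mean(ctrl)
  sigma <- sd(ctrl)
  if (sigma == 0) stop("negative-control rate SD is zero")
  stats$z_score <- (stats$rate - mu) / sigma
  stats$is_hit <- stats$z_score < z_cutoff
  stats$is_depleting <- stats$log2_fc < 0 &
    !is.na(stats$adj_p) & stats$adj_p < 0.05
  stats
}

#' High-confidence guide filter by library frequency
#'
#' Flags guides whose mean baseline frequency reaches a cutoff --
#' conventionally 1:10,000 when comparing large screens across cell
#' lines, or 1\% for small validation pools -- so that poorly sampled
#' guides can be excluded from cross-screen comparisons.
#'
#' @param counts long data frame: \code{guide_id} (or \code{id}),
#'   \code{timepoint_h}, \code{replicate}, \code{count}.
#' @param min_frequency minimum mean frequency at the baseline timepoint
#'   (e.g. \code{1e-4} or \code{0.01}).
#' @param t0 baseline timepoint; default the smallest present.
#' @return Data frame: \code{guide_id}, \code{frequency},
#'   \code{high_confidence}.
#' @export
filter_high_confidence_guides <- function(counts, min_frequency = 1e-4,
                                          t0 = NULL) {
  if ("id" %in% names(counts) && !("guide_id" %in% names(counts)))
    names(counts)[names(counts) == "id"] <- "guide_id"
  if (is.null(t0)) t0 <- min(counts$timepoint_h)
  base <- counts[counts$timepoint_h == t0, ]
  totals <- tapply(base$count, base$replicate, sum)
  base$freq <- base$count / as.numeric(totals[as.character(base$replicate)])
  f <- tapply(base$freq, base$guide_id, mean)
  data.frame(guide_id = names(f), frequency = as.numeric(f),
             high_confidence = as.numeric(f) >= min_frequency,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sliding-window proportion of strongly depleting guides
#'
#' Orders guides along the coding sequence and reports, for every
#' consecutive window of \code{window} guides (step 1), the fraction with
#' Z-score below \code{z_threshold}. The profile is indexed by the
#' position of the window's centre guide.
#'
#' @param z numeric vector of guide Z-scores, ordered by position.
#' @param positions cDNA positions of the guides (same order as \code{z}).
#' @param window window size in guides (default 40).
#' @param z_threshold depletion threshold (default -4).
#' @return Data frame: \code{window_index}, \code{center_pos},
#'   \code{proportion}; \code{length(z) - window + 1} rows.
#' @export
sliding_window_profile <- function(z, positions, window = 40,
                                   z_threshold = -4) {
  n <- length(z)
  if (n < window) stop("fewer guides than the window size")
  if (length(positions) != n) stop("positions must match z in length")
  extreme <- as.numeric(z < z_threshold)
  csum <- c(0, cumsum(extreme))
  starts <- seq_len(n - window + 1)
  prop <- (csum[starts + window] - csum[starts]) / window
  centre <- positions[starts + ceiling(window / 2) - 1]
  data.frame(window_index = starts, center_pos = centre,
             proportion = prop)
}
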