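## DMS arm: UMI consensus building, codon-aware variant calling, the
## two-timepoint growth-rate estimator, skew-normal mixture fitting over
## the bimodal rate distribution, and Z-score hit calling.

#' Timepoint observation: allele frequency, cell count, time
#'
#' Bundles the operands of the growth-rate estimator: the mutant allele
#' frequency (MAF), the dilution-corrected viable-cell count, and the time
#' in hours.
#'
#' @param maf mutant allele frequency in [0, 1].
#' @param cell_count viable-cell count (> 0), corrected for any splits.
#' @param time_h time in hours (>= 0).
#' @return An object of class \code{timepoint_obs}.
#' @export
timepoint_obs <- function(maf, cell_count, time_h) {
  if (!is.numeric(maf) || maf < 0 || maf > 1)
    stop("maf must be in [0, 1]")
  if (!is.numeric(cell_count) || cell_count <= 0)
    stop("cell_count must be > 0")
  if (!is.numeric(time_h) || time_h < 0)
    stop("time_h must be >= 0")
  structure(list(maf = maf, cell_count = cell_count, time_h = time_h),
            class = "timepoint_obs")
}

#' Growth rate from two timepoint observations
#'
#' The exponential growth-rate estimator
#' \deqn{r = \ln\left(\frac{MAF_1 \cdot Count_1}{MAF_0 \cdot Count_0}\right)
#'   / (Time_1 - Time_0)}
#' in h^-1. Cell counts are the split-corrected viable totals, so the
#' product MAF x Count is the absolute abundance of the mutant. A zero
#' final-timepoint MAF is floored at \code{pseudo_maf} (with a warning) to
#' keep the logarithm finite; a zero baseline MAF is not estimable.
#'
#' @param obs0,obs1 \code{\link{timepoint_obs}} objects (or lists with
#'   fields \code{maf}, \code{cell_count}, \code{time_h}).
#' @param pseudo_maf floor applied to \code{obs1$maf} when it is zero;
#'   conventionally 0.5 / total reads. \code{NULL} (default) raises an
#'   error on zero.
#' @return Growth rate in h^-1.
#' @export
growth_rate_from_counts <- function(obs0, obs1, pseudo_maf = NULL) {
  if (obs1$time_h <= obs0$time_h)
    stop("time1 must be greater than time0")
  if (obs0$maf <= 0)
    stop("baseline MAF must be > 0")
  maf1 <- obs1$maf
  if (maf1 == 0) {
    if (is.null(pseudo_maf))
      stop("final MAF is 0; supply pseudo_maf to floor it")
    warning("final MAF floored at pseudo_maf")
    maf1 <- pseudo_maf
  }
  log((maf1 * obs1$cell_count) / (obs0$maf * obs0$cell_count)) /
    (obs1$time_h - obs0$time_h)
}

#' Per-variant growth rates from a long count table
#'
#' Applies the two-timepoint growth-rate estimator to every id in a long
#' count table (as produced by \code{\link{simulate_screen_counts}} or read
#' from disk), converting counts to allele frequencies per sample and
#' using the supplied viable-cell counts. Rates are averaged across
#' replicates.
#'
#' @param counts long data frame: \code{id}, \code{timepoint_h},
#'   \code{replicate}, \code{count}.
#' @param pop data frame of viable cells: \code{timepoint_h},
#'   \code{replicate}, \code{cells}.
#' @param t0,t1 the two timepoints (hours) to compare; default the
#'   smallest and largest in the table.
#' @param pseudo_count added to zero final counts (default 0.5), flagged
#'   in the output.
#' @return Data frame: \code{variant_id}, \code{rate} (mean across
#'   replicates), \code{n_replicates}, \code{floored} (TRUE if any
#'   replicate needed the pseudocount).
#' @export
variant_growth_rates <- function(counts, pop, t0 = NULL, t1 = NULL,
                                 pseudo_count = 0.5) {
  if (is.null(t0)) t0 <- min(counts$timepoint_h)
  if (is.null(t1)) t1 <- max(counts$timepoint_h)
  if (t1 <= t0) stop("t1 must be greater than t0")
  reps <- sort(unique(counts$replicate))
  per_rep <- lapply(reps, function(r) {
    c0 <- counts[counts$timepoint_h == t0 & counts$replicate == r, ]
    c1 <- counts[counts$timepoint_h == t1 & counts$replicate == r, ]
    c1 <- c1[match(c0$id, c1$id), ]
    n0 <- sum(c0$count); n1 <- sum(c1$count)
    cells0 <- pop$cells[pop$timepoint_h == t0 & pop$replicate == r]
    cells1 <- pop$cells[pop$timepoint_h == t1 & pop$replicate == r]
    floored <- c1$count == 0
    cnt1 <- ifelse(floored, pseudo_count, c1$count)
    rate <- log((cnt1 / n1 * cells1) / (c0$count / n0 * cells0)) / (t1 - t0)
    data.frame(id = c0$id, rate = rate, floored = floored,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_rep)
  agg <- aggregate(rate ~ id, all, mean)
  flo <- aggregate(floored ~ id, all, any)
  nrep <- aggregate(cbind(n_replicates = rate) ~ id, all, length)
  out <- Reduce(function(a, b) merge(a, b, by = "id"),
                list(agg, nrep, flo))
  names(out)[names(out) == "id"] <- "variant_id"
  out
}

#' Build single-strand consensus reads from UMI families
#'
#' Groups reads by UMI and takes a per-position majority vote within each
#' family of at least \code{min_family} reads; ties become \code{N}.
#' Reads must share a common alignment frame with the reference amplicon
#' (equal width).
#'
#' @param reads data frame with columns \code{umi} and \code{seq} (equal
#'   widths).
#' @param min_family minimum family size (default 3); smaller families are
#'   dropped and counted in the discard log.
#' @return List with \code{consensus} (data frame: umi, seq, family_size)
#'   and \code{discarded} (data frame: umi, family_size).
#' @export
build_umi_consensus <- function(reads, min_family = 3) {
  if (nrow(reads) == 0)
    return(list(consensus = data.frame(umi = character(0),
                                       seq = character(0),
                                       family_size = integer(0),
                                       stringsAsFactors = FALSE),
                discarded = data.frame(umi = character(0),
                                       family_size = integer(0),
                                       stringsAsFactors = FALSE)))
  if (length(unique(nchar(reads$seq))) != 1L)
    stop("reads must share a common alignment frame (equal width)")
  fams <- split(reads$seq, reads$umi)
  sizes <- lengths(fams)
  keep <- sizes >= min_family
  consensus_of <- function(seqs) {
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    apply(m, 2, function(col) {
      tab <- table(col)
      top <- tab[tab == max(tab)]
      if (length(top) > 1) "N" else names(top)
    })
  }
  cons <- vapply(fams[keep], function(s)
    paste(consensus_of(s), collapse = ""), character(1))
  list(
    consensus = data.frame(umi = names(cons), seq = unname(cons),
                           family_size = unname(sizes[keep]),
                           stringsAsFactors = FALSE),
    discarded = data.frame(umi = names(fams)[!keep],
                           family_size = unname(sizes[!keep]),
                           stringsAsFactors = FALSE)
  )
}

#' Call amino-acid variants from consensus reads
#'
#' Compares each consensus (gapless, aligned to the reference coding
#' sequence) against the reference, retains reads with at most
#' \code{max_mismatches} mismatches, and converts mismatches to codon-aware
#' amino-acid substitutions. Zero-mismatch reads are tallied as wild type.
#' \code{N} positions are ignored.
#'
#' @param consensus data frame with column \code{seq} (width equal to the
#'   reference length).
#' @param cds reference coding sequence.
#' @param max_mismatches maximum mismatches for a read to qualify
#'   (default 4, i.e. reads with five or more are excluded).
#' @return List with \code{variant_counts} (data frame: variant_id,
#'   count), \code{wt_count}, \code{n_retained}, \code{n_excluded}.
#' @export
call_variants <- function(consensus, cds, max_mismatches = 4) {
  ref <- chars(cds)
  wt <- 0L
  excluded <- 0L
  tallies <- new.env(parent = emptyenv())
  for (s in consensus$seq) {
    if (nchar(s) != length(ref)) {
      excluded <- excluded + 1L
      next
    }
    sc <- chars(s)
    mm <- which(sc != ref & sc != "N")
    if (length(mm) > max_mismatches) {
      excluded <- excluded + 1L
      next
    }
    if (length(mm) == 0) {
      wt <- wt + 1L
      next
    }
    aa <- map_edit_to_protein(
      data.frame(cds_pos = mm, ref_base = ref[mm], alt_base = sc[mm],
                 stringsAsFactors = FALSE), cds)
    aa <- aa[aa$consequence != "synonymous", , drop = FALSE]
    if (nrow(aa) == 0) {
      wt <- wt + 1L
      next
    }
    for (v in aa$variant_id)
      assign(v, (get0(v, envir = tallies, ifnotfound = 0L)) + 1L,
             envir = tallies)
  }
  ids <- ls(tallies)
  variant_counts <- data.frame(
    variant_id = ids,
    count = vapply(ids, get, numeric(1), envir = tallies),
    stringsAsFactors = FALSE)
  rownames(variant_counts) <- NULL
  list(variant_counts = variant_counts, wt_count = wt,
       n_retained = nrow(consensus) - excluded, n_excluded = excluded)
}

#' Fit a two-component skew-normal mixture to growth rates
#'
#' Bins the rates into a density-normalised histogram (Freedman-Diaconis
#' bins) and fits \eqn{w\,SN(\xi_1,\omega_1,\alpha_1) +
#' (1-w)\,SN(\xi_2,\omega_2,\alpha_2)} by nonlinear least squares.
#' Components are initialised from a deterministic 2-means split of the
#' rates with shapes seeded at zero. The component with the larger
#' distribution mean is labelled WT-like; component means and standard
#' deviations are reported on the moment scale, and the hit cutoff is
#' \code{mean_WT - 2 sd_WT}.
#'
#' @param rates numeric vector of growth rates (>= 100 finite values).
#' @param z_cutoff Z-score defining the cutoff rate (default -2).
#' @return An object of class \code{mixture_fit}: list with
#'   \code{components} (data frame: location, scale, shape, weight, mean,
#'   sd, label), \code{wt_mean}, \code{wt_sd}, \code{cutoff},
#'   \code{flagged} (TRUE for a degenerate or effectively unimodal fit)
#'   and \code{flag_reason}.
#' @export
fit_growth_mixture <- function(rates, z_cutoff = -2) {
  rates <- rates[is.finite(rates)]
  if (length(rates) < 100)
    stop("at least 100 finite rates are required")
  if (sd(rates) == 0) {
    comp <- data.frame(location = rates[1], scale = 0, shape = 0,
                       weight = c(0.5, 0.5), mean = rates[1], sd = 0,
                       label = c("deleterious", "wt_like"),
                       stringsAsFactors = FALSE)
    return(structure(list(components = comp, wt_mean = rates[1],
                          wt_sd = 0, cutoff = rates[1], z_cutoff = z_cutoff,
                          flagged = TRUE,
                          flag_reason = "degenerate: all rates identical"),
                     class = "mixture_fit"))
  }
  h <- hist(rates, breaks = "FD", plot = FALSE)
  x <- h$mids
  y <- h$density

  km <- kmeans(rates, centers = matrix(quantile(rates, c(0.25, 0.75)), 2, 1))
  grp <- split(rates, km$cluster)
  mu0 <- vapply(grp, mean, numeric(1))
  sd0 <- vapply(grp, sd, numeric(1))
  sd0[!is.finite(sd0) | sd0 <= 0] <- sd(rates) / 10
  w0 <- length(grp[[1]]) / length(rates)
  ord <- order(mu0)

  start <- list(w = w0, xi1 = mu0[ord[1]], om1 = sd0[ord[1]], a1 = 0,
                xi2 = mu0[ord[2]], om2 = sd0[ord[2]], a2 = 0)
  lo <- c(w = 1e-3, xi1 = -Inf, om1 = 1e-6, a1 = -20,
          xi2 = -Inf, om2 = 1e-6, a2 = -20)
  hi <- c(w = 1 - 1e-3, xi1 = Inf, om1 = Inf, a1 = 20,
          xi2 = Inf, om2 = Inf, a2 = 20)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ w * dskewnorm(x, xi1, om1, a1) +
        (1 - w) * dskewnorm(x, xi2, om2, a2),
      start = start, lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("mixture fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  p <- as.list(coef(fit))

  comp <- data.frame(
    location = c(p$xi1, p$xi2),
    scale = c(p$om1, p$om2),
    shape = c(p$a1, p$a2),
    weight = c(p$w, 1 - p$w),
    stringsAsFactors = FALSE)
  comp$mean <- skewnorm_mean(comp$location, comp$scale, comp$shape)
  comp$sd <- skewnorm_sd(comp$location, comp$scale, comp$shape)
  ord <- order(comp$mean)
  comp <- comp[ord, ]
  comp$label <- c("deleterious", "wt_like")

  pooled_sd <- sqrt(sum(comp$weight * comp$sd^2))
  flagged <- min(comp$weight) < 0.02 ||
    diff(comp$mean) < pooled_sd
  flag_reason <- if (!flagged) NA_character_
    else if (min(comp$weight) < 0.02) "component weight below 0.02"
    else "component means closer than one pooled SD"

  wt_mean <- comp$mean[comp$label == "wt_like"]
  wt_sd <- comp$sd[comp$label == "wt_like"]
  structure(list(components = comp, wt_mean = wt_mean, wt_sd = wt_sd,
                 cutoff = wt_mean + z_cutoff * wt_sd, z_cutoff = z_cutoff,
                 flagged = flagged, flag_reason = flag_reason),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Two-component skew-normal mixture fit\n")
  print(x$components, row.names = FALSE)
  cat(sprintf("WT-like mean %.4f, sd %.4f; cutoff (Z = %g): %.4f h^-1\n",
              x$wt_mean, x$wt_sd, x$z_cutoff, x$cutoff))
  if (isTRUE(x$flagged)) cat("flagged:", x$flag_reason, "\n")
  invisible(x)
}

#' Call deleterious variants from growth rates and a mixture fit
#'
#' Computes each variant's Z-score against the WT-like component,
#' \eqn{z = (r - mean_{WT}) / sd_{WT}}, and flags hits below the Z cutoff.
#'
#' @param rates data frame with columns \code{variant_id} and \code{rate}.
#' @param fit a \code{\link{fit_growth_mixture}} result.
#' @param z_cutoff hit threshold on the Z-score (default -2).
#' @return The input with added columns \code{z_score} and \code{is_hit}.
#' @export
call_dms_hits <- function(rates, fit, z_cutoff = -2) {
  if (!inherits(fit, "mixture_fit")) stop("fit must be a mixture_fit")
  if (!is.finite(fit$wt_sd) || fit$wt_sd <= 0)
    stop("WT-like component SD must be positive")
  rates$z_score <- (rates$rate - fit$wt_mean) / fit$wt_sd
  rates$is_hit <- rates$z_score < z_cutoff
  rates
}
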