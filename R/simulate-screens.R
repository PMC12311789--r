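## Whole-screen simulators built on the primitive generators: a tiled
## guide library with negative controls, the pooled guide dropout screen
## (cells per guide propagate at the weighted-model rate), and the
## medium-throughput validation pool where edited cell fractions propagate
## allele by allele and both guides and edits are sequenced.

#' Generate a tiled guide library with negative controls
#'
#' Tiles the reference with every NGN-PAM protospacer on both strands,
#' keeps guides with one to \code{max_editable} editable source bases in
#' the broad window, optionally samples down to \code{n_guides}, and
#' appends negative-control guides (random spacers with no genomic
#' target).
#'
#' @param reference result of \code{\link{generate_reference}}.
#' @param profile an \code{\link{editor_profile}}.
#' @param n_guides optional cap on the number of target guides (sampled).
#' @param n_controls number of negative-control guides (default 60).
#' @param pam_pattern PAM pattern (default "NGN").
#' @param max_editable maximum editable positions in the broad window.
#' @param seed optional integer seed.
#' @return Guide library data frame (guide_id, spacer, pam, strand,
#'   cdna_start, role).
#' @export
generate_guide_library <- function(reference, profile, n_guides = NULL,
                                   n_controls = 60, pam_pattern = "NGN",
                                   max_editable = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lib <- find_protospacers(reference$dna, pam_pattern)
  n_editable <- vapply(lib$spacer, function(sp) {
    s <- chars(sp)
    sum(s == profile$source_base & profile$p > 0)
  }, numeric(1))
  lib <- lib[n_editable >= 1 & n_editable <= max_editable, , drop = FALSE]
  if (!is.null(n_guides) && nrow(lib) > n_guides)
    lib <- lib[sort(sample.int(nrow(lib), n_guides)), , drop = FALSE]
  if (n_controls > 0) {
    ctrl <- data.frame(
      guide_id = sprintf("ctrl_%03d", seq_len(n_controls)),
      spacer = vapply(seq_len(n_controls), function(i)
        paste(sample(BASES, 20, replace = TRUE), collapse = ""),
        character(1)),
      pam = "NGG", strand = "+", cdna_start = NA_integer_,
      role = "negative_control", stringsAsFactors = FALSE)
    lib <- rbind(lib, ctrl)
  }
  rownames(lib) <- NULL
  lib
}

#' Simulate a pooled base-editor guide dropout screen
#'
#' Draws a per-guide editing efficiency from a Beta distribution, builds
#' each guide's editing outcomes under the product bystander model,
#' assigns every outcome its true growth rate from the landscape
#' (multi-amino-acid alleles through the multiplicative null, synonymous
#' and out-of-range edits at the wild-type rate), and propagates each
#' guide's abundance at the weighted-model rate (the proportion-weighted
#' mean of its outcome rates). Negative controls grow at the wild-type
#' rate. Counts are then sampled as in
#' \code{\link{simulate_screen_counts}}.
#'
#' @param library guide library from \code{\link{generate_guide_library}}.
#' @param landscape fitness landscape from
#'   \code{\link{generate_fitness_landscape}}.
#' @param reference result of \code{\link{generate_reference}}.
#' @param profile an \code{\link{editor_profile}}.
#' @param wt_rate wild-type growth rate in h^-1.
#' @param efficiency_beta shape parameters of the per-guide efficiency
#'   Beta distribution (default c(6, 4), mean 0.6).
#' @param depth,count0,timepoints,replicates,concentration,noiseless as in
#'   \code{\link{simulate_screen_counts}}.
#' @param seed optional integer seed.
#' @return List with \code{truth} (guide_id, role, efficiency,
#'   efficiency_score, unedited_proportion, true_rate), \code{outcomes}
#'   (long table: guide_id, positions, proportion, allele_rate,
#'   aa_changes, n_aa), \code{counts}, \code{pop}, \code{depth},
#'   \code{delta_t}.
#' @export
simulate_guide_screen <- function(library, landscape, reference, profile,
                                  wt_rate = 0.055,
                                  efficiency_beta = c(6, 4),
                                  depth = 1e6, count0 = 5e6,
                                  timepoints = c(0, 216), replicates = 3,
                                  concentration = Inf, noiseless = FALSE,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  targets <- library[library$role == "target", , drop = FALSE]
  controls <- library[library$role != "target", , drop = FALSE]
  variant_rates <- data.frame(variant_id = landscape$variant_id,
                              rate = landscape$true_rate,
                              stringsAsFactors = FALSE)
  eff <- rbeta(nrow(targets), efficiency_beta[1], efficiency_beta[2])

  outc_list <- vector("list", nrow(targets))
  truth_list <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    g <- targets[i, ]
    oc <- simulate_editing_outcomes(g$spacer, profile, eff[i])
    oc <- outcome_allele_rates(oc, g, reference$dna, profile,
                               variant_rates, wt_rate)
    ## edits whose variants fall outside the mutagenised range are treated
    ## as neutral in the ground truth
    oc$allele_rate[is.na(oc$allele_rate)] <- wt_rate
    true_rate <- weighted_guide_rate(
      data.frame(proportion = oc$proportion[oc$positions != ""],
                 allele_rate = oc$allele_rate[oc$positions != ""]),
      unedited_proportion = sum(oc$proportion[oc$positions == ""]),
      wt_rate = wt_rate)
    outc_list[[i]] <- cbind(guide_id = g$guide_id, oc,
                            stringsAsFactors = FALSE)
    truth_list[[i]] <- data.frame(
      guide_id = g$guide_id, role = "target", efficiency = eff[i],
      efficiency_score = 100 * eff[i],
      unedited_proportion = sum(oc$proportion[oc$positions == ""]),
      true_rate = true_rate, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_list)
  if (nrow(controls) > 0)
    truth <- rbind(truth, data.frame(
      guide_id = controls$guide_id, role = controls$role,
      efficiency = 0, efficiency_score = NA_real_,
      unedited_proportion = 1, true_rate = wt_rate,
      stringsAsFactors = FALSE))
  sim <- simulate_screen_counts(
    data.frame(id = truth$guide_id, rate = truth$true_rate,
               stringsAsFactors = FALSE),
    depth = depth, count0 = count0, timepoints = timepoints,
    replicates = replicates, concentration = concentration,
    noiseless = noiseless)
  list(truth = truth, outcomes = do.call(rbind, outc_list),
       counts = sim$counts, pop = sim$pop, depth = depth,
       delta_t = diff(range(timepoints)))
}

#' Select validation-pool guides with non-overlapping editing windows
#'
#' Greedily picks target guides whose broad-window coding intervals are
#' pairwise disjoint, guaranteeing unambiguous linkage of observed edits.
#'
#' @param library guide library (targets only are considered).
#' @param profile an \code{\link{editor_profile}}.
#' @param cds_length reference length.
#' @param n_pool maximum number of pool guides.
#' @param max_editable keep guides with at most this many editable broad
#'   window positions (default 3, bounding the outcome count).
#' @param seed optional integer seed.
#' @return The selected guide rows with added \code{win_start},
#'   \code{win_end} columns (coding-strand broad-window interval).
#' @export
select_staggered_guides <- function(library, profile, cds_length,
                                    n_pool = 16, max_editable = 3,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  targets <- library[library$role == "target", , drop = FALSE]
  n_edit <- vapply(targets$spacer, function(sp) {
    s <- chars(sp)
    sum(s == profile$source_base &
          seq_along(s) >= profile$broad[1] & seq_along(s) <= profile$broad[2])
  }, numeric(1))
  targets <- targets[n_edit >= 1 & n_edit <= max_editable, , drop = FALSE]
  targets <- targets[sample.int(nrow(targets)), , drop = FALSE]
  wins <- t(vapply(seq_len(nrow(targets)), function(i)
    window_cds_interval(profile$broad, targets$strand[i],
                        targets$cdna_start[i], cds_length),
    numeric(2)))
  chosen <- integer(0)
  occupied <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(targets))) {
    if (length(chosen) >= n_pool) break
    w <- wins[i, ]
    overlaps <- nrow(occupied) > 0 &&
      any(w[1] <= occupied[, 2] & w[2] >= occupied[, 1])
    if (!overlaps) {
      chosen <- c(chosen, i)
      occupied <- rbind(occupied, w)
    }
  }
  out <- targets[chosen, , drop = FALSE]
  out$win_start <- wins[chosen, 1]
  out$win_end <- wins[chosen, 2]
  rownames(out) <- NULL
  out
}

#' Simulate a medium-throughput validation pool with direct edit sequencing
#'
#' A pool of staggered guides (plus spike-in controls) is sequenced twice
#' at each timepoint: guide amplicons (counts per guide, abundances
#' following the weighted-model forward rate as in the large screen) and
#' edit amplicons (paired reads over the target region drawn from the
#' allele cell fractions, which grow exponentially at their own allele
#' rates, unedited and control cells at the wild-type rate, with
#' substitution errors).
#'
#' @param pool guides from \code{\link{select_staggered_guides}}.
#' @param landscape,reference,profile as in
#'   \code{\link{simulate_guide_screen}}.
#' @param wt_rate wild-type growth rate in h^-1.
#' @param efficiency_beta per-guide efficiency Beta shapes.
#' @param spike_fraction fraction of cells carrying spike-in control
#'   guides (default 0.12).
#' @param n_controls number of spike-in control guides (default 5).
#' @param guide_depth guide-sequencing depth per sample.
#' @param n_pairs edit-sequencing read pairs per sample.
#' @param error_rate per-base substitution error rate.
#' @param timepoints two timepoints in hours (default 0 and 216).
#' @param replicates number of replicates (default 3).
#' @param seed optional integer seed.
#' @return List with \code{truth} (per guide), \code{allele_truth} (per
#'   allele: guide_id, allele label, sequence index, rate, proportions),
#'   \code{guide_counts} (long), \code{reads} (nested list
#'   reads[[replicate]][[timepoint]] of paired-read sets), \code{pool},
#'   \code{delta_t}, \code{n_pairs}.
#' @export
simulate_validation_pool <- function(pool, landscape, reference, profile,
                                     wt_rate = 0.055,
                                     efficiency_beta = c(6, 4),
                                     spike_fraction = 0.12, n_controls = 5,
                                     guide_depth = 1e5, n_pairs = 2e4,
                                     error_rate = 0.003,
                                     timepoints = c(0, 216), replicates = 3,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cds <- reference$dna
  variant_rates <- data.frame(variant_id = landscape$variant_id,
                              rate = landscape$true_rate,
                              stringsAsFactors = FALSE)
  eff <- rbeta(nrow(pool), efficiency_beta[1], efficiency_beta[2])

  allele_rows <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(pool))) {
    g <- pool[i, ]
    oc <- simulate_editing_outcomes(g$spacer, profile, eff[i])
    oc <- outcome_allele_rates(oc, g, cds, profile, variant_rates, wt_rate)
    oc$allele_rate[is.na(oc$allele_rate)] <- wt_rate
    edited <- oc[oc$positions != "", , drop = FALSE]
    lab <- seqs <- character(nrow(edited))
    for (j in seq_len(nrow(edited))) {
      pos <- as.integer(strsplit(edited$positions[j], ",")[[1]])
      cp <- sort(vapply(pos, spacer_to_cds_pos, numeric(1),
                        strand = g$strand, cdna_start = g$cdna_start,
                        cds_length = nchar(cds)))
      ref_b <- substring(cds, cp, cp)
      alt_b <- if (g$strand == "+") profile$target_base
        else unname(COMPLEMENT[profile$target_base])
      lab[j] <- paste(sprintf("%d:%s>%s", cp, ref_b, alt_b), collapse = ",")
      seqs[j] <- apply_edits_to_cds(cds, g, pos, profile)
    }
    allele_rows[[i]] <- data.frame(
      guide_id = g$guide_id, allele = lab, seq = seqs,
      rate = edited$allele_rate, outcome_proportion = edited$proportion,
      aa_changes = edited$aa_changes, n_aa = edited$n_aa,
      stringsAsFactors = FALSE)
    truth_rows[[i]] <- data.frame(
      guide_id = g$guide_id, role = "target", efficiency = eff[i],
      unedited_proportion = sum(oc$proportion[oc$positions == ""]),
      true_rate = weighted_guide_rate(
        data.frame(proportion = edited$proportion,
                   allele_rate = edited$allele_rate),
        unedited_proportion = sum(oc$proportion[oc$positions == ""]),
        wt_rate = wt_rate),
      stringsAsFactors = FALSE)
  }
  alleles <- do.call(rbind, allele_rows)
  truth <- do.call(rbind, truth_rows)
  ctrl_ids <- sprintf("spike_%02d", seq_len(n_controls))
  truth <- rbind(truth, data.frame(
    guide_id = ctrl_ids, role = "spike_in", efficiency = 0,
    unedited_proportion = 1, true_rate = wt_rate, stringsAsFactors = FALSE))

  ## cell fractions at t0: guides even within the target fraction,
  ## controls share the spike fraction; within a guide, outcomes at their
  ## editing proportions
  n_t <- nrow(pool)
  guide_frac <- c(rep((1 - spike_fraction) / n_t, n_t),
                  rep(spike_fraction / n_controls, n_controls))
  names(guide_frac) <- truth$guide_id

  ## per-cell-class (allele or unedited-per-guide or control) fractions
  cls_guide <- c(alleles$guide_id, truth$guide_id)
  cls_rate <- c(alleles$rate, rep(wt_rate, nrow(truth)))
  cls_frac0 <- c(guide_frac[alleles$guide_id] * alleles$outcome_proportion,
                 guide_frac[truth$guide_id] * truth$unedited_proportion)
  cls_allele <- c(seq_len(nrow(alleles)), rep(0L, nrow(truth)))

  allele_seqs <- c(reference$dna, alleles$seq)

  guide_counts <- list()
  reads <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    reads[[r]] <- vector("list", length(timepoints))
    for (ti in seq_along(timepoints)) {
      t <- timepoints[ti]
      w <- cls_frac0 * exp(cls_rate * (t - timepoints[1]))
      frac <- w / sum(w)
      ## guide sequencing: guide abundances follow the weighted-model
      ## forward rate (the proportion-weighted mean of outcome rates),
      ## as in the large screen
      gw <- guide_frac * exp(truth$true_rate * (t - timepoints[1]))
      gf <- gw / sum(gw)
      gcnt <- as.numeric(rmultinom(1, guide_depth, gf))
      guide_counts[[length(guide_counts) + 1L]] <- data.frame(
        guide_id = truth$guide_id, timepoint_h = t, replicate = r,
        count = gcnt, stringsAsFactors = FALSE)
      ## edit sequencing: allele index 0 collapses to the WT sequence
      af <- tapply(frac, cls_allele, sum)
      props <- numeric(length(allele_seqs))
      props[as.integer(names(af)) + 1L] <- af
      reads[[r]][[ti]] <- simulate_paired_reads(
        allele_seqs, props, n_pairs, error_rate = error_rate)
    }
  }
  list(truth = truth, allele_truth = alleles,
       guide_counts = do.call(rbind, guide_counts),
       reads = reads, pool = pool, timepoints = timepoints,
       delta_t = diff(range(timepoints)), n_pairs = n_pairs,
       control_ids = ctrl_ids)
}
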