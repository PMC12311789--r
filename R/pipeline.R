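## End-to-end simulated workflow: one configuration object drives
## simulation, the DMS arm, the guide arm, edit prediction, concordance,
## the weighted model, and the validation pool, in dependency order.

#' Default pipeline configuration
#'
#' Returns the nested configuration list consumed by
#' \code{\link{run_pipeline}}. Defaults describe the study conditions the
#' simulator emulates: a 0.055 h^-1 wild-type growth rate, a bimodal
#' landscape with 56\% deleterious variants centred at 0.02 h^-1, a
#' 6-day (144 h) DMS selection read at depth 1e6 with two replicates, a
#' 9-day (216 h) guide screen with three replicates, an ABE with broad
#' window 2-12 and core window 4-8, Beta(6, 4) per-guide editing
#' efficiency, and a staggered validation pool sequenced as
#' paired reads with substitution errors.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param demo if TRUE, shrink problem sizes for a fast end-to-end run.
#' @return A named list of configuration blocks.
#' @export
default_config <- function(seed = 1, demo = FALSE) {
  list(
    seed = seed,
    wt_rate = 0.055,
    reference = list(orf_length_aa = if (demo) 60 else 80),
    landscape = list(
      deleterious_weight = 0.56,
      deleterious = list(mean = 0.02, sd = 0.006, alpha = 2),
      wt_like = list(mean = 0.055, sd = 0.004, alpha = -2)),
    dms = list(depth = if (demo) 2e5 else 1e6, count0 = 5e6,
               timepoints = c(0, 144), replicates = 2,
               z_cutoff = -2),
    editor = list(editor = "ABE", broad = c(2, 12), core = c(4, 8)),
    guides = list(depth = if (demo) 2e5 else 1e6, count0 = 5e6,
                  timepoints = c(0, 216), replicates = 3,
                  n_controls = 60, efficiency_beta = c(6, 4),
                  z_cutoff = -2, z_window = -4, window_size = 40,
                  efficiency_min = 50),
    weighted_model = list(edit_freq_min = 0.05),
    validation = list(n_pools = if (demo) 1 else 4,
                      n_pool = if (demo) 12 else 16, n_controls = 5,
                      spike_fraction = 0.12,
                      guide_depth = if (demo) 5e4 else 1e5,
                      n_pairs = if (demo) 8e3 else 2e4,
                      error_rate = 0.003, min_q = 20,
                      timepoints = c(0, 216), replicates = 3,
                      freq_permissive = 0.00015, freq_stringent = 0.01)
  )
}

#' Run the complete simulated comparison workflow
#'
#' Executes the stages in dependency order: simulate reference, landscape
#' and screens; estimate DMS variant rates, fit the growth-rate mixture
#' and call hits; count and analyse guides; predict window edits; join
#' and run the concordance filter ladder; fit the weighted sgRNA model;
#' and run the validation-pool edit-sequencing analysis. With the same
#' configuration (including seed) the result is identical between runs.
#'
#' @param config configuration list from \code{\link{default_config}}.
#' @param out_dir optional directory; when given, the main tables are
#'   written there as TSV/JSON.
#' @return A list with one element per stage (\code{reference},
#'   \code{landscape}, \code{dms}, \code{guides}, \code{annotations},
#'   \code{concordance}, \code{weighted}, \code{validation}).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  seed <- config$seed
  wt <- config$wt_rate

  ## --- simulate -----------------------------------------------------
  reference <- generate_reference(config$reference$orf_length_aa,
                                  seed = seed)
  landscape <- generate_fitness_landscape(
    reference$protein,
    deleterious_weight = config$landscape$deleterious_weight,
    wt_rate = wt,
    deleterious = config$landscape$deleterious,
    wt_like = config$landscape$wt_like,
    seed = seed + 1)
  profile <- editor_profile(config$editor$editor,
                            broad = config$editor$broad,
                            core = config$editor$core)
  library <- generate_guide_library(reference, profile,
                                    n_controls = config$guides$n_controls,
                                    seed = seed + 2)

  dms_sim <- simulate_screen_counts(
    data.frame(id = landscape$variant_id, rate = landscape$true_rate,
               stringsAsFactors = FALSE),
    depth = config$dms$depth, count0 = config$dms$count0,
    timepoints = config$dms$timepoints,
    replicates = config$dms$replicates, seed = seed + 3)

  guide_sim <- simulate_guide_screen(
    library, landscape, reference, profile, wt_rate = wt,
    efficiency_beta = config$guides$efficiency_beta,
    depth = config$guides$depth, count0 = config$guides$count0,
    timepoints = config$guides$timepoints,
    replicates = config$guides$replicates, seed = seed + 4)

  ## --- DMS arm ------------------------------------------------------
  dms_rates <- variant_growth_rates(dms_sim$counts, dms_sim$pop)
  names(dms_rates)[names(dms_rates) == "rate"] <- "rate"
  fit <- fit_growth_mixture(dms_rates$rate, z_cutoff = config$dms$z_cutoff)
  dms_hits <- call_dms_hits(dms_rates, fit, z_cutoff = config$dms$z_cutoff)

  ## --- guide arm ----------------------------------------------------
  lfc <- estimate_log2fc(guide_sim$counts)
  ctrl_ids <- library$guide_id[library$role == "negative_control"]
  ctrl_lfc <- lfc$log2_fc[lfc$guide_id %in% ctrl_ids]
  lfc$rate <- guide_growth_rate(lfc$log2_fc, delta_t = guide_sim$delta_t,
                                wt_rate = wt, control_lfc = ctrl_lfc)
  guide_stats <- call_guide_hits(lfc, ctrl_ids,
                                 z_cutoff = config$guides$z_cutoff)

  targets <- library[library$role == "target", ]
  ord <- order(vapply(seq_len(nrow(targets)), function(i)
    spacer_to_cds_pos(1, targets$strand[i], targets$cdna_start[i],
                      nchar(reference$dna)), numeric(1)))
  targ_sorted <- targets[ord, ]
  z_sorted <- guide_stats$z_score[match(targ_sorted$guide_id,
                                        guide_stats$guide_id)]
  pos_sorted <- vapply(seq_len(nrow(targ_sorted)), function(i)
    spacer_to_cds_pos(1, targ_sorted$strand[i], targ_sorted$cdna_start[i],
                      nchar(reference$dna)), numeric(1))
  window_profile <- if (nrow(targ_sorted) >= config$guides$window_size)
    sliding_window_profile(z_sorted, pos_sorted,
                           window = config$guides$window_size,
                           z_threshold = config$guides$z_window) else NULL

  ## --- edit prediction ----------------------------------------------
  efficiency <- guide_sim$truth[guide_sim$truth$role == "target",
                                c("guide_id", "efficiency_score")]
  ann <- annotate_guides(library, reference$dna, profile,
                         efficiency = efficiency,
                         dms_variants = dms_hits$variant_id)
  ann$guides <- classify_guides(ann$guides,
                                efficiency_min = config$guides$efficiency_min)

  ## --- concordance ladder -------------------------------------------
  dms_cmp <- data.frame(variant_id = dms_hits$variant_id,
                        rate = dms_hits$rate, is_hit = dms_hits$is_hit,
                        stringsAsFactors = FALSE)
  rows <- join_guide_variant(guide_stats, dms_cmp, ann, wt_rate = wt)
  ladder <- filter_ladder(rows)

  ## --- weighted model -----------------------------------------------
  outc <- guide_sim$outcomes
  measured <- data.frame(variant_id = dms_hits$variant_id,
                         rate = dms_hits$rate, stringsAsFactors = FALSE)
  outc_measured <- do.call(rbind, lapply(
    split(outc, outc$guide_id), function(ot) {
      g <- targets[targets$guide_id == ot$guide_id[1], ]
      om <- outcome_allele_rates(ot[, c("positions", "proportion")], g,
                                 reference$dna, profile, measured, wt)
      om$guide_id <- ot$guide_id[1]
      om
    }))
  observed <- data.frame(guide_id = guide_stats$guide_id,
                         rate = guide_stats$rate, stringsAsFactors = FALSE)
  weighted <- predict_vs_observe(outc_measured, observed,
                                 edit_freq_min = config$weighted_model$edit_freq_min,
                                 wt_rate = wt)

  ## --- validation pools ---------------------------------------------
  validation <- run_validation_arm(library, landscape, reference, profile,
                                   config$validation, wt_rate = wt,
                                   seed = seed + 5)

  result <- list(reference = reference, landscape = landscape,
                 profile = profile, library = library,
                 dms = list(rates = dms_hits, fit = fit),
                 guides = list(stats = guide_stats,
                               window_profile = window_profile,
                               truth = guide_sim$truth),
                 annotations = ann,
                 concordance = list(rows = rows, ladder = ladder),
                 weighted = weighted,
                 validation = validation)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(c(reference = reference$dna),
                file.path(out_dir, "reference.fasta"))
    write_tsv(landscape, file.path(out_dir, "landscape_truth.tsv"))
    write_tsv(dms_hits, file.path(out_dir, "dms_rates.tsv"))
    write_tsv(guide_stats, file.path(out_dir, "guide_stats.tsv"))
    write_tsv(rows, file.path(out_dir, "comparison_rows.tsv"))
    write_tsv(ladder_table(ladder), file.path(out_dir, "ladder_summary.tsv"))
    write_tsv(weighted$table, file.path(out_dir, "weighted_predictions.tsv"))
    write_tsv(validation$linked, file.path(out_dir, "validation_alleles.tsv"))
    jsonlite::write_json(
      list(seed = seed,
           mixture = list(wt_mean = fit$wt_mean, wt_sd = fit$wt_sd,
                          cutoff = fit$cutoff),
           weighted_r = weighted$r,
           validation_major_r = validation$major_r),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Simulate and analyse the validation arm across several pools
#'
#' Mirrors the two-step workflow in which hits from a large screen are
#' re-examined in medium-sized pools of guides with staggered,
#' non-overlapping editing windows so every observed edit is attributable
#' to one guide. Each pool is simulated and analysed independently
#' (spike-in controls anchor its guide rates); guide-level and
#' major-edit results are then combined across pools and the pooled
#' guide-versus-major-edit Pearson correlation reported.
#'
#' @param library guide library (targets are partitioned into pools).
#' @param landscape,reference,profile as in
#'   \code{\link{simulate_guide_screen}}.
#' @param vcfg validation configuration block (see
#'   \code{\link{default_config}}).
#' @param wt_rate wild-type growth rate in h^-1.
#' @param seed integer seed; pool p uses seed + p.
#' @return As \code{\link{analyse_validation_pool}}, with results
#'   concatenated across pools and \code{major_r} computed on the pooled
#'   major-edit table.
#' @export
run_validation_arm <- function(library, landscape, reference, profile,
                               vcfg, wt_rate = 0.055, seed = 1) {
  remaining <- library
  linked <- list(); majors <- list(); rates <- list(); guides <- list()
  for (p in seq_len(vcfg$n_pools)) {
    pool <- select_staggered_guides(remaining, profile,
                                    nchar(reference$dna),
                                    n_pool = vcfg$n_pool,
                                    seed = seed + 10 * p)
    if (nrow(pool) < 2) break
    remaining <- remaining[!remaining$guide_id %in% pool$guide_id, ,
                           drop = FALSE]
    vsim <- simulate_validation_pool(
      pool, landscape, reference, profile, wt_rate = wt_rate,
      spike_fraction = vcfg$spike_fraction, n_controls = vcfg$n_controls,
      guide_depth = vcfg$guide_depth, n_pairs = vcfg$n_pairs,
      error_rate = vcfg$error_rate, timepoints = vcfg$timepoints,
      replicates = vcfg$replicates, seed = seed + 10 * p + 1)
    va <- analyse_validation_pool(vsim, reference, wt_rate = wt_rate,
                                  min_q = vcfg$min_q,
                                  freq_min = vcfg$freq_permissive,
                                  freq_stringent = vcfg$freq_stringent)
    va$linked$pool <- p
    linked[[p]] <- va$linked
    majors[[p]] <- va$major_table
    rates[[p]] <- cbind(va$allele_rates, pool = p)
    va$guide_rates$pool <- p
    guides[[p]] <- va$guide_rates
  }
  major_table <- do.call(rbind, majors)
  major_r <- if (!is.null(major_table) && nrow(major_table) >= 3 &&
                 sd(major_table$rate_major_edit) > 0 &&
                 sd(major_table$rate_guide) > 0)
    cor(major_table$rate_major_edit, major_table$rate_guide) else NA_real_
  list(allele_rates = do.call(rbind, rates),
       linked = do.call(rbind, linked),
       guide_rates = do.call(rbind, guides),
       major_table = major_table, major_r = major_r)
}

#' Analyse a simulated validation pool
#'
#' Runs the verification-screen analysis on the output of
#' \code{\link{simulate_validation_pool}}: quality-gated paired edit
#' calling per sample, WT-anchored edit growth rates under the frequency
#' threshold, guide growth rates from the spike-in-centred guide counts,
#' linkage of alleles to guides and major-edit identification, and the
#' guide-versus-major-edit correlation.
#'
#' @param vsim result of \code{\link{simulate_validation_pool}}.
#' @param reference result of \code{\link{generate_reference}}.
#' @param wt_rate wild-type growth rate in h^-1.
#' @param min_q quality gate for edit calling (default 20).
#' @param freq_min permissive allele-frequency threshold used for the edit
#'   discovery table (default 0.00015).
#' @param freq_stringent high-confidence threshold (default 0.01, i.e. 1
#'   percent of reads); the per-guide major-edit growth-rate comparison is
#'   restricted to alleles passing it, since growth rates of
#'   near-detection-limit alleles are unreliable.
#' @return List with \code{allele_rates} (permissive table),
#'   \code{linked} (high-confidence rates plus guide linkage and major
#'   flags), \code{guide_rates}, \code{major_r} (Pearson correlation of
#'   guide rate and major-edit rate) and \code{wt_counts}.
#' @export
analyse_validation_pool <- function(vsim, reference, wt_rate = 0.055,
                                    min_q = 20, freq_min = 0.00015,
                                    freq_stringent = 0.01) {
  timepoints <- vsim$timepoints
  allele_counts <- list()
  wt_counts <- list()
  for (r in seq_along(vsim$reads)) {
    for (ti in seq_along(timepoints)) {
      called <- call_edits_paired(vsim$reads[[r]][[ti]]$r1,
                                  vsim$reads[[r]][[ti]]$r2,
                                  reference$dna, min_q = min_q)
      if (nrow(called$alleles) > 0)
        allele_counts[[length(allele_counts) + 1L]] <- cbind(
          called$alleles, timepoint_h = timepoints[ti], replicate = r)
      wt_counts[[length(wt_counts) + 1L]] <- data.frame(
        timepoint_h = timepoints[ti], replicate = r,
        count = called$wt_count, total = called$n_pairs)
    }
  }
  allele_counts <- do.call(rbind, allele_counts)
  wt_counts <- do.call(rbind, wt_counts)

  rates <- edit_growth_rates(allele_counts, wt_counts,
                             freq_min = freq_min, wt_rate = wt_rate)
  rates$freq <- rates$freq_t0
  hc <- rates[rates$freq_t0 >= freq_stringent, , drop = FALSE]
  link <- link_and_major_edit(
    hc, vsim$pool[, c("guide_id", "win_start", "win_end")])

  lfc <- estimate_log2fc(vsim$guide_counts)
  ctrl_lfc <- lfc$log2_fc[lfc$guide_id %in% vsim$control_ids]
  lfc$rate <- guide_growth_rate(lfc$log2_fc, delta_t = vsim$delta_t,
                                wt_rate = wt_rate, control_lfc = ctrl_lfc)

  majors <- link$linked[link$linked$is_major, , drop = FALSE]
  cmp <- merge(majors[, c("guide_id", "rate")],
               lfc[, c("guide_id", "rate")],
               by = "guide_id", suffixes = c("_major_edit", "_guide"))
  major_r <- if (nrow(cmp) >= 3 &&
                 sd(cmp$rate_major_edit) > 0 && sd(cmp$rate_guide) > 0)
    cor(cmp$rate_major_edit, cmp$rate_guide) else NA_real_
  list(allele_rates = rates, linked = link$linked,
       ambiguous = link$ambiguous, guide_rates = lfc,
       major_table = cmp, major_r = major_r, wt_counts = wt_counts)
}
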