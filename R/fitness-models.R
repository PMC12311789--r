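## Analytic fitness models: the multiplicative compound-mutant null and the
## weighted sgRNA growth-rate model, plus prediction-vs-observation
## comparison of guide rates.

#' Multiplicative null model for compound mutants
#'
#' Models the growth rate of a multi-amino-acid mutant as the wild-type
#' rate times the product of the single mutants' relative fitnesses
#' (growth rate divided by the WT rate): \eqn{WT \prod_i r_i / WT}. Two
#' mutants each at 0.7x WT therefore combine to 0.49x WT. With a single
#' rate the model reduces to the identity.
#'
#' @param single_rates growth rates of the individual mutants, in h^-1.
#' @param wt_rate wild-type growth rate in h^-1 (default 0.055).
#' @return The compound growth rate in h^-1.
#' @export
multiplicative_null <- function(single_rates, wt_rate = 0.055) {
  if (length(single_rates) == 0) stop("at least one rate is required")
  if (!all(is.finite(single_rates))) stop("rates must be finite")
  if (!is.numeric(wt_rate) || wt_rate <= 0) stop("wt_rate must be > 0")
  wt_rate * prod(single_rates / wt_rate)
}

#' Weighted sgRNA growth-rate model
#'
#' Predicts an sgRNA's growth rate as the proportion-weighted sum of the
#' growth rates of the edited cell fractions plus the unedited fraction
#' growing at the wild-type rate:
#' \deqn{r_{sgRNA} = \sum_i p_i r_i + p_{unedited} \cdot r_{WT}.}
#' Multi-amino-acid alleles should be pre-combined with
#' \code{\link{multiplicative_null}}.
#'
#' @param outcomes data frame with columns \code{proportion} and
#'   \code{allele_rate} (h^-1), one row per edited outcome.
#' @param unedited_proportion fraction of unedited cells.
#' @param wt_rate wild-type growth rate in h^-1.
#' @param tol tolerance on the proportions summing to 1.
#' @return Predicted sgRNA growth rate in h^-1.
#' @export
weighted_guide_rate <- function(outcomes, unedited_proportion,
                                wt_rate = 0.055, tol = 1e-6) {
  total <- sum(outcomes$proportion) + unedited_proportion
  if (abs(total - 1) > tol)
    stop(sprintf("proportions sum to %.8f, not 1", total))
  if (nrow(outcomes) > 0 && any(!is.finite(outcomes$allele_rate)))
    stop("all allele rates must be finite")
  sum(outcomes$proportion * outcomes$allele_rate) +
    unedited_proportion * wt_rate
}

#' Assign growth rates to editing outcomes from variant-level measurements
#'
#' Maps each outcome (a cis set of spacer positions) of a guide to the
#' amino-acid changes it creates and assigns a growth rate: missense
#' changes are looked up in the variant rate table; synonymous changes are
#' treated as WT-like; multi-amino-acid alleles are combined with the
#' multiplicative null; stop gains or missense changes without a variant
#' measurement yield \code{NA}.
#'
#' @param outcomes data frame with column \code{positions} (comma-separated
#'   spacer positions, \code{""} = unedited) and \code{proportion}.
#' @param guide one-row guide record.
#' @param cds reference coding sequence.
#' @param profile an \code{\link{editor_profile}}.
#' @param variant_rates data frame with columns \code{variant_id} and
#'   \code{rate} (h^-1), e.g. DMS measurements or simulation truth.
#' @param wt_rate wild-type growth rate in h^-1.
#' @return The outcomes table with added columns \code{allele_rate},
#'   \code{aa_changes} (comma-separated variant ids) and \code{n_aa}.
#' @export
outcome_allele_rates <- function(outcomes, guide, cds, profile,
                                 variant_rates, wt_rate = 0.055) {
  lookup <- setNames(variant_rates$rate, variant_rates$variant_id)
  res <- lapply(outcomes$positions, function(ps) {
    if (ps == "")
      return(list(rate = wt_rate, aa = "", n_aa = 0L))
    pos <- as.integer(strsplit(ps, ",", fixed = TRUE)[[1]])
    cds_pos <- vapply(pos, spacer_to_cds_pos, numeric(1),
                      strand = guide$strand, cdna_start = guide$cdna_start,
                      cds_length = nchar(cds))
    if (guide$strand == "+") {
      ref <- profile$source_base; alt <- profile$target_base
    } else {
      ref <- unname(COMPLEMENT[profile$source_base])
      alt <- unname(COMPLEMENT[profile$target_base])
    }
    edits <- data.frame(cds_pos = as.integer(cds_pos), ref_base = ref,
                        alt_base = alt, stringsAsFactors = FALSE)
    aa <- map_edit_to_protein(edits, cds)
    nonsyn <- aa[aa$consequence != "synonymous", , drop = FALSE]
    if (nrow(nonsyn) == 0)
      return(list(rate = wt_rate,
                  aa = paste(aa$variant_id, collapse = ","),
                  n_aa = 0L))
    if (any(nonsyn$consequence == "stop") ||
        !all(nonsyn$variant_id %in% names(lookup)))
      return(list(rate = NA_real_,
                  aa = paste(aa$variant_id, collapse = ","),
                  n_aa = nrow(nonsyn)))
    singles <- unname(lookup[nonsyn$variant_id])
    rate <- if (length(singles) == 1) singles
      else multiplicative_null(singles, wt_rate)
    list(rate = rate, aa = paste(aa$variant_id, collapse = ","),
         n_aa = nrow(nonsyn))
  })
  outcomes$allele_rate <- vapply(res, `[[`, numeric(1), "rate")
  outcomes$aa_changes <- vapply(res, `[[`, character(1), "aa")
  outcomes$n_aa <- vapply(res, `[[`, integer(1), "n_aa")
  outcomes
}

#' Compare weighted-model predictions to observed guide rates
#'
#' Applies the edit-frequency filter (outcomes below \code{edit_freq_min}
#' are dropped and the remaining proportions, including the unedited
#' fraction, renormalised), computes each guide's predicted rate with the
#' weighted model, joins the observed rates, and reports the Pearson
#' correlation.
#'
#' @param outcome_table long data frame of outcomes with columns
#'   \code{guide_id}, \code{positions}, \code{proportion},
#'   \code{allele_rate} (see \code{\link{outcome_allele_rates}}; rows with
#'   \code{NA} allele rates disqualify their guide).
#' @param observed data frame with columns \code{guide_id} and
#'   \code{rate} (observed sgRNA growth rates, h^-1).
#' @param edit_freq_min minimum outcome proportion (default 0.05); edited
#'   outcomes at or below this are dropped before renormalisation.
#' @param wt_rate wild-type growth rate in h^-1.
#' @return List with \code{table} (guide_id, predicted_rate,
#'   observed_rate), \code{r} (Pearson correlation, NA when undefined) and
#'   \code{n}.
#' @export
predict_vs_observe <- function(outcome_table, observed, edit_freq_min = 0.05,
                               wt_rate = 0.055) {
  preds <- lapply(split(outcome_table, outcome_table$guide_id), function(ot) {
    unedited <- ot$proportion[ot$positions == ""]
    unedited <- if (length(unedited)) sum(unedited) else 0
    edited <- ot[ot$positions != "", , drop = FALSE]
    edited <- edited[edited$proportion > edit_freq_min, , drop = FALSE]
    if (any(is.na(edited$allele_rate)))
      return(NULL)
    total <- sum(edited$proportion) + unedited
    if (total <= 0) return(NULL)
    rate <- weighted_guide_rate(
      data.frame(proportion = edited$proportion / total,
                 allele_rate = edited$allele_rate),
      unedited_proportion = unedited / total,
      wt_rate = wt_rate)
    data.frame(guide_id = ot$guide_id[1], predicted_rate = rate,
               stringsAsFactors = FALSE)
  })
  pred <- do.call(rbind, preds)
  if (is.null(pred)) stop("no guides with complete outcome rates")
  tab <- merge(pred, observed[, c("guide_id", "rate")], by = "guide_id")
  names(tab)[names(tab) == "rate"] <- "observed_rate"
  if (nrow(tab) == 0) stop("no overlapping guides")
  r <- if (nrow(tab) >= 3 &&
           sd(tab$predicted_rate) > 0 && sd(tab$observed_rate) > 0)
    cor(tab$predicted_rate, tab$observed_rate) else NA_real_
  list(table = tab, r = r, n = nrow(tab))
}
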