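## Concordance between guide-level and variant-level measurements:
## joining, quadrant classification, correlation/odds-ratio summaries, and
## the cumulative filter ladder.

#' Join guide measurements with the variants they are predicted to create
#'
#' One row per (guide, predicted amino-acid variant) pair: the guide's
#' measured growth rate and hit flag next to the variant's DMS rate and
#' hit flag. Synonymous predicted edits are retained with the wild-type
#' rate (never hits); predicted stop gains are excluded. Guides lacking a
#' DMS measurement for any predicted missense edit are dropped when
#' \code{require_complete_dms} is TRUE.
#'
#' @param guide_stats data frame with \code{guide_id}, \code{rate},
#'   \code{is_hit} (and optionally the filter flags from
#'   \code{\link{classify_guides}}).
#' @param dms data frame with \code{variant_id}, \code{rate},
#'   \code{is_hit}.
#' @param annotations result of \code{\link{annotate_guides}} (list with
#'   \code{edits} and \code{guides}).
#' @param wt_rate rate assigned to synonymous predicted edits.
#' @param require_complete_dms drop guides whose predicted missense edits
#'   are not all measured (default TRUE).
#' @return Data frame of comparison rows: \code{guide_id},
#'   \code{variant_id}, \code{in_core}, \code{guide_rate},
#'   \code{variant_rate}, \code{guide_hit}, \code{variant_hit},
#'   \code{quadrant}, plus per-guide filter flags.
#' @export
join_guide_variant <- function(guide_stats, dms, annotations,
                               wt_rate = 0.055,
                               require_complete_dms = TRUE) {
  edits <- annotations$edits
  ginfo <- annotations$guides
  edits <- edits[edits$consequence != "stop", , drop = FALSE]
  if (require_complete_dms) {
    ok <- ginfo$guide_id[ginfo$complete_dms %in% TRUE]
    edits <- edits[edits$guide_id %in% ok, , drop = FALSE]
  }
  rows <- merge(edits, guide_stats[, c("guide_id", "rate", "is_hit")],
                by = "guide_id")
  names(rows)[names(rows) == "rate"] <- "guide_rate"
  names(rows)[names(rows) == "is_hit"] <- "guide_hit"
  dm <- dms[, c("variant_id", "rate", "is_hit")]
  names(dm) <- c("variant_id", "variant_rate", "variant_hit")
  rows <- merge(rows, dm, by = "variant_id", all.x = TRUE)
  syn <- rows$consequence == "synonymous"
  rows$variant_rate[syn] <- wt_rate
  rows$variant_hit[syn] <- FALSE
  rows <- rows[!is.na(rows$variant_rate), , drop = FALSE]
  if (nrow(rows) == 0) stop("no overlap between guides and variants")
  flag_cols <- intersect(c("pass_efficiency", "pass_single_core",
                           "single_core_edit", "efficiency_score"),
                         names(ginfo))
  for (fc in flag_cols)
    rows[[fc]] <- ginfo[[fc]][match(rows$guide_id, ginfo$guide_id)]
  rows$quadrant <- quadrant_classify(rows$guide_hit, rows$variant_hit)
  rows[order(rows$guide_id, rows$variant_id), , drop = FALSE]
}

#' Quadrant classification of a comparison row
#'
#' Labels each (guide, variant) pair by agreement of the two hit calls:
#' both deleterious = TP; guide depletes but variant does not = FP; guide
#' fails to deplete but the variant is deleterious = FN; neither = TN.
#'
#' @param guide_hit,variant_hit logical vectors.
#' @return Character vector of quadrant labels.
#' @export
quadrant_classify <- function(guide_hit, variant_hit) {
  ifelse(guide_hit & variant_hit, "TP",
         ifelse(guide_hit & !variant_hit, "FP",
                ifelse(!guide_hit & variant_hit, "FN", "TN")))
}

#' Concordance summary: correlation, odds ratio, TPR, accuracy
#'
#' Pearson correlation between variant and guide growth rates, the odds
#' ratio TP*TN/(FP*FN) of the 2x2 hit table (with a Haldane-Anscombe 0.5
#' correction, flagged, when any cell is zero), a two-sided Fisher exact
#' p-value, the true-positive rate TP/(TP+FN) and the accuracy (TP+TN)/n.
#'
#' @param rows comparison rows from \code{\link{join_guide_variant}}.
#' @return An object of class \code{concordance_summary} (a list).
#' @export
concordance_metrics <- function(rows) {
  n <- nrow(rows)
  q <- c(TP = sum(rows$quadrant == "TP"), FP = sum(rows$quadrant == "FP"),
         FN = sum(rows$quadrant == "FN"), TN = sum(rows$quadrant == "TN"))
  r <- p_r <- NA_real_
  if (n >= 3 && sd(rows$variant_rate) > 0 && sd(rows$guide_rate) > 0) {
    ct <- cor.test(rows$variant_rate, rows$guide_rate, method = "pearson")
    r <- unname(ct$estimate)
    p_r <- ct$p.value
  }
  corrected <- any(q == 0) && n > 0
  qq <- if (corrected) q + 0.5 else q
  odds_ratio <- if (n == 0) NA_real_
    else unname((qq["TP"] * qq["TN"]) / (qq["FP"] * qq["FN"]))
  fisher_p <- if (n > 0)
    fisher.test(matrix(q, 2, 2, byrow = TRUE))$p.value else NA_real_
  tpr <- if ((q["TP"] + q["FN"]) > 0)
    unname(q["TP"] / (q["TP"] + q["FN"])) else NA_real_
  accuracy <- if (n > 0) unname((q["TP"] + q["TN"]) / n) else NA_real_
  structure(list(n = n, quadrants = q, r = r, r_p = p_r,
                 odds_ratio = odds_ratio, or_corrected = corrected,
                 fisher_p = fisher_p, tpr = tpr, accuracy = accuracy),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("n = %d rows | TP %d FP %d FN %d TN %d\n", x$n,
              x$quadrants["TP"], x$quadrants["FP"], x$quadrants["FN"],
              x$quadrants["TN"]))
  cat(sprintf("Pearson r = %.3f (p = %.3g) | OR = %.2f%s (Fisher p = %.3g)\n",
              x$r, x$r_p, x$odds_ratio,
              if (x$or_corrected) " [0.5-corrected]" else "", x$fisher_p))
  cat(sprintf("TPR = %.3f | accuracy = %.3f\n", x$tpr, x$accuracy))
  invisible(x)
}

#' Cumulative filter ladder over comparison rows
#'
#' Applies the filters cumulatively -- broad window (all rows), core
#' window, efficiency score, single core edit -- and summarises each rung.
#' An empty rung yields a summary with n = 0 and undefined metrics rather
#' than an error.
#'
#' @param rows comparison rows from \code{\link{join_guide_variant}} (with
#'   the filter flag columns).
#' @param rungs character vector naming the cumulative rungs, a subset of
#'   \code{c("broad", "core", "efficiency", "single_edit")}, in order.
#' @return List with \code{summaries} (one \code{concordance_summary} per
#'   rung, named) and \code{retained} (data frame: rung, n_rows,
#'   n_guides).
#' @export
filter_ladder <- function(rows, rungs = c("broad", "core", "efficiency",
                                          "single_edit")) {
  keep <- rep(TRUE, nrow(rows))
  summaries <- list()
  retained <- list()
  for (rung in rungs) {
    keep <- keep & switch(
      rung,
      broad = TRUE,
      core = rows$in_core,
      efficiency = rows$pass_efficiency %in% TRUE,
      single_edit = rows$pass_single_core %in% TRUE,
      stop("unknown rung: ", rung))
    sub <- rows[keep, , drop = FALSE]
    summaries[[rung]] <- if (nrow(sub) > 0) concordance_metrics(sub)
      else structure(list(n = 0L,
                          quadrants = c(TP = 0L, FP = 0L, FN = 0L, TN = 0L),
                          r = NA_real_, r_p = NA_real_,
                          odds_ratio = NA_real_, or_corrected = FALSE,
                          fisher_p = NA_real_, tpr = NA_real_,
                          accuracy = NA_real_),
                     class = "concordance_summary")
    retained[[rung]] <- data.frame(rung = rung, n_rows = nrow(sub),
                                   n_guides = length(unique(sub$guide_id)),
                                   stringsAsFactors = FALSE)
  }
  list(summaries = summaries, retained = do.call(rbind, retained))
}

#' Tabulate a filter ladder
#'
#' Flattens \code{\link{filter_ladder}} output into one row per rung.
#'
#' @param ladder result of \code{\link{filter_ladder}}.
#' @return Data frame with rung, n, quadrant counts, r, odds ratio, TPR
#'   and accuracy.
#' @export
ladder_table <- function(ladder) {
  do.call(rbind, lapply(names(ladder$summaries), function(nm) {
    s <- ladder$summaries[[nm]]
    data.frame(rung = nm, n = s$n,
               TP = unname(s$quadrants["TP"]), FP = unname(s$quadrants["FP"]),
               FN = unname(s$quadrants["FN"]), TN = unname(s$quadrants["TN"]),
               r = s$r, odds_ratio = s$odds_ratio, tpr = s$tpr,
               accuracy = s$accuracy, stringsAsFactors = FALSE)
  }))
}
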