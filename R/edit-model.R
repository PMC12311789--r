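## Editing-outcome prediction: protospacer discovery, window edit
## enumeration, protein consequence annotation, and guide classification
## for the concordance filter ladder.

IUPAC_MAP <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

pam_matches <- function(pam, pattern) {
  pp <- chars(pam)
  pt <- chars(pattern)
  all(vapply(seq_along(pt), function(i) pp[i] %in% IUPAC_MAP[[pt[i]]],
             logical(1)))
}

#' Editor profile: base identity, windows and positional efficiency
#'
#' Describes a base editor: the source/target base (A>G for adenine base
#' editors, C>T for cytosine base editors), the broad and core editing
#' windows in spacer coordinates (position 1 = PAM-distal 5' end), and a
#' per-position editing probability curve over spacer positions 1-20. The
#' default curve is bell-shaped, peaking at position 6 and zero outside the
#' broad window, reflecting the concentration of editing activity around
#' the centre of the window.
#'
#' @param editor "ABE" (A>G) or "CBE" (C>T).
#' @param broad broad editing window, inclusive bounds (default 2-12).
#' @param core core (most likely) editing window, inclusive (default 4-8).
#' @param p optional length-20 vector of per-position edit probabilities;
#'   if NULL a Gaussian-bell default is built from \code{peak},
#'   \code{center}, \code{width}.
#' @param peak,center,width parameters of the default positional curve.
#' @return An object of class \code{editor_profile}.
#' @export
editor_profile <- function(editor = c("ABE", "CBE"), broad = c(2L, 12L),
                           core = c(4L, 8L), p = NULL, peak = 0.8,
                           center = 6, width = 2) {
  editor <- match.arg(editor)
  if (any(broad < 1 | broad > 20) || any(core < 1 | core > 20))
    stop("windows must lie within spacer positions 1-20")
  if (core[1] < broad[1] || core[2] > broad[2])
    stop("core window must be contained in the broad window")
  if (is.null(p)) {
    pos <- 1:20
    p <- peak * exp(-(pos - center)^2 / (2 * width^2))
    p[pos < broad[1] | pos > broad[2]] <- 0
  }
  if (length(p) != 20 || any(p < 0 | p > 1))
    stop("p must be a length-20 probability vector")
  structure(list(
    editor = editor,
    source_base = if (editor == "ABE") "A" else "C",
    target_base = if (editor == "ABE") "G" else "T",
    broad = as.integer(broad),
    core = as.integer(core),
    p = p
  ), class = "editor_profile")
}

#' @export
print.editor_profile <- function(x, ...) {
  cat(sprintf("%s editor (%s>%s), broad window %d-%d, core window %d-%d\n",
              x$editor, x$source_base, x$target_base,
              x$broad[1], x$broad[2], x$core[1], x$core[2]))
  invisible(x)
}

#' Find all protospacers on both strands of a coding sequence
#'
#' Scans every 20-mer followed immediately by a PAM match (default NGN) on
#' the coding strand and on its reverse complement. \code{cdna_start} is
#' the 1-based position of spacer position 1 on the guide's own strand
#' (for '-' guides, an index into the reverse complement).
#'
#' @param cds coding sequence (length >= 23).
#' @param pam_pattern IUPAC PAM pattern (default "NGN").
#' @return Data frame with columns \code{guide_id}, \code{spacer},
#'   \code{pam}, \code{strand}, \code{cdna_start}, \code{role}.
#' @export
find_protospacers <- function(cds, pam_pattern = "NGN") {
  if (nchar(cds) < 23)
    return(data.frame(guide_id = character(0), spacer = character(0),
                      pam = character(0), strand = character(0),
                      cdna_start = integer(0), role = character(0),
                      stringsAsFactors = FALSE))
  scan_strand <- function(s, strand) {
    L <- nchar(s)
    starts <- seq_len(L - 22L)
    spacers <- substring(s, starts, starts + 19L)
    pams <- substring(s, starts + 20L, starts + 22L)
    keep <- vapply(pams, pam_matches, logical(1), pattern = pam_pattern)
    if (!any(keep))
      return(NULL)
    data.frame(
      guide_id = sprintf("g_%s_%04d", ifelse(strand == "+", "fwd", "rev"),
                         starts[keep]),
      spacer = spacers[keep],
      pam = pams[keep],
      strand = strand,
      cdna_start = starts[keep],
      role = "target",
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(scan_strand(cds, "+"), scan_strand(revcomp(cds), "-"))
  if (is.null(out))
    out <- data.frame(guide_id = character(0), spacer = character(0),
                      pam = character(0), strand = character(0),
                      cdna_start = integer(0), role = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Enumerate candidate base edits of a guide inside a window
#'
#' One predicted edit per source base in the window on the protospacer
#' strand, mapped to the coding strand: for '+' guides an A>G on the coding
#' strand (ABE), for '-' guides the complementary T>C. Candidate alleles
#' are all non-empty subsets of the edits (cis combinations), capped at 2^8.
#'
#' @param guide one-row guide record (fields \code{spacer}, \code{strand},
#'   \code{cdna_start}).
#' @param profile an \code{\link{editor_profile}}.
#' @param window inclusive spacer-position window, e.g. \code{c(4, 8)}.
#' @param cds_length length of the coding sequence (needed to map '-'
#'   strand coordinates).
#' @return List with \code{edits} (data frame: spacer_pos, cds_pos,
#'   ref_base, alt_base) and \code{alleles} (list of integer index vectors
#'   into \code{edits}, one per non-empty cis combination).
#' @export
enumerate_window_edits <- function(guide, profile, window, cds_length) {
  if (window[1] < 1 || window[2] > 20 || window[1] > window[2])
    stop("window must lie within [1, 20]")
  sp <- chars(guide$spacer)
  pos <- which(sp == profile$source_base)
  pos <- pos[pos >= window[1] & pos <= window[2]]
  k <- length(pos)
  if (k > 8)
    stop(sprintf("guide has %d editable positions in window (cap 8)", k))
  if (k == 0L)
    return(list(edits = data.frame(spacer_pos = integer(0),
                                   cds_pos = integer(0),
                                   ref_base = character(0),
                                   alt_base = character(0),
                                   stringsAsFactors = FALSE),
                alleles = list()))
  cds_pos <- vapply(pos, spacer_to_cds_pos, numeric(1),
                    strand = guide$strand, cdna_start = guide$cdna_start,
                    cds_length = cds_length)
  if (guide$strand == "+") {
    ref <- profile$source_base
    alt <- profile$target_base
  } else {
    ref <- unname(COMPLEMENT[profile$source_base])
    alt <- unname(COMPLEMENT[profile$target_base])
  }
  edits <- data.frame(spacer_pos = pos, cds_pos = as.integer(cds_pos),
                      ref_base = ref, alt_base = alt,
                      stringsAsFactors = FALSE)
  alleles <- lapply(seq_len(2^k - 1), function(s)
    which(bitwAnd(s, 2^(seq_len(k) - 1)) > 0))
  list(edits = edits, alleles = alleles)
}

#' Map a cis set of base edits to amino-acid changes
#'
#' Applies all edits simultaneously to the coding sequence and re-translates
#' the affected codons, reporting one change per affected codon with its
#' consequence (missense, synonymous, or stop).
#'
#' @param edits data frame with columns \code{cds_pos}, \code{ref_base},
#'   \code{alt_base} (all applied in cis).
#' @param cds coding sequence; its length defines the ORF.
#' @return Data frame with columns \code{aa_pos}, \code{ref_aa},
#'   \code{alt_aa}, \code{consequence}, \code{variant_id}.
#' @export
map_edit_to_protein <- function(edits, cds) {
  if (nrow(edits) == 0)
    return(data.frame(aa_pos = integer(0), ref_aa = character(0),
                      alt_aa = character(0), consequence = character(0),
                      variant_id = character(0), stringsAsFactors = FALSE))
  L <- nchar(cds)
  if (any(edits$cds_pos < 1 | edits$cds_pos > L))
    stop("edit position outside the ORF")
  s <- chars(cds)
  if (!all(s[edits$cds_pos] == edits$ref_base))
    stop("ref_base does not match the coding sequence")
  s_alt <- s
  s_alt[edits$cds_pos] <- edits$alt_base
  codon_idx <- sort(unique((edits$cds_pos - 1L) %/% 3L + 1L))
  out <- lapply(codon_idx, function(ci) {
    i0 <- (ci - 1L) * 3L + 1L
    ref_codon <- paste(s[i0:(i0 + 2L)], collapse = "")
    alt_codon <- paste(s_alt[i0:(i0 + 2L)], collapse = "")
    ref_aa <- GENETIC_CODE_TABLE[[ref_codon]]
    alt_aa <- GENETIC_CODE_TABLE[[alt_codon]]
    consequence <- if (alt_aa == "*") "stop"
      else if (alt_aa == ref_aa) "synonymous"
      else "missense"
    data.frame(aa_pos = ci, ref_aa = ref_aa, alt_aa = alt_aa,
               consequence = consequence,
               variant_id = variant_id(ref_aa, ci, alt_aa),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Annotate a guide library with predicted window edits
#'
#' For every guide, enumerates the candidate edits in the broad window,
#' flags which fall inside the core window, and maps each single edit to
#' its amino-acid consequence. Also produces per-guide summary flags used
#' by the concordance filter ladder.
#'
#' @param library guide library data frame (\code{guide_id}, \code{spacer},
#'   \code{strand}, \code{cdna_start}; negative controls, which have no
#'   genomic target, are skipped).
#' @param cds reference coding sequence.
#' @param profile an \code{\link{editor_profile}}.
#' @param efficiency optional data frame (\code{guide_id},
#'   \code{efficiency_score}) of externally supplied efficiency scores.
#' @param dms_variants optional character vector of variant ids with DMS
#'   measurements, used for the complete-DMS flag.
#' @return List with \code{edits} (one row per predicted broad-window edit:
#'   guide_id, spacer_pos, cds_pos, ref_base, alt_base, in_core, aa_pos,
#'   ref_aa, alt_aa, consequence, variant_id) and \code{guides} (per-guide:
#'   guide_id, n_broad, n_core, single_core_edit, efficiency_score,
#'   complete_dms).
#' @export
annotate_guides <- function(library, cds, profile, efficiency = NULL,
                            dms_variants = NULL) {
  targets <- if ("role" %in% names(library))
    library[library$role == "target", , drop = FALSE] else library
  edit_rows <- list()
  guide_rows <- list()
  for (i in seq_len(nrow(targets))) {
    g <- targets[i, ]
    enum <- enumerate_window_edits(g, profile, profile$broad, nchar(cds))
    e <- enum$edits
    if (nrow(e) > 0) {
      aa <- do.call(rbind, lapply(seq_len(nrow(e)), function(j)
        map_edit_to_protein(e[j, , drop = FALSE], cds)))
      e <- cbind(guide_id = g$guide_id, e,
                 in_core = e$spacer_pos >= profile$core[1] &
                   e$spacer_pos <= profile$core[2],
                 aa, stringsAsFactors = FALSE)
      edit_rows[[length(edit_rows) + 1L]] <- e
    }
    n_broad <- nrow(e)
    n_core <- if (n_broad > 0) sum(e$in_core) else 0L
    missense <- if (n_broad > 0) e$variant_id[e$consequence == "missense"]
      else character(0)
    complete_dms <- if (is.null(dms_variants)) NA
      else n_broad > 0 && all(missense %in% dms_variants)
    guide_rows[[i]] <- data.frame(
      guide_id = g$guide_id,
      n_broad = n_broad,
      n_core = as.integer(n_core),
      single_core_edit = n_core == 1L,
      complete_dms = complete_dms,
      stringsAsFactors = FALSE
    )
  }
  guides <- do.call(rbind, guide_rows)
  if (is.null(guides))
    guides <- data.frame(guide_id = character(0), n_broad = integer(0),
                         n_core = integer(0), single_core_edit = logical(0),
                         complete_dms = logical(0), stringsAsFactors = FALSE)
  if (!is.null(efficiency)) {
    guides$efficiency_score <-
      efficiency$efficiency_score[match(guides$guide_id, efficiency$guide_id)]
  } else {
    guides$efficiency_score <- NA_real_
  }
  edits <- if (length(edit_rows)) do.call(rbind, edit_rows)
    else data.frame(guide_id = character(0), spacer_pos = integer(0),
                    cds_pos = integer(0), ref_base = character(0),
                    alt_base = character(0), in_core = logical(0),
                    aa_pos = integer(0), ref_aa = character(0),
                    alt_aa = character(0), consequence = character(0),
                    variant_id = character(0), stringsAsFactors = FALSE)
  rownames(edits) <- NULL
  list(edits = edits, guides = guides)
}

#' Classify guides for the concordance filter ladder
#'
#' Adds the boolean filter flags used as cumulative rungs: presence of
#' broad- and core-window edits, efficiency score above the threshold, a
#' single core-window edit, and complete DMS coverage of predicted edits.
#'
#' @param guides per-guide annotation table from
#'   \code{\link{annotate_guides}}.
#' @param efficiency_min efficiency score threshold; guides must score
#'   strictly above it (default 50).
#' @return The input with added logical columns \code{has_broad},
#'   \code{has_core}, \code{pass_efficiency}, \code{pass_single_core}.
#' @export
classify_guides <- function(guides, efficiency_min = 50) {
  guides$has_broad <- guides$n_broad > 0
  guides$has_core <- guides$n_core > 0
  guides$pass_efficiency <- !is.na(guides$efficiency_score) &
    guides$efficiency_score > efficiency_min
  guides$pass_single_core <- guides$single_core_edit
  guides
}
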