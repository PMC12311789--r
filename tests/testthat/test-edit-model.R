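test_that("protospacer scan matches a brute-force scan of both strands", {
  ref <- fixture_reference(40, seed = 13)
  found <- find_protospacers(ref$dna)
  brute <- oracle_protospacers(ref$dna)
  key <- function(df) sort(paste(df$spacer, df$strand, df$cdna_start))
  expect_identical(key(found), key(brute))

  # no G anywhere: no guides
  expect_equal(nrow(find_protospacers(strrep("AT", 30))), 0)

  # 23-nt input with a single + strand site
  s23 <- paste0(strrep("A", 20), "AGA")
  hits <- find_protospacers(s23)
  expect_true(any(hits$strand == "+" & hits$cdna_start == 1))
})

test_that("reverse-complementing the input swaps the strand sets", {
  ref <- fixture_reference(30, seed = 14)
  rc <- oracle_revcomp(ref$dna)
  fwd <- find_protospacers(ref$dna)
  rev <- find_protospacers(rc)
  key <- function(df, strand) sort(df$spacer[df$strand == strand])
  expect_identical(key(fwd, "+"), key(rev, "-"))
  expect_identical(key(fwd, "-"), key(rev, "+"))
})

test_that("window edit enumeration equals brute-force subset enumeration", {
  prof <- editor_profile("ABE")
  guide <- data.frame(spacer = "CCCCACACCCCCCCCCCCCC", strand = "+",
                      cdna_start = 10, stringsAsFactors = FALSE)
  enum <- enumerate_window_edits(guide, prof, c(4, 8), 240)
  expect_equal(enum$edits$spacer_pos, c(5, 7))
  expect_equal(enum$edits$cds_pos, c(14, 16))
  expect_equal(length(enum$alleles), 3)  # {5}, {7}, {5,7}

  # no source base in the window
  none <- enumerate_window_edits(
    data.frame(spacer = strrep("C", 20), strand = "+", cdna_start = 1),
    prof, c(4, 8), 240)
  expect_equal(nrow(none$edits), 0)
  expect_equal(length(none$alleles), 0)

  # minus strand: spacer A maps to coding-strand T>C
  gm <- data.frame(spacer = "CCCCCACCCCCCCCCCCCCC", strand = "-",
                   cdna_start = 10, stringsAsFactors = FALSE)
  em <- enumerate_window_edits(gm, prof, c(4, 8), 240)
  expect_equal(em$edits$ref_base, "T")
  expect_equal(em$edits$alt_base, "C")
  # manual coordinate arithmetic: L - (start + pos - 1) + 1
  expect_equal(em$edits$cds_pos, 240 - (10 + 6 - 1) + 1)

  # cap on editable positions
  expect_error(enumerate_window_edits(
    data.frame(spacer = strrep("A", 20), strand = "+", cdna_start = 1),
    prof, c(2, 12), 240), "cap")
})

test_that("oracle equivalence holds for many random spacers", {
  prof <- editor_profile("ABE")
  set.seed(17)
  for (i in 1:200) {
    sp <- random_spacer()
    window <- sort(sample(1:20, 2))
    oc <- oracle_window_edits(sp, window)
    if (length(oc$positions) > 8) next
    enum <- enumerate_window_edits(
      data.frame(spacer = sp, strand = "+", cdna_start = 1), prof,
      window, 240)
    expect_equal(enum$edits$spacer_pos, oc$positions)
    expect_equal(length(enum$alleles), length(oc$subsets))
    got <- lapply(enum$alleles, function(a) sort(enum$edits$spacer_pos[a]))
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(oc$subsets, function(s)
                      paste(sort(s), collapse = ","), character(1)))
  }
})

test_that("edit-to-protein mapping follows the codon table", {
  cds <- "ATGAAATTTGGG"  # M K F G
  # AAA -> GAA (K2E) via A>G at codon base 1
  aa <- map_edit_to_protein(
    data.frame(cds_pos = 4, ref_base = "A", alt_base = "G"), cds)
  expect_equal(aa$variant_id, "K2E")
  expect_equal(aa$consequence, "missense")
  # AAA -> AAG: synonymous
  syn <- map_edit_to_protein(
    data.frame(cds_pos = 6, ref_base = "A", alt_base = "G"), cds)
  expect_equal(syn$consequence, "synonymous")
  # cis edits in two adjacent codons: two changes in one allele
  two <- map_edit_to_protein(
    data.frame(cds_pos = c(4, 8), ref_base = c("A", "T"),
               alt_base = c("G", "C")), cds)
  expect_equal(nrow(two), 2)
  expect_equal(two$aa_pos, c(2, 3))
  # stop gain (C>T editor style)
  stp <- map_edit_to_protein(
    data.frame(cds_pos = 4, ref_base = "A", alt_base = "T"), cds)
  expect_equal(stp$consequence, "stop")
  expect_error(map_edit_to_protein(
    data.frame(cds_pos = 99, ref_base = "A", alt_base = "G"), cds),
    "outside")
  expect_error(map_edit_to_protein(
    data.frame(cds_pos = 4, ref_base = "C", alt_base = "G"), cds),
    "match")
})

test_that("applying a predicted edit and re-translating reproduces the aa change", {
  ref <- fixture_reference(40, seed = 23)
  prof <- editor_profile("ABE")
  lib <- find_protospacers(ref$dna)
  set.seed(24)
  lib <- lib[sample(nrow(lib), min(30, nrow(lib))), ]
  for (i in seq_len(nrow(lib))) {
    g <- lib[i, ]
    enum <- tryCatch(
      enumerate_window_edits(g, prof, prof$broad, nchar(ref$dna)),
      error = function(e) NULL)
    if (is.null(enum) || nrow(enum$edits) == 0) next
    for (j in seq_len(nrow(enum$edits))) {
      e <- enum$edits[j, ]
      aa <- map_edit_to_protein(e, ref$dna)
      mutated <- apply_edits_to_cds(ref$dna, g, e$spacer_pos, prof)
      prot <- oracle_translate(mutated)
      expect_equal(substr(prot, aa$aa_pos, aa$aa_pos), aa$alt_aa)
    }
  }
})

test_that("strand consistency: predictions match after reverse complement", {
  ref <- fixture_reference(30, seed = 25)
  prof <- editor_profile("ABE")
  L <- nchar(ref$dna)
  pred_set <- function(cds) {
    lib <- find_protospacers(cds)
    out <- character(0)
    for (i in seq_len(nrow(lib))) {
      enum <- tryCatch(
        enumerate_window_edits(lib[i, ], prof, prof$broad, nchar(cds)),
        error = function(e) NULL)
      if (is.null(enum) || nrow(enum$edits) == 0) next
      out <- c(out, sprintf("%d:%s>%s", enum$edits$cds_pos,
                            enum$edits$ref_base, enum$edits$alt_base))
    }
    sort(out)
  }
  fwd <- pred_set(ref$dna)
  rev <- pred_set(oracle_revcomp(ref$dna))
  # map the reverse-complement predictions back to forward coordinates
  remap <- vapply(strsplit(rev, "[:>]"), function(p) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    sprintf("%d:%s>%s", L - as.integer(p[1]) + 1, comp[p[2]], comp[p[3]])
  }, character(1))
  expect_identical(fwd, sort(remap))
})

test_that("guide annotation flags core membership and edit counts", {
  ref <- fixture_reference(40, seed = 26)
  prof <- editor_profile("ABE")
  lib <- find_protospacers(ref$dna)
  lib$role <- "target"
  ann <- annotate_guides(head(lib, 40), ref$dna, prof)
  expect_true(all(ann$guides$n_core <= ann$guides$n_broad))
  # edits flagged in_core are exactly those in 4-8
  expect_true(all(ann$edits$in_core ==
                    (ann$edits$spacer_pos >= 4 & ann$edits$spacer_pos <= 8)))
  expect_true(all(ann$guides$single_core_edit == (ann$guides$n_core == 1)))
})

test_that("guide classification applies the efficiency threshold strictly", {
  guides <- data.frame(guide_id = c("a", "b", "c", "d"),
                       n_broad = c(2, 1, 0, 3), n_core = c(1, 1, 0, 2),
                       single_core_edit = c(TRUE, TRUE, FALSE, FALSE),
                       complete_dms = TRUE,
                       efficiency_score = c(45, 51, 80, NA))
  cls <- classify_guides(guides, efficiency_min = 50)
  expect_equal(cls$pass_efficiency, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(cls$has_broad, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(cls$pass_single_core, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("editor profile validates windows and probabilities", {
  expect_error(editor_profile("ABE", broad = c(0, 12)), "within")
  expect_error(editor_profile("ABE", core = c(1, 13)), "contained")
  expect_error(editor_profile("ABE", p = rep(2, 20)), "probability")
  cbe <- editor_profile("CBE")
  expect_equal(cbe$source_base, "C")
  expect_equal(cbe$target_base, "T")
  abe <- editor_profile("ABE")
  expect_true(all(abe$p[c(1, 13:20)] == 0))
  expect_equal(which.max(abe$p), 6)
})
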