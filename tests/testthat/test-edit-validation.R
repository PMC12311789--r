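# Hand-built paired reads for rule-level checks: full-length mates
# (no stagger), qualities given per base.
pair_fixture <- function(ref, edits1 = NULL, q1 = 37, q2 = 37) {
  L <- nchar(ref)
  s <- strsplit(ref, "")[[1]]
  if (!is.null(edits1)) s[edits1$pos] <- edits1$alt
  seq_fwd <- paste(s, collapse = "")
  qual1 <- strrep(intToUtf8(q1 + 33), L)
  qual2 <- strrep(intToUtf8(q2 + 33), L)
  list(r1 = data.frame(seq = seq_fwd, qual = qual1),
       r2 = data.frame(seq = oracle_revcomp(seq_fwd), qual = qual2))
}

test_that("quality-gated edit calling applies the both-mates rule", {
  ref <- paste(rep(c("A", "C", "G", "T"), 10), collapse = "")
  # clean A>G at position 5, high quality in both mates
  p <- pair_fixture(ref, data.frame(pos = 5, alt = "G"))
  res <- call_edits_paired(p$r1, p$r2, ref)
  expect_equal(res$alleles$allele, "5:A>G")
  expect_equal(res$alleles$count, 1)
  expect_equal(res$wt_count, 0)

  # same mismatch with Q19 in one mate: not an edit, pair counts as WT
  p19 <- pair_fixture(ref, data.frame(pos = 5, alt = "G"), q1 = 37, q2 = 19)
  res19 <- call_edits_paired(p19$r1, p19$r2, ref)
  expect_equal(nrow(res19$alleles), 0)
  expect_equal(res19$wt_count, 1)

  # exactly Q20 fails the strict > 20 gate
  p20 <- pair_fixture(ref, data.frame(pos = 5, alt = "G"), q1 = 20, q2 = 37)
  expect_equal(call_edits_paired(p20$r1, p20$r2, ref)$wt_count, 1)

  # two high-quality mismatches form one cis allele
  p2 <- pair_fixture(ref, data.frame(pos = c(5, 9), alt = c("G", "G")))
  res2 <- call_edits_paired(p2$r1, p2$r2, ref)
  expect_equal(res2$alleles$allele, "5:A>G,9:A>G")

  # disagreeing mates: ignored
  pd <- pair_fixture(ref, data.frame(pos = 5, alt = "G"))
  pd$r2 <- pair_fixture(ref, data.frame(pos = 5, alt = "T"))$r2
  expect_equal(call_edits_paired(pd$r1, pd$r2, ref)$wt_count, 1)

  # zero-mismatch pair tallies as WT
  pw <- pair_fixture(ref)
  expect_equal(call_edits_paired(pw$r1, pw$r2, ref)$wt_count, 1)
})

test_that("reads incompatible with the reference raise an error", {
  ref <- strrep("ACGT", 10)
  long <- data.frame(seq = strrep("A", 60), qual = strrep("I", 60))
  expect_error(call_edits_paired(long, long, ref), "longer")
})

test_that("edit calling on simulated reads recovers truth without false positives", {
  ref <- fixture_reference(40, seed = 71)
  # two alleles: A>G edits written at high quality
  g <- list(dna = ref$dna)
  s <- strsplit(ref$dna, "")[[1]]
  a_pos <- which(s == "A")[c(3, 4)]
  mut1 <- s; mut1[a_pos[1]] <- "G"
  mut2 <- s; mut2[a_pos] <- "G"
  alleles <- c(ref$dna, paste(mut1, collapse = ""),
               paste(mut2, collapse = ""))
  sim <- simulate_paired_reads(alleles, c(0.5, 0.3, 0.2), n_pairs = 4000,
                               error_rate = 0.004, seed = 72)
  res <- call_edits_paired(sim$r1, sim$r2, ref$dna)
  lab1 <- sprintf("%d:A>G", a_pos[1])
  lab2 <- paste(sprintf("%d:A>G", a_pos), collapse = ",")
  # no false edits: every called single edit is a true simulated edit
  # (low-quality error bases never pass the gate; an error can at most
  # mask one member of a cis pair, yielding a partial allele)
  called_edits <- unique(unlist(strsplit(res$alleles$allele, ",")))
  expect_true(all(called_edits %in% sprintf("%d:A>G", a_pos)))
  # counts match the sampling truth up to the rare error-masking losses
  truth_counts <- table(factor(sim$truth$allele_index, levels = 1:3))
  expect_lt(abs(res$wt_count - truth_counts[1]), 0.01 * 4000)
  expect_lt(abs(res$alleles$count[res$alleles$allele == lab1] -
                  truth_counts[2]), 0.01 * 4000)
  expect_lt(abs(res$alleles$count[res$alleles$allele == lab2] -
                  truth_counts[3]), 0.01 * 4000)
  # pairs with no injected error at an edit position are called exactly
  err_at_edit <- tapply(sim$errors$pos %in% a_pos, sim$errors$id, any)
  clean <- !(sim$truth$id %in% names(err_at_edit)[err_at_edit %in% TRUE])
  expected_allele <- c("", lab1, lab2)[sim$truth$allele_index]
  expect_identical(res$per_pair[clean], expected_allele[clean])
})

test_that("background threshold averages replicate percentiles", {
  # constant control frequencies: threshold equals the constant
  expect_equal(background_threshold(list(rep(2e-4, 50)))$threshold, 2e-4)
  # replicate percentiles 1e-4, 2e-4, 3e-4 average to 2e-4
  reps <- list(rep(1e-4, 20), rep(2e-4, 20), rep(3e-4, 20))
  expect_equal(background_threshold(reps)$threshold, 2e-4)
  expect_error(background_threshold(list()), "control")
})

test_that("edit growth rates are anchored to the WT fraction", {
  wt_counts <- data.frame(timepoint_h = c(0, 144), replicate = 1,
                          count = c(5000, 5000), total = c(10000, 10000))
  # allele tracking WT exactly: 0.055
  ac <- data.frame(allele = "10:A>G", timepoint_h = c(0, 144),
                   replicate = 1, count = c(400, 400))
  r <- edit_growth_rates(ac, wt_counts)
  expect_equal(r$rate, 0.055)
  # allele/WT ratio halving over 144 h
  ac2 <- data.frame(allele = "10:A>G", timepoint_h = c(0, 144),
                    replicate = 1, count = c(400, 200))
  expect_equal(edit_growth_rates(ac2, wt_counts)$rate,
               0.055 - log(2) / 144)
  # frequency threshold drops rare alleles
  ac3 <- rbind(ac2, data.frame(allele = "20:A>G", timepoint_h = c(0, 144),
                               replicate = 1, count = c(3, 1)))
  res <- edit_growth_rates(ac3, wt_counts, freq_min = 0.01)
  expect_equal(res$allele, "10:A>G")
  # zero count at t1 floors with the pseudocount and flags
  ac4 <- data.frame(allele = "10:A>G", timepoint_h = c(0, 144),
                    replicate = 1, count = c(400, 0))
  res4 <- edit_growth_rates(ac4, wt_counts)
  expect_true(res4$floored)
  expect_equal(res4$rate, 0.055 + log((0.5 / 5000) / (400 / 5000)) / 144)
  expect_error(edit_growth_rates(
    ac, data.frame(timepoint_h = c(0, 144), replicate = 1,
                   count = c(0, 10), total = c(10, 10))), "positive")
})

test_that("allele-guide linkage requires full window containment and finds majors", {
  gw <- data.frame(guide_id = c("g1", "g2"),
                   win_start = c(10, 40), win_end = c(20, 50))
  alleles <- data.frame(
    allele = c("12:A>G", "15:A>G,18:A>G", "45:A>G", "12:A>G,45:A>G",
               "30:A>G"),
    freq = c(0.06, 0.04, 0.02, 0.01, 0.01),
    rate = 0.03, stringsAsFactors = FALSE)
  res <- link_and_major_edit(alleles, gw)
  linked <- res$linked
  expect_equal(sort(linked$allele[linked$guide_id == "g1"]),
               c("12:A>G", "15:A>G,18:A>G"))
  expect_equal(linked$allele[linked$guide_id == "g2"], "45:A>G")
  # allele spanning both windows cannot be linked to either (positions in
  # different windows): excluded as unlinked, not ambiguous
  expect_true("12:A>G,45:A>G" %in% res$unlinked$allele)
  expect_true("30:A>G" %in% res$unlinked$allele)
  # major edit: 0.06 of 0.10 > 50%
  expect_true(linked$is_major[linked$allele == "12:A>G"])
  expect_false(linked$is_major[linked$allele == "15:A>G,18:A>G"])
  # single allele is major with share 1
  expect_equal(linked$share[linked$allele == "45:A>G"], 1)
  expect_true(linked$is_major[linked$allele == "45:A>G"])

  # exact 50/50 split: no major edit
  tie <- data.frame(allele = c("11:A>G", "13:A>G"), freq = c(0.05, 0.05),
                    stringsAsFactors = FALSE)
  rt <- link_and_major_edit(tie, gw[1, ])
  expect_false(any(rt$linked$is_major))

  # overlapping windows create ambiguity
  gw2 <- data.frame(guide_id = c("a", "b"),
                    win_start = c(10, 12), win_end = c(20, 22))
  ra <- link_and_major_edit(data.frame(allele = "15:A>G", freq = 0.1,
                                       stringsAsFactors = FALSE), gw2)
  expect_equal(nrow(ra$linked), 0)
  expect_equal(ra$ambiguous$allele, "15:A>G")
})

test_that("per-sample allele, WT and discard fractions account for every pair", {
  ref <- fixture_reference(40, seed = 73)
  sim <- simulate_paired_reads(ref$dna, 1, n_pairs = 300,
                               error_rate = 0.01, seed = 74)
  res <- call_edits_paired(sim$r1, sim$r2, ref$dna)
  expect_equal(res$wt_count + sum(res$alleles$count), res$n_pairs)
})
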