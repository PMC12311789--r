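make_lib <- function(n = 5) {
  set.seed(99)
  data.frame(guide_id = paste0("g", seq_len(n)),
             spacer = replicate(n, random_spacer()),
             stringsAsFactors = FALSE)
}

test_that("guide counting matches exact spacers after trimming", {
  lib <- make_lib()
  reads <- c(paste0("ACCG", lib$spacer[1], "GTTTT"),
             paste0("ACCG", lib$spacer[3], "GTTTT"),
             paste0("ACCG", lib$spacer[3], "GTTTT"))
  res <- count_guides(reads, lib)
  expect_equal(res$counts$count, c(1, 0, 2, 0, 0))
  expect_equal(res$n_unmatched, 0)

  # one substitution, rescue off: unmatched
  mut <- lib$spacer[2]
  substr(mut, 5, 5) <- if (substr(mut, 5, 5) == "A") "C" else "A"
  res2 <- count_guides(paste0("ACCG", mut, "GTTTT"), lib)
  expect_equal(sum(res2$counts$count), 0)
  expect_equal(res2$n_unmatched, 1)
  # with rescue on it is assigned
  res3 <- count_guides(paste0("ACCG", mut, "GTTTT"), lib, rescue_1mm = TRUE)
  expect_equal(res3$counts$count[2], 1)

  dup <- rbind(lib, lib[1, ])
  expect_error(count_guides(reads, dup), "duplicate")
})

test_that("simulated read counting stays within multinomial bounds", {
  lib <- make_lib(4)
  props <- c(0.4, 0.3, 0.2, 0.1)
  counts_true <- data.frame(guide_id = lib$guide_id,
                            count = as.vector(rmultinom(1, 1e4, props)))
  reads <- simulate_guide_reads(counts_true, lib, seed = 7)
  res <- count_guides(reads, lib)
  # 99% binomial envelope around the sampled truth (exact recount expected)
  expect_equal(res$counts$count, counts_true$count)
  z <- abs(res$counts$count - 1e4 * props) / sqrt(1e4 * props * (1 - props))
  expect_true(all(z < qnorm(0.995) + 1))
})

test_that("median-of-ratios normalisation removes global scaling", {
  set.seed(12)
  base <- rpois(50, 500) + 100
  counts <- do.call(rbind, lapply(1:2, function(r)
    rbind(data.frame(guide_id = paste0("g", 1:50), timepoint_h = 0,
                     replicate = r, count = base),
          data.frame(guide_id = paste0("g", 1:50), timepoint_h = 144,
                     replicate = r, count = base * 3))))
  res <- estimate_log2fc(counts)
  expect_equal(res$log2_fc, rep(0, 50), tolerance = 1e-12)

  # multiplying one sample's counts by a constant changes nothing
  counts2 <- counts
  sel <- counts2$timepoint_h == 144 & counts2$replicate == 2
  counts2$count[sel] <- counts2$count[sel] * 10
  res2 <- estimate_log2fc(counts2)
  expect_equal(res2$log2_fc, res$log2_fc, tolerance = 1e-12)
})

test_that("a single halving guide gets the hand-computed fold change", {
  n <- 40
  base <- rep(1000, n)
  t1 <- base; t1[7] <- 500
  counts <- do.call(rbind, lapply(1:3, function(r)
    rbind(data.frame(guide_id = paste0("g", 1:n), timepoint_h = 0,
                     replicate = r, count = base),
          data.frame(guide_id = paste0("g", 1:n), timepoint_h = 144,
                     replicate = r, count = t1))))
  res <- estimate_log2fc(counts)
  # hand computation: size factors are medians of count ratios; with one
  # guide out of 40 changed the median ratio is unchanged, so normalised
  # counts equal raw counts and lfc = log2(500.5/1000.5)
  expect_equal(res$log2_fc[7], log2(500.5 / 1000.5), tolerance = 1e-10)
  expect_lt(abs(res$log2_fc[7] - (-1)), 2e-3)
  expect_equal(res$log2_fc[-7], rep(0, n - 1), tolerance = 1e-12)
  expect_lt(res$adj_p[7], 0.05)
  # permuting guide order leaves results unchanged
  perm <- counts[sample(nrow(counts)), ]
  res_p <- estimate_log2fc(perm)
  expect_equal(res_p$log2_fc[match(res$guide_id, res_p$guide_id)],
               res$log2_fc)
})

test_that("fold change to growth rate conversion is the documented affine map", {
  expect_equal(guide_growth_rate(0.3, 144, control_lfc = c(0.3, 0.3)), 0.055)
  expect_equal(guide_growth_rate(-1, 144), 0.055 - log(2) / 144)
  # affine in log2_fc with slope ln2 / delta_t
  lfc <- seq(-3, 2, by = 0.5)
  r <- guide_growth_rate(lfc, 100)
  expect_equal(diff(r) / diff(lfc), rep(log(2) / 100, length(lfc) - 1))
  expect_error(guide_growth_rate(0, 0), "delta_t")
})

test_that("guide hit calling uses the negative-control distribution and Table-2 rule", {
  set.seed(8)
  ctrl_ids <- paste0("c", 1:30)
  stats <- data.frame(
    guide_id = c(ctrl_ids, "gA", "gB", "gC"),
    rate = c(rnorm(30, 0.055, 0.002), 0.055, NA, 0.02),
    log2_fc = c(rnorm(30, 0, 0.1), 0.01, -0.5, -2),
    adj_p = c(runif(30, 0.2, 1), 0.9, 0.01, 0.001))
  mu <- mean(stats$rate[1:30]); sdev <- sd(stats$rate[1:30])
  stats$rate[32] <- mu - 2.5 * sdev
  res <- call_guide_hits(stats, ctrl_ids)
  expect_false(res$is_hit[res$guide_id == "gA"])
  expect_true(res$is_hit[res$guide_id == "gB"])
  expect_true(res$is_hit[res$guide_id == "gC"])
  expect_equal(res$is_depleting[res$guide_id %in% c("gA", "gB", "gC")],
               c(FALSE, TRUE, TRUE))
  expect_error(call_guide_hits(stats, ctrl_ids[1:5]), "20")
  same <- stats; same$rate[1:30] <- 0.055
  expect_error(call_guide_hits(same, ctrl_ids), "zero")
})

test_that("z-hit fraction tracks the truth on a simulated guide set", {
  # 12% of guides strongly deleterious, controls define the null
  set.seed(77)
  n <- 250
  true_del <- runif(n) < 0.12
  rates <- data.frame(id = paste0("g", 1:n),
                      rate = ifelse(true_del, 0.03, 0.055))
  ctrl <- data.frame(id = paste0("c", 1:40), rate = 0.055)
  sim <- simulate_screen_counts(rbind(rates, ctrl), depth = 2e6,
                                timepoints = c(0, 216), replicates = 3,
                                seed = 78)
  lfc <- estimate_log2fc(sim$counts)
  lfc$rate <- guide_growth_rate(
    lfc$log2_fc, 216,
    control_lfc = lfc$log2_fc[lfc$guide_id %in% ctrl$id])
  res <- call_guide_hits(lfc, ctrl$id)
  frac <- mean(res$is_hit[res$guide_id %in% rates$id])
  expect_lt(abs(frac - mean(true_del)), 0.05)
})

test_that("high-confidence guide filtering applies the frequency cutoff", {
  counts <- data.frame(
    guide_id = rep(c("a", "b", "c"), 2),
    timepoint_h = 0, replicate = rep(1:2, each = 3),
    count = c(9900, 99, 1, 9900, 99, 1))
  hc <- filter_high_confidence_guides(counts, min_frequency = 1e-4)
  expect_equal(hc$frequency[hc$guide_id == "b"], 0.0099)
  # the 1:10,000 bound is inclusive: 1/10000 just qualifies
  expect_equal(hc$high_confidence, c(TRUE, TRUE, TRUE))
  # validation-pool mode: 1% cutoff
  hc2 <- filter_high_confidence_guides(counts, min_frequency = 0.01)
  expect_equal(hc2$high_confidence, c(TRUE, FALSE, FALSE))
})

test_that("sliding window profile equals a brute-force count", {
  z <- rep(0, 60)
  pos <- seq_len(60) * 3
  res <- sliding_window_profile(z, pos)
  expect_equal(nrow(res), 60 - 39)
  expect_true(all(res$proportion == 0))

  z2 <- rep(0, 50)
  z2[5:14] <- -5
  res2 <- sliding_window_profile(z2, seq_len(50))
  # brute force on the first window: ten guides below -4 out of 40
  expect_equal(res2$proportion[1], sum(z2[1:40] < -4) / 40)
  expect_equal(res2$proportion[1], 0.25)
  brute <- vapply(seq_len(11), function(s) mean(z2[s:(s + 39)] < -4),
                  numeric(1))
  expect_equal(res2$proportion, brute)
  expect_error(sliding_window_profile(rep(0, 10), 1:10), "window")
})

test_that("cross-replicate rate estimates are reproducible on generator defaults", {
  ref <- fixture_reference()
  ls1 <- fixture_landscape(ref)
  prof <- editor_profile("ABE")
  lib <- generate_guide_library(ref, prof, n_guides = 60, n_controls = 30,
                                seed = 50)
  gs <- simulate_guide_screen(lib, ls1, ref, prof, depth = 5e5, seed = 51)
  rate_of_rep <- function(r) {
    cc <- gs$counts[gs$counts$replicate == r, ]
    cc$replicate <- 1
    lfc <- estimate_log2fc(cc)
    ctrl <- lib$guide_id[lib$role == "negative_control"]
    guide_growth_rate(lfc$log2_fc, gs$delta_t,
                      control_lfc = lfc$log2_fc[lfc$guide_id %in% ctrl])
  }
  r1 <- rate_of_rep(1); r2 <- rate_of_rep(2)
  expect_gt(cor(r1, r2), 0.8)
})
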