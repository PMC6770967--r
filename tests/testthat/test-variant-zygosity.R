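# allele-depth zygosity classification, filter and summaries

test_that("zygosity thresholds are inclusive at the stated boundaries", {
  thr <- zygosity_thresholds()
  v <- make_variants(ad_ref = c(0, 4, 5), ad_alt = c(100, 96, 95))
  expect_equal(classify_zygosity(v, thr),
               c("homozygous", "homozygous", "deviating_frequency"),
               ignore_attr = TRUE)
})

test_that("classification matches the brute-force rule for all DP <= 30", {
  thr <- zygosity_thresholds()
  for (dp in 1:30) {
    for (a_alt in 0:dp) {
      ad <- c(dp - a_alt, a_alt)
      if (sum(ad) == 0) next
      v <- variant_table("chr1", 1L, "A", "T", dp, list(ad))
      expect_identical(as.character(classify_zygosity(v, thr)),
                       oracle_zygosity(ad, dp))
    }
  }
  # multi-allelic: all compositions of DP <= 12 into three allele depths
  for (dp in 1:12) {
    for (a1 in 0:dp) for (a2 in 0:(dp - a1)) {
      ad <- c(dp - a1 - a2, a1, a2)
      if (sum(ad) == 0) next
      v <- variant_table("chr1", 1L, "A", "T,G", dp, list(ad))
      expect_identical(as.character(classify_zygosity(v, thr)),
                       oracle_zygosity(ad, dp))
    }
  }
})

test_that("dominance ties classify as deviating and are counted", {
  v <- variant_table("chr1", 1L, "A", "T", 100L, list(c(50L, 50L)))
  cls <- classify_zygosity(v)
  expect_equal(as.character(cls), "deviating_frequency")
  expect_equal(attr(cls, "ties"), 1L)
  # a tie below the thresholds stays homozygous
  v <- variant_table("chr1", 1L, "A", "T", 100L, list(c(2L, 2L)))
  expect_equal(as.character(classify_zygosity(v)), "homozygous")
})

test_that("classification rejects missing or all-zero allele depths", {
  v <- make_variants(10, 10)
  v$ad <- NULL
  expect_error(classify_zygosity(v), "missing")
  v0 <- variant_table("chr1", 1L, "A", "T", 0L, list(c(0L, 0L)))
  expect_error(classify_zygosity(v0), "DP")
  v2 <- make_variants(1, 1)
  v2$ad[[1]] <- c(0L, 0L)
  expect_error(classify_zygosity(v2), "all-zero")
})

test_that("coverage-deviation filter is strict at 20% and excludes the base", {
  # flat flank at 100 with a spike at the variant base: the base itself
  # must not contaminate the flank mean
  d <- rep(100L, 5000); d[2500] <- 1000L
  tr <- make_track(chr1 = d)
  mk <- function(dp) variant_table("chr1", 2500L, "A", "T", dp,
                                   list(c(0L, dp)))
  expect_equal(coverage_deviation_filter(mk(100L), tr)$status, "pass")
  expect_equal(coverage_deviation_filter(mk(120L), tr)$status, "pass")
  out <- coverage_deviation_filter(mk(121L), tr)
  expect_equal(out$status, "coverage_deviation")
  expect_equal(out$reason, "depth_deviation")

  # zero-depth flank: excluded with explicit reason
  tr0 <- make_track(chr1 = rep(0L, 5000))
  out0 <- coverage_deviation_filter(mk(50L), tr0)
  expect_equal(out0$reason, "flank_zero")
})

test_that("filter agrees with brute-force recomputation on random cases", {
  set.seed(40)
  thr <- zygosity_thresholds()
  d <- rpois(20000, 80)
  tr <- make_track(chr1 = d)
  pos <- sample(seq_len(20000), 500)
  dp <- pmax(1L, rpois(500, 80) + sample(c(-40L, 0L, 40L), 500,
                                         replace = TRUE))
  v <- variant_table("chr1", pos, "A", "T", dp,
                     lapply(dp, function(x) c(0L, x)))
  got <- coverage_deviation_filter(v, tr, thr)
  for (i in seq_len(500)) {
    lo <- max(1, pos[i] - 2000); hi <- min(20000, pos[i] + 2000)
    flank <- d[lo:hi][-(pos[i] - lo + 1)]
    m <- mean(flank)
    want <- if (abs(dp[i] - m) / m > 0.20) "coverage_deviation" else "pass"
    expect_identical(got$status[i], want)
  }
  # chromosome-end flanks are clipped, not padded
  v_end <- variant_table("chr1", 1L, "A", "T", 80L, list(c(0L, 80L)))
  m_end <- mean(d[2:2001])
  expect_identical(coverage_deviation_filter(v_end, tr, thr)$status,
                   if (abs(80 - m_end) / m_end > 0.2) "coverage_deviation"
                   else "pass")
})

test_that("variant density blocks conserve counts", {
  empty <- make_variants(integer(0), integer(0))
  dens0 <- variant_density(empty, character(0),
                           chrom_lengths = c(chr1 = 3e5))
  expect_equal(sum(dens0$total), 0L)
  expect_equal(nrow(dens0), 3L)

  v <- make_variants(rep(0, 7), rep(50, 7), pos = 150000 + 1:7)
  dens <- variant_density(v, rep("homozygous", 7),
                          chrom_lengths = c(chr1 = 3e5))
  expect_equal(dens$homozygous, c(0L, 7L, 0L))

  set.seed(41)
  n <- 400
  v <- make_variants(rep(10, n), rep(40, n),
                     pos = sort(sample.int(3e5, n)))
  cls <- sample(c("homozygous", "deviating_frequency"), n, replace = TRUE)
  dens <- variant_density(v, cls, chrom_lengths = c(chr1 = 3e5))
  expect_equal(sum(dens$total), n)
  expect_equal(sum(dens$homozygous), sum(cls == "homozygous"))
})

test_that("substitution spectrum counts, collapses and rejects non-SNVs", {
  v <- make_variants(10, 40, ref = "C", alt = "T")
  sp <- substitution_spectrum(v)
  expect_equal(sum(sp$directed), 1)
  expect_equal(unname(sp$directed["C>T"]), 1)
  expect_equal(sp$cg_to_at_share, 1)

  expect_error(substitution_spectrum(make_variants(5, 5, ref = "CA",
                                                   alt = "C")), "SNV")

  # planted 90% C>T spectrum recovered
  set.seed(42)
  n <- 1000
  is_ct <- runif(n) < 0.9
  ref <- ifelse(is_ct, "C", "G")
  alt <- ifelse(is_ct, "T", "C")
  v <- variant_table("chr1", 1:n, ref, alt, rep(50L, n),
                     replicate(n, c(25L, 25L), simplify = FALSE))
  sp <- substitution_spectrum(v)
  expect_lt(abs(sp$collapsed[["C>T"]] / sp$n - 0.9), 0.03)

  # reverse-complementing every variant leaves the collapsed classes fixed
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v_rc <- variant_table("chr1", 1:n, unname(comp[ref]), unname(comp[alt]),
                        rep(50L, n),
                        replicate(n, c(25L, 25L), simplify = FALSE))
  expect_equal(substitution_spectrum(v_rc)$collapsed, sp$collapsed)
})

test_that("snv_indel_ratio handles the degenerate and balanced cases", {
  v <- variant_table("chr1", 1:20, c(rep("A", 10), rep("AT", 10)),
                     c(rep("T", 10), rep("A", 10)), rep(60L, 20),
                     replicate(20, c(30L, 30L), simplify = FALSE))
  r <- snv_indel_ratio(v)
  expect_equal(c(r$n_snv, r$n_indel, r$ratio), c(10, 10, 1))

  snv_only <- make_variants(rep(5, 3), rep(5, 3))
  expect_identical(snv_indel_ratio(snv_only)$ratio, Inf)
})

test_that("coverage histograms separate zygosity classes by depth", {
  v <- make_variants(rep(0, 5), rep(25, 5), pos = 1:5)
  tr <- make_track(chr1 = rep(25L, 10))
  h <- coverage_histogram_at_variants(v, tr, rep("homozygous", 5))
  expect_equal(sum(h$counts[, "homozygous"]), 5)
  expect_equal(sum(h$counts[, "deviating_frequency"]), 0)

  # hemizygous homozygous variants at depth ~50, deviating at ~150:
  # modal homozygous depth is about a third (here: half-unit analogue)
  set.seed(43)
  d <- c(rpois(500, 50), rpois(500, 100))
  tr <- make_track(chr1 = as.integer(d))
  v <- make_variants(rep(10, 1000), rep(40, 1000), pos = 1:1000)
  cls <- rep(c("homozygous", "deviating_frequency"), each = 500)
  h <- coverage_histogram_at_variants(v, tr, cls)
  expect_equal(sum(h$counts), 1000)
  expect_lt(abs(h$mode[["homozygous"]] /
                  h$mode[["deviating_frequency"]] - 0.5), 0.15)
  expect_lt(h$mean[["homozygous"]], h$mean[["deviating_frequency"]])
})
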