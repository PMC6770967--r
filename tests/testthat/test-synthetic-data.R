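# synthetic aneuploid genome generator

test_that("generate_reference handles the empty-annotation case", {
  spec <- genome_spec(c(chr1 = 5000), n_genes = 0, seed = 1)
  ref <- generate_reference(spec)
  expect_equal(length(ref$sequences), 1L)
  expect_equal(nrow(ref$genes), 0L)
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_reference(ref, fa, gff)
  lines <- readLines(gff)
  expect_true(all(startsWith(lines, "#")))
  expect_equal(length(Biostrings::readDNAStringSet(fa)), 1L)
})

test_that("generate_reference is byte-deterministic under a fixed seed", {
  run_once <- function() {
    spec <- genome_spec(c(chrA = 1e5, chrB = 1e5), n_genes = 20, seed = 1)
    ref <- generate_reference(spec)
    fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
    write_reference(ref, fa, gff)
    c(tools::md5sum(fa), tools::md5sum(gff))
  }
  expect_equal(unname(run_once()), unname(run_once()))
})

test_that("every emitted CDS is a multiple of 3 with start and stop codons", {
  spec <- genome_spec(c(chr1 = 2e5, chr2 = 1e5), n_genes = 40,
                      organelles = TRUE, seed = 3)
  ref <- generate_reference(spec)
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_reference(ref, fa, gff)
  # independent re-parse: rtracklayer for GFF3, Biostrings for sequences
  ann <- read_annotation(gff)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(nrow(ann$cds), 40L)
  for (i in seq_len(nrow(ann$cds))) {
    row <- ann$cds[i, ]
    len <- row$end - row$start + 1L
    expect_identical(len %% 3L, 0L)
    cds <- Biostrings::subseq(seqs[[row$chrom]], row$start, row$end)
    if (row$strand == "-") cds <- Biostrings::reverseComplement(cds)
    cds <- as.character(cds)
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, len - 2, len) %in% c("TAA", "TAG", "TGA"))
    # no internal stop codon
    inner <- substring(cds, seq(4, len - 3, by = 3), seq(6, len, by = 3) - 0)
    expect_false(any(head(inner, -1) %in% c("TAA", "TAG", "TGA")))
  }
  # genes do not overlap within a chromosome
  for (chrom in unique(ann$genes$chrom)) {
    g <- ann$genes[ann$genes$chrom == chrom, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > head(g$end, -1)))
  }
})

test_that("generate_reference errors when genes cannot be packed", {
  spec <- genome_spec(c(chr1 = 3000), n_genes = 10,
                      gene_length_range = c(900, 900))
  expect_error(generate_reference(spec), "cannot fit")
})

test_that("plant_copy_map: identity, round trip and validation", {
  cm <- one_segment_map(10000, 2)
  expect_equal(nrow(cm), 1L)
  expect_equal(cm$k, 2)

  segs <- data.frame(chrom = "chr1",
                     start = c(1, 2001, 5001, 8001, 9501),
                     end = c(2000, 5000, 8000, 9500, 10000),
                     k = c(1, 2, 3, 5, 0))
  cm <- plant_copy_map(c(chr1 = 10000), segments = segs)
  bed <- tempfile(fileext = ".bed")
  write_copy_bed(cm, bed)
  back <- read_copy_bed(bed)
  expect_equal(back$start, segs$start)
  expect_equal(back$end, segs$end)
  expect_equal(back$k, segs$k)

  bad <- data.frame(chrom = "chr1", start = 1, end = 10001, k = 1)
  expect_error(plant_copy_map(c(chr1 = 10000), segments = bad))
  gap <- data.frame(chrom = "chr1", start = c(1, 6000), end = c(4999, 10000),
                    k = c(1, 2))
  expect_error(plant_copy_map(c(chr1 = 10000), segments = gap), "gaps")
})

test_that("random copy maps partition chromosomes and match the length law", {
  lens <- setNames(rep(2e5, 100), paste0("c", 1:100))
  cm <- plant_copy_map(lens, seg_mean_len = 2e4, seed = 5)
  for (chrom in names(lens)) {
    s <- cm[cm$chrom == chrom, ]
    expect_equal(s$start[1], 1)
    expect_equal(s$end[nrow(s)], 2e5)
    if (nrow(s) > 1) expect_equal(s$start[-1], head(s$end, -1) + 1)
  }
  # interior (untruncated) segment lengths follow the requested mean
  interior <- cm[cm$end < 2e5, ]
  expect_lt(abs(mean(interior$end - interior$start + 1) / 2e4 - 1), 0.1)
})

test_that("plant_variants: zero rates, carrier rule and SNV:InDel balance", {
  spec <- genome_spec(c(chr1 = 10000), n_genes = 2, seed = 2)
  ref <- generate_reference(spec)
  cm <- one_segment_map(10000, 3)
  expect_equal(nrow(plant_variants(ref, cm, snv_rate = 0, indel_rate = 0,
                                   seed = 1)), 0L)

  tv <- plant_variants(ref, cm, snv_rate = 0.02, indel_rate = 0.02, seed = 1)
  expect_true(all(tv$true_fraction == 1 / 3))   # default single-carrier rule
  expect_true(all(tv$carriers == 1L))

  # equal rates: SNV count within exact binomial 95% bounds of half
  n <- nrow(tv)
  n_snv <- sum(tv$class == "SNV")
  expect_gte(n_snv, qbinom(0.025, n, 0.5))
  expect_lte(n_snv, qbinom(0.975, n, 0.5))

  # no variants in k = 0 segments
  segs <- data.frame(chrom = "chr1", start = c(1, 5001), end = c(5000, 10000),
                     k = c(0, 2))
  cm0 <- plant_copy_map(c(chr1 = 10000), segments = segs)
  tv0 <- plant_variants(ref, cm0, snv_rate = 0.02, indel_rate = 0.02,
                        seed = 1)
  expect_true(all(tv0$pos > 5000))
  expect_true(all(tv0$k == 2))
})

test_that("simulate_coverage respects copy number and noise law", {
  segs <- data.frame(chrom = "chr1", start = c(1, 1e4 + 1), end = c(1e4, 2e4),
                     k = c(0, 2))
  cm <- plant_copy_map(c(chr1 = 2e4), segments = segs)
  tr <- simulate_coverage(cm, noise_model(c = 50), seed = 1)
  expect_true(all(tr$chr1[1:1e4] == 0L))
  expect_gt(mean(tr$chr1[(1e4 + 1):2e4]), 0)

  # 1 Mbp at k = 1 and k = 3: means concentrate at k * c
  segs <- data.frame(chrom = "chr1", start = c(1, 1e6 + 1),
                     end = c(1e6, 2e6), k = c(1, 3))
  cm <- plant_copy_map(c(chr1 = 2e6), segments = segs)
  tr <- simulate_coverage(cm, noise_model(c = 50), seed = 2)
  m1 <- mean(tr$chr1[1:1e6]); m3 <- mean(tr$chr1[(1e6 + 1):2e6])
  expect_true(m1 >= 49 && m1 <= 51)
  expect_true(m3 / m1 >= 2.9 && m3 / m1 <= 3.1)
})

test_that("emit_vcf produces binomial allele depths that sum to DP", {
  spec <- genome_spec(c(chr1 = 20000), n_genes = 3, seed = 4)
  ref <- generate_reference(spec)
  cm <- one_segment_map(20000, 2)
  tr <- simulate_coverage(cm, noise_model(c = 50), seed = 1)
  tv <- plant_variants(ref, cm, snv_rate = 0.01, indel_rate = 0.01, seed = 2)
  v <- emit_vcf(tv, tr, seed = 3)

  expect_equal(nrow(v), nrow(tv))                       # conservation
  expect_true(all(vapply(v$ad, sum, 0) == v$dp))        # AD sums to DP
  # pooled alt fraction within 3 binomial SE of 1/2 (carriers=1, k=2)
  alt <- vapply(v$ad, `[`, 0L, 2L)
  phat <- sum(alt) / sum(v$dp)
  se <- sqrt(0.5 * 0.5 / sum(v$dp))
  expect_lt(abs(phat - 0.5), 3 * se)

  # carriers = k (fixed variant): alt fraction exactly 1
  tv_all <- plant_variants(ref, cm, snv_rate = 0.01, indel_rate = 0,
                           carrier_rule = "all", seed = 5)
  v_all <- emit_vcf(tv_all, tr, seed = 6)
  expect_true(all(vapply(v_all$ad, `[`, 0L, 1L) == 0L))

  # VCF round trip conserves sites and depths
  path <- tempfile(fileext = ".vcf")
  write_vcf(v, path, c(chr1 = 20000), seed = 3)
  back <- read_vcf(path)
  expect_equal(nrow(back), nrow(tv))
  expect_equal(back$pos, v$pos)
  expect_equal(back$dp, v$dp)
  expect_equal(back$ad, v$ad)

  # truth variant outside the track errors
  orphan <- tv[1, ]; orphan$chrom <- "chrX"
  expect_error(emit_vcf(orphan, tr), "absent")
})

test_that("allele-fraction law holds per (carriers, k) class", {
  spec <- genome_spec(c(chr1 = 6e4), n_genes = 5, seed = 7)
  ref <- generate_reference(spec)
  segs <- data.frame(chrom = "chr1", start = c(1, 2e4 + 1, 4e4 + 1),
                     end = c(2e4, 4e4, 6e4), k = c(1, 3, 5))
  cm <- plant_copy_map(c(chr1 = 6e4), segments = segs)
  tr <- simulate_coverage(cm, noise_model(c = 50), seed = 8)
  tv <- plant_variants(ref, cm, snv_rate = 0.01, indel_rate = 0.01, seed = 9)
  v <- emit_vcf(tv, tr, seed = 10)
  alt <- vapply(v$ad, `[`, 0L, 2L)
  for (k in c(1, 3, 5)) {
    sel <- tv$k == k
    p <- 1 / k
    phat <- sum(alt[sel]) / sum(v$dp[sel])
    se <- sqrt(p * (1 - p) / sum(v$dp[sel]))
    expect_lt(abs(phat - p), max(3 * se, 1e-12))
  }
})

test_that("simulate_rna_counts is copy-proportional", {
  truth <- structure(data.frame(
    chrom = "chr1", pos = 1:200, ref = "A", alt = "T", class = "SNV",
    k = 3L, carriers = 1L, true_fraction = 1 / 3,
    gene_id = rep(c("g1", NA), 100), stringsAsFactors = FALSE),
    class = c("truth_variants", "data.frame"))
  rna <- simulate_rna_counts(truth, rna_depth = 300, seed = 1)
  expect_equal(nrow(rna), 100L)   # intergenic variants are not expressed
  # pooled alternative share within 3 binomial SE of 1/3
  tot <- sum(rna$ref_count + rna$alt_count)
  se <- sqrt((1 / 3) * (2 / 3) / tot)
  expect_lt(abs(sum(rna$alt_count) / tot - 1 / 3), 3 * se)

  # carriers = k: reference expectation 0
  truth$carriers <- 3L; truth$true_fraction <- 1
  rna_all <- simulate_rna_counts(truth, rna_depth = 300, seed = 2)
  expect_true(all(rna_all$ref_count == 0L))

  expect_true(all(simulate_rna_counts(truth, rna_depth = 0,
                                      seed = 3)[c("ref_count",
                                                  "alt_count")] == 0))
})

test_that("simulation stages are deterministic under a fixed seed", {
  spec <- genome_spec(c(chr1 = 3e4), n_genes = 5, seed = 11)
  ref <- generate_reference(spec)
  cm <- one_segment_map(3e4, 3)
  run <- function() {
    tr <- simulate_coverage(cm, noise_model(c = 50), seed = 12)
    tv <- plant_variants(ref, cm, seed = 13)
    v <- emit_vcf(tv, tr, seed = 14)
    list(tr = tr, tv = tv, v = v)
  }
  expect_identical(run(), run())
})
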