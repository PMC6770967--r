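# simplified effect annotation and InDel frame analysis

test_that("SNV effects: stop gain, missense, synonymous on both strands", {
  cds <- paste0("ATG", "TGG", "CTT", "AAA", "TAA")
  for (strand in c("+", "-")) {
    fix <- gene_fixture(cds, strand = strand)
    # genomic coordinate of the third base of codon 2 (TGG -> TGA)
    rel <- 6L
    pos <- if (strand == "+") fix$start + rel - 1L else fix$end - rel + 1L
    base_old <- substr(cds, rel, rel)
    genomic_ref <- if (strand == "+") base_old else
      c(A = "T", C = "G", G = "C", T = "A")[[base_old]]
    genomic_alt <- if (strand == "+") "A" else "T"   # G>A on the CDS strand
    v <- variant_table("chr1", pos, genomic_ref, genomic_alt, 50L,
                       list(c(25L, 25L)))
    eff <- annotate_effect(v, fix$cds, fix$sequences)
    expect_equal(eff$effect, "stop_gain")
    expect_equal(eff$impact, "high")
    expect_equal(eff$gene_id, "g1")
  }
})

test_that("InDel length mod 3 decides frameshift vs inframe", {
  fix <- gene_fixture(paste0("ATG", strrep("CTT", 8), "TAA"))
  s <- as.character(fix$sequences[[1]])
  p <- fix$start + 3L
  del4 <- variant_table("chr1", p, substr(s, p, p + 4L), substr(s, p, p),
                        50L, list(c(25L, 25L)))
  del3 <- variant_table("chr1", p, substr(s, p, p + 3L), substr(s, p, p),
                        50L, list(c(25L, 25L)))
  ins2 <- variant_table("chr1", p, substr(s, p, p), paste0(substr(s, p, p),
                                                           "AT"),
                        50L, list(c(25L, 25L)))
  expect_equal(annotate_effect(del4, fix$cds, fix$sequences)$effect,
               "frameshift")
  expect_equal(annotate_effect(del3, fix$cds, fix$sequences)$effect,
               "inframe_indel")
  expect_equal(annotate_effect(ins2, fix$cds, fix$sequences)$effect,
               "frameshift")
  # outside any CDS
  nc <- variant_table("chr1", 2L, substr(s, 2, 2),
                      setdiff(c("A", "C", "G", "T"), substr(s, 2, 2))[1],
                      50L, list(c(25L, 25L)))
  eff <- annotate_effect(nc, fix$cds, fix$sequences)
  expect_equal(eff$effect, "noncoding")
  expect_equal(eff$impact, "none")
})

test_that("annotator agrees with the full-mutant-translation oracle", {
  set.seed(50)
  n_codons <- 30L
  for (strand in c("+", "-")) {
    body <- paste(sample(setdiff(
      as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0), c("A", "C", "G", "T"), paste0)),
      c("TAA", "TAG", "TGA")), n_codons - 2L, replace = TRUE),
      collapse = "")
    fix <- gene_fixture(paste0("ATG", body, "TAA"), strand = strand)
    s <- as.character(fix$sequences[[1]])
    for (pos in fix$start:fix$end) {
      ref <- substr(s, pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        v <- variant_table("chr1", pos, ref, alt, 50L, list(c(25L, 25L)))
        got <- annotate_effect(v, fix$cds, fix$sequences)$effect
        expect_identical(got, oracle_snv_effect(fix, pos, alt),
                         label = sprintf("%s strand pos %d %s>%s", strand,
                                         pos, ref, alt))
      }
    }
  }
})

test_that("reference allele mismatches are rejected", {
  fix <- gene_fixture("ATGCTTTAA")
  s <- as.character(fix$sequences[[1]])
  wrong <- setdiff(c("A", "C", "G", "T"),
                   c(substr(s, 5, 5)))[1:2]
  v <- variant_table("chr1", 5L, wrong[1], wrong[2], 50L, list(c(25L, 25L)))
  expect_error(annotate_effect(v, fix$cds, fix$sequences), "mismatch")
})

test_that("multi-allelic records report the most severe allele", {
  fix <- gene_fixture(paste0("ATG", strrep("CTT", 8), "TAA"))
  s <- as.character(fix$sequences[[1]])
  p <- fix$start + 3L
  ref <- substr(s, p, p)
  # one frameshift insertion + whatever the SNV gives: high wins
  v <- variant_table("chr1", p, ref,
                     paste0(setdiff(c("A", "C", "G", "T"), ref)[1], ",",
                            ref, "GG"),
                     60L, list(c(20L, 20L, 20L)))
  eff <- annotate_effect(v, fix$cds, fix$sequences)
  expect_equal(eff$effect, "frameshift")
  expect_equal(eff$impact, "high")
})

test_that("genes_with_high_impact uses distinct-gene semantics", {
  eff <- data.frame(gene_id = c("g1", "g1", "g1", "g2", NA),
                    impact = c("high", "high", "high", "low", "none"))
  expect_equal(genes_with_high_impact(eff)$count, 1L)
  expect_equal(genes_with_high_impact(eff)$genes, "g1")
  none <- data.frame(gene_id = "g1", impact = "low")
  expect_equal(genes_with_high_impact(none)$count, 0L)

  # planted stop-gains in known genes are recovered exactly
  spec <- genome_spec(c(chr1 = 1e5), n_genes = 15, seed = 51)
  ref <- generate_reference(spec)
  cm <- one_segment_map(1e5, 2)
  tv <- plant_variants(ref, cm, snv_rate = 2e-3, indel_rate = 2e-3,
                       seed = 52)
  tr <- simulate_coverage(cm, noise_model(c = 50), seed = 53)
  v <- emit_vcf(tv, tr, seed = 54)
  eff <- annotate_effect(v, ref, ref$sequences)
  truth_hi <- sort(unique(eff$gene_id[eff$impact == "high" &
                                        !is.na(eff$gene_id)]))
  expect_equal(genes_with_high_impact(eff)$genes, truth_hi)
})

test_that("indel_frame_analysis splits compartments and counts frames", {
  fix <- gene_fixture(strrep("ATGCTTAAATAA", 1))   # 12 bp CDS
  s <- as.character(fix$sequences[[1]])
  mk_del <- function(pos, L) {
    variant_table("chr1", pos, substr(s, pos, pos + L), substr(s, pos, pos),
                  50L, list(c(25L, 25L)))
  }
  inside <- mk_del(fix$start + 2L, 3L)   # 3 bp, inside
  outside <- mk_del(5L, 2L)              # 2 bp, outside
  v <- rbind(inside, outside)
  class(v) <- c("variant_table", "data.frame")
  ft <- indel_frame_analysis(v, fix$cds, nchar(s))
  expect_equal(ft$n_inside + ft$n_outside, ft$n_total)
  expect_equal(ft$frac_div3_inside, 1)
  expect_equal(ft$frac_div3_outside, 0)
  expect_equal(ft$cds_length, 12)

  # insertion compartment rule: anchor base decides
  ins_in <- variant_table("chr1", fix$start, substr(s, fix$start, fix$start),
                          paste0(substr(s, fix$start, fix$start), "AAAA"),
                          50L, list(c(25L, 25L)))
  ft_in <- indel_frame_analysis(ins_in, fix$cds, nchar(s))
  expect_equal(ft_in$n_inside, 1L)
  # deletion anchored just before the CDS overlaps it via deleted bases
  del_cross <- mk_del(fix$start - 1L, 2L)
  ft_cross <- indel_frame_analysis(del_cross, fix$cds, nchar(s))
  expect_equal(ft_cross$n_inside, 1L)

  expect_error(indel_frame_analysis(v, fix$cds, 10), "exceed")
})

test_that("per-Mbp densities are invariant under genome doubling", {
  fix <- gene_fixture(strrep("ATGCTTAAATAA", 4))
  s <- as.character(fix$sequences[[1]])
  p <- fix$start + 2L
  v <- variant_table("chr1", p, substr(s, p, p + 3L), substr(s, p, p),
                     50L, list(c(25L, 25L)))
  ft1 <- indel_frame_analysis(v, fix$cds, nchar(s))
  # doubled genome: same chromosome concatenated with itself
  cds2 <- rbind(fix$cds,
                within(fix$cds, {start <- start + nchar(s)
                                 end <- end + nchar(s)
                                 gene_id <- "g2"}))
  v2 <- rbind(v, variant_table("chr1", p + nchar(s),
                               substr(s, p, p + 3L), substr(s, p, p),
                               50L, list(c(25L, 25L))))
  class(v2) <- c("variant_table", "data.frame")
  ft2 <- indel_frame_analysis(v2, cds2, 2 * nchar(s))
  expect_equal(ft2$density_inside, ft1$density_inside)
  expect_equal(ft2$density_outside, ft1$density_outside)
  expect_equal(ft2$density_ratio, ft1$density_ratio)
})

test_that("frame enrichment test flags a strong 3n excess", {
  res <- frame_enrichment_test(350, 500, 165, 500)
  expect_equal(res$method, "normal_approximation")
  expect_lt(res$p_value, 1e-6)
  # small counts take the exact route
  res2 <- frame_enrichment_test(3, 4, 1, 5)
  expect_equal(res2$method, "fisher_exact")
  expect_true(res2$p_value > 0 && res2$p_value <= 1)
})
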