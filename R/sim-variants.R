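#' Plant truth variants on a copy map
#'
#' Scatters SNVs and small InDels over all k >= 1 segments at the given
#' per-base rates and assigns each variant to a subset of the local
#' haplophase copies.  The default carrier rule plants every variant on
#' exactly one copy — the single-lineage model of an asexually dividing
#' culture, where a mutation arises once in one allele and is inherited by
#' all descendants — so the true alternative-allele fraction of a variant
#' in a k-copy segment is 1/k.  No variant is planted in k = 0 (deleted)
#' segments.
#'
#' @param ref an `sc_reference`.
#' @param copy_map a `copy_map` over the nuclear chromosomes.
#' @param snv_rate,indel_rate per-base rates (defaults emulate ~1 variant
#'   per kbp split evenly between SNVs and InDels).
#' @param indel_geom_mean mean InDel length (geometric law, capped).
#' @param indel_max maximum InDel length in bp.
#' @param carrier_rule "single" (1 copy), "all" (k copies, i.e. fixed /
#'   homozygous), or a function(k) returning an integer in 1..k.
#' @param seed integer seed.
#' @return data.frame of class `truth_variants`: chrom, pos (1-based),
#'   ref, alt, class ("SNV"/"insertion"/"deletion"), k, carriers,
#'   true_fraction, gene_id (NA outside genes).
#' @export
plant_variants <- function(ref, copy_map,
                           snv_rate = 5e-4, indel_rate = 5e-4,
                           indel_geom_mean = 3, indel_max = 30L,
                           carrier_rule = "single",
                           seed = NULL) {
  check_that(inherits(ref, "sc_reference"), "ref must be an sc_reference")
  check_that(snv_rate >= 0 && indel_rate >= 0, "rates must be >= 0")
  pick_carriers <- if (is.function(carrier_rule)) {
    carrier_rule
  } else if (identical(carrier_rule, "single")) {
    function(k) 1L
  } else if (identical(carrier_rule, "all")) {
    function(k) as.integer(k)
  } else stop("carrier_rule must be 'single', 'all' or a function(k)")

  lens <- reference_lengths(ref)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    rows <- list()
    seg_use <- copy_map[copy_map$k >= 1, , drop = FALSE]
    for (i in seq_len(nrow(seg_use))) {
      chrom <- seg_use$chrom[i]
      k <- seg_use$k[i]
      s0 <- seg_use$start[i]; e0 <- seg_use$end[i]
      len <- e0 - s0 + 1L
      n_snv <- rbinom(1L, len, min(1, snv_rate))
      n_ind <- rbinom(1L, len, min(1, indel_rate))
      n <- n_snv + n_ind
      if (n == 0) next
      pos <- s0 - 1L + sample.int(len, min(n, len))
      is_snv <- rep(c(TRUE, FALSE), c(n_snv, n_ind))[seq_along(pos)]
      chrom_seq <- as.character(ref$sequences[[chrom]])
      for (j in seq_along(pos)) {
        p <- pos[j]
        refb <- substr(chrom_seq, p, p)
        carriers <- as.integer(pick_carriers(k))
        check_that(carriers >= 1 && carriers <= k,
                   "carrier rule returned %d for k=%d", carriers, k)
        if (is_snv[j]) {
          altb <- sample(setdiff(bases, refb), 1L)
          cls <- "SNV"
        } else {
          L <- min(indel_max, 1L + rgeom(1L, 1 / indel_geom_mean))
          if (runif(1) < 0.5 && p + L <= lens[[chrom]]) {
            # deletion, anchored representation
            refb <- substr(chrom_seq, p, p + L)
            altb <- substr(chrom_seq, p, p)
            cls <- "deletion"
          } else {
            altb <- paste0(refb, paste(sample(bases, L, replace = TRUE),
                                       collapse = ""))
            cls <- "insertion"
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, pos = p, ref = refb, alt = altb, class = cls,
          k = k, carriers = carriers, true_fraction = carriers / k,
          stringsAsFactors = FALSE)
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else data.frame(
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), class = character(0), k = integer(0),
      carriers = integer(0), true_fraction = numeric(0),
      stringsAsFactors = FALSE)
    # de-duplicate positions (keep the first planted) and sort
    out <- out[!duplicated(out[c("chrom", "pos")]), , drop = FALSE]
    out <- out[order(match(out$chrom, names(lens)), out$pos), , drop = FALSE]
    out$gene_id <- assign_gene(ref$genes, out$chrom, out$pos)
    rownames(out) <- NULL
    class(out) <- c("truth_variants", "data.frame")
    out
  })
}

# gene id containing each position, NA if intergenic
assign_gene <- function(genes, chrom, pos) {
  if (!nrow(genes) || !length(pos)) return(rep(NA_character_, length(pos)))
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start, genes$end))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hit <- GenomicRanges::findOverlaps(q, g, select = "first")
  ifelse(is.na(hit), NA_character_, genes$gene_id[hit])
}

#' Emit observed variant calls (VCF-style DP/AD) from truth variants
#'
#' Reads the total depth DP at each truth position from the coverage track
#' and samples the alternative-allele depth binomially at the true fraction
#' carriers/k, so AD always sums to DP.  Every truth variant must lie in a
#' covered (k >= 1) position of the track.
#'
#' @param truth a `truth_variants` table.
#' @param track a `coverage_track` covering all truth positions.
#' @param seed integer seed.
#' @return a `variant_table` (see [variant_table()]) with one row per
#'   truth variant, same order.
#' @export
emit_vcf <- function(truth, track, seed = NULL) {
  check_that(all(truth$k >= 1), "truth variants must lie in k >= 1 segments")
  check_that(all(truth$chrom %in% names(track)),
             "truth variant on a chromosome absent from the coverage track")
  with_seed(seed, {
    n <- nrow(truth)
    dp <- integer(n)
    for (ch in unique(truth$chrom)) {
      sel <- truth$chrom == ch
      check_that(all(truth$pos[sel] <= length(track[[ch]])),
                 "truth variant beyond coverage track on %s", ch)
      dp[sel] <- track[[ch]][truth$pos[sel]]
    }
    alt_d <- rbinom(n, dp, truth$true_fraction)
    variant_table(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
                  alt = truth$alt, dp = dp,
                  ad = lapply(seq_len(n), function(i) c(dp[i] - alt_d[i],
                                                        alt_d[i])))
  })
}

#' Construct a variant table
#'
#' The canonical in-memory small-variant container: one row per site,
#' `alt` holds one or more comma-separated alternative alleles and `ad`
#' is a list column of integer allele depths ordered (ref, alt1, alt2, ...).
#'
#' @param chrom,pos,ref,alt,dp,ad parallel vectors / list.
#' @return data.frame of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref, alt, dp, ad) {
  n <- length(pos)
  check_that(all(lengths(ad) >= 2), "ad must hold ref and >= 1 alt depth")
  n_alt <- lengths(strsplit(alt, ",", fixed = TRUE))
  check_that(all(lengths(ad) == n_alt + 1L),
             "ad length must equal 1 + number of alt alleles")
  check_that(all(vapply(ad, sum, 0) <= dp), "sum(AD) must be <= DP")
  out <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                    alt = alt, dp = as.integer(dp), stringsAsFactors = FALSE)
  out$ad <- lapply(ad, as.integer)
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Write a variant table as VCF 4.2 with DP and AD
#'
#' @param variants a `variant_table`.
#' @param path output path.
#' @param chrom_lengths named lengths for the contig header lines.
#' @param seed seed recorded in the header for provenance (optional).
#' @param info optional character vector of per-record INFO strings.
#' @export
write_vcf <- function(variants, path, chrom_lengths = NULL, seed = NULL,
                      info = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=somaclone-%s",
                   as.character(packageVersion("somaclone"))))
  if (!is.null(seed)) hdr <- c(hdr, sprintf("##somacloneSeed=%d",
                                            as.integer(seed)))
  if (!is.null(chrom_lengths)) {
    chrom_lengths <- reference_lengths(chrom_lengths)
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), chrom_lengths))
  }
  hdr <- c(hdr,
    "##INFO=<ID=ZYG,Number=1,Type=String,Description=\"Zygosity class\">",
    "##INFO=<ID=FILTREASON,Number=1,Type=String,Description=\"Filter detail\">",
    paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
           "Description=\"Total read depth\">"),
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths (ref,alt...)\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tCULTURE")
  inf <- if (is.null(info)) rep(".", nrow(variants)) else info
  recs <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tDP:AD\t%d:%s",
                  variants$chrom, variants$pos, variants$ref, variants$alt,
                  inf, variants$dp,
                  vapply(variants$ad, paste, "", collapse = ","))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a VCF with DP and AD into a variant table
#'
#' Uses VariantAnnotation when available (any standards-compliant VCF);
#' falls back to a minimal reader for the subset this package writes.
#'
#' @param path VCF file.
#' @return a `variant_table`.
#' @export
read_vcf <- function(path) {
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    alt <- vapply(as.list(VariantAnnotation::alt(vcf)),
                  function(a) paste(as.character(a), collapse = ","), "")
    dp <- as.integer(VariantAnnotation::geno(vcf)$DP[, 1])
    ad_raw <- VariantAnnotation::geno(vcf)$AD
    ad <- lapply(seq_len(nrow(vcf)), function(i) {
      v <- ad_raw[i, 1]
      as.integer(if (is.list(v)) v[[1]] else v)
    })
    return(variant_table(
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      ref = as.character(VariantAnnotation::ref(vcf)),
      alt = alt, dp = dp, ad = ad))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  geno <- data.table::tstrsplit(f[[10]], ":", fixed = TRUE)
  fmt1 <- strsplit(f[[9]][1], ":", fixed = TRUE)[[1]]
  variant_table(chrom = f[[1]], pos = as.integer(f[[2]]), ref = f[[4]],
                alt = f[[5]],
                dp = as.integer(geno[[match("DP", fmt1)]]),
                ad = lapply(strsplit(geno[[match("AD", fmt1)]], ",",
                                     fixed = TRUE), as.integer))
}

#' Simulate copy-proportional RNA allele counts
#'
#' For each truth variant inside a gene, draws a Poisson total RNA read
#' count with the given per-site expression depth and splits it binomially
#' at the variant's true copy share carriers/k — transcript abundance
#' proportional to allele copy number, with no decay term.
#'
#' @param truth a `truth_variants` table (needs `gene_id`).
#' @param rna_depth expected total RNA reads per variant site; 0 gives
#'   all-zero counts.
#' @param seed integer seed.
#' @return data.frame: chrom, pos, ref, alt, gene_id, ref_count, alt_count.
#' @export
simulate_rna_counts <- function(truth, rna_depth = 300, seed = NULL) {
  check_that(rna_depth >= 0, "rna_depth must be >= 0")
  keep <- !is.na(truth$gene_id)
  tv <- truth[keep, , drop = FALSE]
  with_seed(seed, {
    n <- nrow(tv)
    total <- if (rna_depth > 0) rpois(n, rna_depth) else integer(n)
    alt_c <- rbinom(n, total, tv$true_fraction)
    data.frame(chrom = tv$chrom, pos = tv$pos, ref = tv$ref, alt = tv$alt,
               gene_id = tv$gene_id, ref_count = total - alt_c,
               alt_count = alt_c, stringsAsFactors = FALSE)
  })
}

#' @rdname plant_variants
#' @param truth a `truth_variants` table.
#' @param path output TSV path.
#' @export
write_truth_tsv <- function(truth, path) {
  data.table::fwrite(as.data.frame(truth), path, sep = "\t")
  invisible(path)
}

#' @rdname plant_variants
#' @export
read_truth_tsv <- function(path) {
  out <- as.data.frame(data.table::fread(path, sep = "\t"))
  class(out) <- c("truth_variants", "data.frame")
  out
}
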