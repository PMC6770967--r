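#' Collect allele-specific expression records at high-impact variants
#'
#' Joins RNA allele counts to high-impact variant positions by
#' chromosome + position and checks the alleles agree; sites whose alleles
#' mismatch between DNA and RNA tables are skipped (counted in the
#' `skipped` attribute), as are sites below the minimum total RNA depth.
#'
#' @param variants a `variant_table` of pass variants.
#' @param effects matching output of [annotate_effect()].
#' @param rna data.frame with chrom, pos, ref, alt, ref_count, alt_count
#'   (see [simulate_rna_counts()] / [read_rna_counts()]).
#' @param min_rna_depth minimum ref + alt RNA reads (default 10).
#' @return data.frame of class `ase_records`: chrom, pos, gene_id, ref,
#'   alt, rna_ref, rna_alt, dp, ad_ref, ad_alt; attribute `skipped` counts
#'   allele-mismatch records.
#' @export
collect_ase <- function(variants, effects, rna, min_rna_depth = 10L) {
  check_that(nrow(variants) == nrow(effects),
             "variants and effects must be parallel")
  hi <- which(effects$impact == "high")
  skipped <- 0L
  rna_key <- paste(rna$chrom, rna$pos)
  rows <- list()
  for (i in hi) {
    j <- match(paste(variants$chrom[i], variants$pos[i]), rna_key)
    if (is.na(j)) next
    alt1 <- strsplit(variants$alt[i], ",", fixed = TRUE)[[1]][1]
    if (!identical(rna$ref[j], variants$ref[i]) ||
          !identical(rna$alt[j], alt1)) {
      skipped <- skipped + 1L
      next
    }
    if (rna$ref_count[j] + rna$alt_count[j] < min_rna_depth) next
    ad <- variants$ad[[i]]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = variants$chrom[i], pos = variants$pos[i],
      gene_id = effects$gene_id[i], ref = variants$ref[i], alt = alt1,
      rna_ref = rna$ref_count[j], rna_alt = rna$alt_count[j],
      dp = variants$dp[i], ad_ref = ad[1], ad_alt = ad[2],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    chrom = character(0), pos = integer(0), gene_id = character(0),
    ref = character(0), alt = character(0), rna_ref = integer(0),
    rna_alt = integer(0), dp = integer(0), ad_ref = integer(0),
    ad_alt = integer(0), stringsAsFactors = FALSE)
  if (skipped > 0) {
    warning(sprintf("%d RNA records skipped (allele mismatch)", skipped))
  }
  attr(out, "skipped") <- skipped
  class(out) <- c("ase_records", "data.frame")
  out
}

#' Reference-vs-alternative abundance contrast with genomic control
#'
#' Tests whether RNA reads supporting the reference allele outnumber those
#' supporting the (gene-disrupting) alternative allele across sites, and
#' runs the identical contrast on the genomic allele depths at the same
#' positions.  When the genomic control shows the same skew as the RNA,
#' the expression difference is explained by allele copy number rather
#' than transcript degradation (e.g. nonsense-mediated decay).
#'
#' @param records an `ase_records` table (>= 2 rows).
#' @param exact_limit passed to [mann_whitney_u()].
#' @return object of class `ase_contrast`: `rna_test`, `genomic_test`
#'   ([mann_whitney_u()] results), per-site alt/ref ratio summaries and
#'   pooled alternative-allele shares for both data types.
#' @export
ase_contrast <- function(records, exact_limit = 10L) {
  check_that(nrow(records) >= 2, "need >= 2 ASE records")
  ratio <- function(alt, ref) {
    ifelse(ref > 0, alt / ref, ifelse(alt > 0, Inf, NA_real_))
  }
  rna_ratio <- ratio(records$rna_alt, records$rna_ref)
  gen_ratio <- ratio(records$ad_alt, records$ad_ref)
  structure(list(
    n = nrow(records),
    rna_test = mann_whitney_u(records$rna_ref, records$rna_alt,
                              exact_limit = exact_limit),
    genomic_test = mann_whitney_u(records$ad_ref, records$ad_alt,
                                  exact_limit = exact_limit),
    rna_alt_share = sum(records$rna_alt) /
      max(1, sum(records$rna_alt + records$rna_ref)),
    genomic_alt_share = sum(records$ad_alt) /
      max(1, sum(records$ad_alt + records$ad_ref)),
    rna_median_ratio = median(rna_ratio[is.finite(rna_ratio)]),
    genomic_median_ratio = median(gen_ratio[is.finite(gen_ratio)]),
    rna_ratios = rna_ratio, genomic_ratios = gen_ratio
  ), class = "ase_contrast")
}

#' @export
print.ase_contrast <- function(x, ...) {
  cat(sprintf(
    paste0("<ase_contrast> %d sites\n",
           "  RNA:     alt share %.3f, median alt/ref %.3f, U p = %.3g\n",
           "  genomic: alt share %.3f, median alt/ref %.3f, U p = %.3g\n"),
    x$n, x$rna_alt_share, x$rna_median_ratio, x$rna_test$p_value,
    x$genomic_alt_share, x$genomic_median_ratio,
    x$genomic_test$p_value))
  invisible(x)
}

#' Read / write RNA allele-count tables
#'
#' TSV with columns chrom, pos, ref, alt, ref_count, alt_count (extra
#' columns preserved on read).
#' @param path file path.
#' @export
read_rna_counts <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' @rdname read_rna_counts
#' @param rna the count table.
#' @export
write_rna_counts <- function(rna, path) {
  data.table::fwrite(rna, path, sep = "\t")
  invisible(path)
}

#' Build an RNA allele-count table from samtools pileup text
#'
#' Minimal reader for 6-column `samtools mpileup` output (chrom, pos, ref
#' base, depth, read bases, qualities) restricted to SNV counting: `.` and
#' `,` support the reference; the most frequent mismatch base becomes the
#' alternative allele.  Indel and read start/end markup is stripped.
#'
#' @param path pileup file.
#' @return data.frame: chrom, pos, ref, alt, ref_count, alt_count.
#' @export
read_pileup_counts <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 3, 5)))
  check_that(ncol(dt) >= 5, "pileup needs >= 5 columns")
  parse_one <- function(ref, bases) {
    bases <- gsub("\\^.", "", bases)           # read starts (+ mapq char)
    bases <- gsub("\\$", "", bases)            # read ends
    while (grepl("[+-][0-9]+", bases)) {       # indel markup
      m <- regmatches(bases, regexpr("[+-][0-9]+", bases))
      L <- as.integer(substr(m, 2, nchar(m)))
      bases <- sub(sprintf("[+-][0-9]+[ACGTNacgtn]{%d}", L), "", bases)
    }
    ch <- strsplit(toupper(bases), "")[[1]]
    ref_n <- sum(ch %in% c(".", ","))
    mism <- ch[ch %in% c("A", "C", "G", "T") & ch != toupper(ref)]
    if (length(mism)) {
      tab <- sort(table(mism), decreasing = TRUE)
      c(ref_n, tab[[1]], names(tab)[1])
    } else {
      c(ref_n, 0L, NA_character_)
    }
  }
  parsed <- t(vapply(seq_len(nrow(dt)),
                     function(i) parse_one(dt[[3]][i], dt[[5]][i]),
                     c("", "", "")))
  data.frame(chrom = dt[[1]], pos = as.integer(dt[[2]]),
             ref = toupper(dt[[3]]), alt = parsed[, 3],
             ref_count = as.integer(parsed[, 1]),
             alt_count = as.integer(parsed[, 2]),
             stringsAsFactors = FALSE)
}
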