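#' Two-proportion enrichment test for codon-multiple InDels
#'
#' Tests whether the fraction of InDels with length divisible by 3 differs
#' between the inside-CDS and outside-CDS compartments.  Uses the pooled
#' two-proportion z-test (normal approximation, no continuity correction);
#' when any expected cell count is below 5, falls back to Fisher's exact
#' (hypergeometric) test.
#'
#' @param x_in,n_in divisible-by-3 count and total inside CDS.
#' @param x_out,n_out the same outside CDS.
#' @return list: `statistic` (z, NA for the exact route), `p_value`
#'   (two-sided), `method`, per-compartment proportions.
#' @export
frame_enrichment_test <- function(x_in, n_in, x_out, n_out) {
  check_that(n_in >= 1 && n_out >= 1, "both compartments need >= 1 InDel")
  check_that(x_in <= n_in && x_out <= n_out, "counts exceed totals")
  p_pool <- (x_in + x_out) / (n_in + n_out)
  expected <- c(n_in * p_pool, n_in * (1 - p_pool),
                n_out * p_pool, n_out * (1 - p_pool))
  if (any(expected < 5) || p_pool %in% c(0, 1)) {
    tab <- matrix(c(x_in, n_in - x_in, x_out, n_out - x_out), nrow = 2)
    p <- fisher.test(tab)$p.value
    return(list(statistic = NA_real_, p_value = p, method = "fisher_exact",
                prop_in = x_in / n_in, prop_out = x_out / n_out))
  }
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n_in + 1 / n_out))
  z <- (x_in / n_in - x_out / n_out) / se
  list(statistic = z, p_value = 2 * pnorm(-abs(z)),
       method = "normal_approximation",
       prop_in = x_in / n_in, prop_out = x_out / n_out)
}

#' InDel length and codon-frame analysis inside vs outside CDS
#'
#' Splits small InDels into the coding compartment (affected reference
#' span overlapping any CDS base; for insertions, anchor base inside CDS)
#' and the rest of the genome, then compares their length distributions:
#' counts divisible by 3 (one codon) per compartment, per-compartment
#' densities per Mbp (CDS length = union of CDS intervals, no
#' double-counting), a density-depletion ratio, and the
#' [frame_enrichment_test()].  Residual selection against gene disruption
#' shows up as 3n-enrichment and overall InDel depletion inside CDS.
#'
#' @param variants a `variant_table`; only records typed InDel are used.
#' @param annotation CDS annotation (as for [annotate_effect()]).
#' @param genome_length total genome length in bp.
#' @return object of class `indel_frame_table`.
#' @export
indel_frame_analysis <- function(variants, annotation, genome_length) {
  cds <- effect_cds_table(annotation)
  cds_gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(cds$chrom, IRanges::IRanges(cds$start, cds$end)))
  cds_len <- sum(as.numeric(GenomicRanges::width(cds_gr)))
  check_that(cds_len > 0, "zero total CDS length")
  check_that(genome_length > cds_len,
             "genome_length must exceed total CDS length")

  ind <- variants[variant_type(variants) == "InDel", , drop = FALSE]
  n <- nrow(ind)
  len <- integer(n); inside <- logical(n)
  if (n > 0) {
    alts1 <- vapply(strsplit(ind$alt, ",", fixed = TRUE), `[`, "", 1)
    rl <- nchar(ind$ref); al <- nchar(alts1)
    len <- abs(al - rl)
    check_that(all(len > 0), "InDel with zero length difference")
    span_start <- ifelse(al > rl, ind$pos, ind$pos + 1L)
    span_end <- ifelse(al > rl, ind$pos, ind$pos + rl - 1L)
    q <- GenomicRanges::GRanges(ind$chrom,
                                IRanges::IRanges(span_start, span_end))
    inside <- !is.na(GenomicRanges::findOverlaps(q, cds_gr,
                                                 select = "first"))
  }
  len_in <- len[inside]; len_out <- len[!inside]
  div3 <- function(v) sum(v %% 3L == 0L)
  mbp_in <- cds_len / 1e6
  mbp_out <- (genome_length - cds_len) / 1e6
  test <- if (length(len_in) >= 1 && length(len_out) >= 1) {
    frame_enrichment_test(div3(len_in), length(len_in),
                          div3(len_out), length(len_out))
  } else {
    list(statistic = NA_real_, p_value = NA_real_, method = "not_run",
         prop_in = NA_real_, prop_out = NA_real_)
  }
  structure(list(
    n_total = n,
    n_inside = length(len_in), n_outside = length(len_out),
    hist_inside = table(factor(len_in, levels = sort(unique(len)))),
    hist_outside = table(factor(len_out, levels = sort(unique(len)))),
    div3_inside = div3(len_in), div3_outside = div3(len_out),
    frac_div3_inside = if (length(len_in)) div3(len_in) / length(len_in)
                       else NA_real_,
    frac_div3_outside = if (length(len_out)) div3(len_out) / length(len_out)
                        else NA_real_,
    cds_length = cds_len, genome_length = genome_length,
    density_inside = length(len_in) / mbp_in,
    density_outside = length(len_out) / mbp_out,
    density_ratio = (length(len_in) / mbp_in) /
      max(length(len_out) / mbp_out, .Machine$double.eps),
    test = test
  ), class = "indel_frame_table")
}

#' @export
print.indel_frame_table <- function(x, ...) {
  cat(sprintf(
    paste0("<indel_frame_table> %d InDels: %d inside CDS (%.1f/Mbp, ",
           "%.0f%% 3n), %d outside (%.1f/Mbp, %.0f%% 3n)\n",
           "  enrichment: %s p = %.3g, density ratio (in/out) = %.3f\n"),
    x$n_total, x$n_inside, x$density_inside, 100 * x$frac_div3_inside,
    x$n_outside, x$density_outside, 100 * x$frac_div3_outside,
    x$test$method, x$test$p_value, x$density_ratio))
  invisible(x)
}
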