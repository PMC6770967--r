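#' Zygosity classification thresholds
#'
#' The bespoke small-variant filters of the culture-genome analysis: a
#' non-dominant allele supported by at least `r_min` reads and at least
#' `f_min` of the total depth marks a site as deviating-frequency (the
#' cell-culture analogue of heterozygosity, both bounds inclusive); a
#' variant whose depth deviates from the mean of a `flank` bp flanking
#' window by strictly more than `max_dev` is excluded as unreliable.
#'
#' @param r_min minimum supporting reads (default 5).
#' @param f_min minimum supporting fraction of DP (default 0.05).
#' @param flank flank length in bp on each side (default 2000).
#' @param max_dev maximum relative coverage deviation (default 0.20,
#'   strict: exactly 20\% still passes).
#' @return object of class `zygosity_thresholds`.
#' @export
zygosity_thresholds <- function(r_min = 5L, f_min = 0.05, flank = 2000L,
                                max_dev = 0.20) {
  check_that(r_min >= 1, "r_min must be >= 1")
  check_that(f_min > 0 && f_min < 1, "f_min must be in (0, 1)")
  check_that(flank > 0, "flank must be positive")
  check_that(max_dev > 0 && max_dev < 1, "max_dev must be in (0, 1)")
  structure(list(r_min = as.integer(r_min), f_min = f_min,
                 flank = as.integer(flank), max_dev = max_dev),
            class = "zygosity_thresholds")
}

#' Classify variant zygosity from allele depths
#'
#' The dominant allele at a site is the one with maximal allele depth.  A
#' site is `deviating_frequency` when any non-dominant allele is supported
#' by at least `r_min` reads and at least `f_min` of the total depth
#' (both inclusive); otherwise it is `homozygous` for the dominant allele.
#' When two alleles tie for dominance, the site is deviating if the tied
#' depth itself passes the thresholds (two equally supported co-existing
#' alleles); ties are counted in the `ties` attribute.
#'
#' @param variants a `variant_table` (or any data.frame with `dp` and a
#'   list column `ad` ordered ref, alt1, ...).
#' @param thresholds a [zygosity_thresholds()].
#' @return character vector ("homozygous" / "deviating_frequency") with
#'   attribute `ties` (number of dominance ties observed).
#' @export
classify_zygosity <- function(variants, thresholds = zygosity_thresholds()) {
  check_that(!is.null(variants$ad), "allele depths (ad) missing")
  check_that(all(variants$dp > 0), "DP must be > 0 for classification")
  ties <- 0L
  out <- vapply(seq_len(nrow(variants)), function(i) {
    ad <- variants$ad[[i]]
    check_that(length(ad) >= 2 && !anyNA(ad), "invalid AD at record %d", i)
    check_that(sum(ad) > 0, "all-zero AD at record %d", i)
    dp <- variants$dp[i]
    dom <- which.max(ad)
    tied <- sum(ad == ad[dom]) > 1L
    if (tied) ties <<- ties + 1L
    others <- if (tied) ad[-dom[1]] else ad[-dom]
    dev <- any(others >= thresholds$r_min &
                 others / dp >= thresholds$f_min)
    if (dev) "deviating_frequency" else "homozygous"
  }, "")
  attr(out, "ties") <- ties
  out
}

#' Coverage-deviation exclusion filter
#'
#' Excludes a variant when its total depth DP deviates from the mean depth
#' of the surrounding flanking window (default 2 kb each side, variant base
#' itself excluded, clipped at chromosome ends) by strictly more than
#' `max_dev` (default 20\%).  A variant whose flank has zero mean depth is
#' excluded with reason `flank_zero`.
#'
#' @param variants a `variant_table`.
#' @param track a `coverage_track` (the depth source for the flank mean —
#'   not the VCF DP values).
#' @param thresholds a [zygosity_thresholds()].
#' @return data.frame: status ("pass" / "coverage_deviation"), reason
#'   ("", "depth_deviation" or "flank_zero"), flank_mean, rel_dev.
#' @export
coverage_deviation_filter <- function(variants, track,
                                      thresholds = zygosity_thresholds()) {
  check_that(all(variants$chrom %in% names(track)),
             "variant chromosome absent from coverage track")
  n <- nrow(variants)
  fm <- numeric(n)
  for (i in seq_len(n)) {
    d <- track[[variants$chrom[i]]]
    p <- variants$pos[i]
    check_that(p >= 1 && p <= length(d),
               "variant position %d outside track", p)
    fm[i] <- interval_mean_depth(d, p - thresholds$flank,
                                 p + thresholds$flank, exclude = p)
  }
  rel <- ifelse(fm > 0, abs(variants$dp - fm) / fm, Inf)
  status <- ifelse(fm <= 0, "coverage_deviation",
                   ifelse(rel > thresholds$max_dev, "coverage_deviation",
                          "pass"))
  reason <- ifelse(fm <= 0, "flank_zero",
                   ifelse(status == "coverage_deviation", "depth_deviation",
                          ""))
  data.frame(status = status, reason = reason, flank_mean = fm,
             rel_dev = ifelse(is.finite(rel), rel, NA_real_),
             stringsAsFactors = FALSE)
}

#' Variant density in genomic blocks, split by zygosity class
#'
#' Counts variants per fixed-size block (default 100 kb) separately for
#' homozygous and deviating-frequency sites — the genome-wide variant
#' landscape view.
#'
#' @param variants a `variant_table`.
#' @param classes zygosity class per variant (from [classify_zygosity()]).
#' @param block_size block length in bp.
#' @param chrom_lengths optional named lengths so trailing empty blocks are
#'   included.
#' @return data.frame: chrom, block_start, block_end (1-based closed),
#'   homozygous, deviating_frequency, total.
#' @export
variant_density <- function(variants, classes, block_size = 100000L,
                            chrom_lengths = NULL) {
  check_that(block_size >= 1, "block size must be >= 1")
  check_that(nrow(variants) == length(classes),
             "classes must match variants")
  block_size <- as.integer(block_size)
  chroms <- if (!is.null(chrom_lengths)) {
    reference_lengths(chrom_lengths)
  } else if (nrow(variants)) {
    tapply(variants$pos, variants$chrom, max)[unique(variants$chrom)]
  } else {
    setNames(integer(0), character(0))
  }
  parts <- lapply(names(chroms), function(chrom) {
    nb <- max(1L, as.integer(ceiling(chroms[[chrom]] / block_size)))
    sel <- variants$chrom == chrom
    blk <- (variants$pos[sel] - 1L) %/% block_size + 1L
    hom <- tabulate(blk[classes[sel] == "homozygous"], nbins = nb)
    dev <- tabulate(blk[classes[sel] == "deviating_frequency"], nbins = nb)
    data.frame(chrom = chrom,
               block_start = (seq_len(nb) - 1L) * block_size + 1L,
               block_end = pmin(as.integer(chroms[[chrom]]),
                                seq_len(nb) * block_size),
               homozygous = hom, deviating_frequency = dev,
               total = hom + dev, stringsAsFactors = FALSE)
  })
  do.call(rbind, parts)
}

#' Base substitution spectrum of SNVs
#'
#' Tallies the 12 directed nucleotide substitutions over all alternative
#' alleles of the supplied SNV records, collapses them to the 6
#' strand-symmetric classes (keyed on a pyrimidine reference base, e.g.
#' G:C>T:A is reported as C>A), and reports the share of changes away from
#' C:G pairs towards A:T pairs — the signature expected from spontaneous
#' cytosine deamination and oxidative G damage.
#'
#' @param variants a `variant_table` of SNVs only (single-base ref and
#'   alts); anything else is an error.
#' @return object of class `spectrum_table`: list with `directed` (named
#'   12-vector), `collapsed` (named 6-vector), `cg_to_at_share`, `n`.
#' @export
substitution_spectrum <- function(variants) {
  alts <- strsplit(variants$alt, ",", fixed = TRUE)
  check_that(all(nchar(variants$ref) == 1) &&
               all(nchar(unlist(alts)) == 1),
             "substitution_spectrum accepts SNV records only")
  ref <- rep(variants$ref, lengths(alts))
  alt <- unlist(alts)
  bases <- c("A", "C", "G", "T")
  keys <- paste0(ref, ">", alt)
  all12 <- as.vector(t(outer(bases, bases, paste, sep = ">")))
  all12 <- all12[substr(all12, 1, 1) != substr(all12, 3, 3)]
  directed <- setNames(tabulate(factor(keys, levels = all12),
                                nbins = length(all12)), all12)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  collapse_key <- function(k) {
    r <- substr(k, 1, 1); a <- substr(k, 3, 3)
    if (r %in% c("C", "T")) paste0(r, ">", a)
    else paste0(comp[[r]], ">", comp[[a]])
  }
  coll6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  collapsed <- setNames(numeric(6), coll6)
  for (k in names(directed)) {
    ck <- collapse_key(k)
    collapsed[ck] <- collapsed[ck] + directed[k]
  }
  n <- sum(directed)
  cg_at <- sum(directed[c("C>A", "C>T", "G>T", "G>A")])
  structure(list(directed = directed, collapsed = collapsed,
                 cg_to_at_share = if (n > 0) cg_at / n else NA_real_,
                 n = n,
                 collapse_convention = "pyrimidine-reference (C/T) keys"),
            class = "spectrum_table")
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat(sprintf("<spectrum_table> %d substitutions, CG->AT share %.3f\n",
              x$n, x$cg_to_at_share))
  print(x$collapsed)
  invisible(x)
}

#' Variant type of each record
#'
#' "SNV" when reference and every alternative allele are single bases,
#' "InDel" when any alternative allele length differs from the reference,
#' "MNV" otherwise (multi-base same-length substitutions).
#'
#' @param variants a `variant_table`.
#' @return character vector.
#' @export
variant_type <- function(variants) {
  alts <- strsplit(variants$alt, ",", fixed = TRUE)
  vapply(seq_len(nrow(variants)), function(i) {
    rl <- nchar(variants$ref[i]); al <- nchar(alts[[i]])
    if (rl == 1 && all(al == 1)) "SNV"
    else if (any(al != rl)) "InDel"
    else "MNV"
  }, "")
}

#' SNV : InDel counts and ratio
#'
#' @param variants a `variant_table`.
#' @return list with `n_snv`, `n_indel`, `ratio` (Inf when there are SNVs
#'   but no InDels, NA when both are zero).
#' @export
snv_indel_ratio <- function(variants) {
  ty <- variant_type(variants)
  n_snv <- sum(ty == "SNV"); n_indel <- sum(ty == "InDel")
  ratio <- if (n_indel > 0) n_snv / n_indel
           else if (n_snv > 0) Inf else NA_real_
  list(n_snv = n_snv, n_indel = n_indel, ratio = ratio)
}

#' Depth histograms at variant positions, per zygosity class
#'
#' Bins the coverage-track depth at each variant position separately for
#' homozygous and deviating-frequency variants.  On a hemizygosity-driven
#' genome the homozygous class concentrates at the per-copy unit (one
#' remaining allele) and the deviating class at its multiples.
#'
#' @param variants a `variant_table`.
#' @param track a `coverage_track`.
#' @param classes zygosity class per variant.
#' @param binwidth histogram bin width in depth units.
#' @return list with `breaks`, per-class `counts` matrices, per-class
#'   `mean` and `mode` depths.
#' @export
coverage_histogram_at_variants <- function(variants, track, classes,
                                           binwidth = 5) {
  depth <- integer(nrow(variants))
  for (chrom in unique(variants$chrom)) {
    sel <- variants$chrom == chrom
    depth[sel] <- track[[chrom]][variants$pos[sel]]
  }
  top <- max(depth, 1)
  breaks <- seq(0, (top %/% binwidth + 1) * binwidth, by = binwidth)
  cls <- c("homozygous", "deviating_frequency")
  counts <- sapply(cls, function(cl) {
    if (!any(classes == cl)) return(integer(length(breaks) - 1L))
    graphics::hist(depth[classes == cl], breaks = breaks,
                   plot = FALSE)$counts
  })
  modal <- vapply(cls, function(cl) {
    ct <- counts[, cl]
    if (sum(ct) == 0) return(NA_real_)
    i <- which.max(ct)
    (breaks[i] + breaks[i + 1]) / 2
  }, 0)
  means <- vapply(cls, function(cl) {
    if (!any(classes == cl)) NA_real_ else mean(depth[classes == cl])
  }, 0)
  list(breaks = breaks, counts = counts, mean = means, mode = modal)
}
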