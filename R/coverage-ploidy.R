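#' Windowed mean coverage
#'
#' Mean depth in consecutive non-overlapping windows of `w` bases; the last
#' window of a chromosome may be shorter and is averaged over its actual
#' length.  This is the track behind genome-wide coverage overview plots.
#'
#' @param track a `coverage_track`.
#' @param w window size in bp (>= 1).
#' @return data.frame: chrom, start, end (1-based closed), mean_depth.
#' @export
windowed_mean_coverage <- function(track, w) {
  check_that(length(track) > 0, "empty coverage track")
  check_that(w >= 1, "window size must be >= 1")
  w <- as.integer(w)
  parts <- lapply(names(track), function(chrom) {
    d <- as.numeric(track[[chrom]])
    n <- length(d)
    idx <- rep(seq_len(ceiling(n / w)), each = w, length.out = n)
    m <- tapply(d, idx, mean)
    start <- (seq_along(m) - 1L) * w + 1L
    data.frame(chrom = chrom, start = start,
               end = pmin(n, start + w - 1L),
               mean_depth = as.numeric(m),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, parts)
}

#' Find zero-coverage regions (complete deletions)
#'
#' Maximal runs of exactly zero depth strictly longer than `L_min` bp,
#' interpreted as regions completely deleted from the culture genome.
#' The default threshold follows the convention of counting only regions
#' larger than 100 bp, so a run of exactly 100 bp is excluded and a run of
#' 101 bp reported.
#'
#' @param track a `coverage_track`.
#' @param L_min minimum length threshold in bp (strict: reported runs have
#'   length > L_min).
#' @return data.frame: chrom, start, end (1-based closed), length; sorted
#'   by chromosome (track order) then position.
#' @export
find_zero_coverage_regions <- function(track, L_min = 100L) {
  check_that(L_min >= 1, "L_min must be >= 1")
  parts <- lapply(names(track), function(chrom) {
    r <- rle(track[[chrom]] == 0L)
    end <- cumsum(r$lengths)
    start <- end - r$lengths + 1L
    keep <- r$values & r$lengths > L_min
    data.frame(chrom = rep(chrom, sum(keep)), start = start[keep],
               end = end[keep], length = r$lengths[keep],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, parts)
}

#' Mean depth per annotated gene
#'
#' Arithmetic mean of per-base depth over the full gene span (not
#' CDS-only), the per-gene copy-number proxy.
#'
#' @param track a `coverage_track`.
#' @param genes data.frame with gene_id, chrom, start, end (1-based closed).
#' @return data.frame: gene_id, chrom, start, end, mean_depth.
#' @export
gene_mean_depths <- function(track, genes) {
  check_that(all(genes$chrom %in% names(track)),
             "gene chromosome absent from coverage track")
  md <- numeric(nrow(genes))
  for (chrom in unique(genes$chrom)) {
    cs <- c(0, cumsum(as.numeric(track[[chrom]])))
    sel <- which(genes$chrom == chrom)
    s <- genes$start[sel]; e <- genes$end[sel]
    check_that(all(e <= length(track[[chrom]])),
               "gene beyond coverage track on %s", chrom)
    md[sel] <- (cs[e + 1L] - cs[s]) / (e - s + 1L)
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = genes$start, end = genes$end, mean_depth = md,
             stringsAsFactors = FALSE)
}

#' Estimate the per-copy depth unit from gene coverage values
#'
#' Smooths the distribution of per-gene mean depths (kernel density) and
#' reads the copy-number structure off its peaks and valleys: the unit `c`
#' is the location of the first non-zero peak (the hemizygous class);
#' valleys between successive peaks act as class boundaries.  The peak
#' location is refined to the median of the depth values falling between
#' the flanking valleys, which makes the degenerate one-class case exact.
#'
#' @param depths numeric vector of per-gene mean depths (>= 20 positive
#'   values required).
#' @param bandwidth kernel bandwidth; default `median(depths > 0) / 20`,
#'   i.e. about a tenth of a first-pass median-based guess of `c` for a
#'   predominantly 2-3 copy genome.
#' @param min_peak_frac peaks below this fraction of the tallest peak are
#'   ignored (noise suppression).
#' @return object of class `ploidy_baseline`: list with `c` (the unit),
#'   `peaks`, `valleys`, `low_confidence` (TRUE when only a single peak is
#'   detectable), `bandwidth`.
#' @export
estimate_ploidy_baseline <- function(depths, bandwidth = NULL,
                                     min_peak_frac = 0.05) {
  d <- depths[is.finite(depths) & depths > 0]
  check_that(length(d) >= 20, "need >= 20 genes with positive depth")
  if (is.null(bandwidth)) bandwidth <- max(median(d) / 20, 1e-8)
  if (length(unique(d)) == 1L) {
    return(structure(list(c = d[1], peaks = d[1], valleys = numeric(0),
                          low_confidence = TRUE, bandwidth = bandwidth),
                     class = "ploidy_baseline"))
  }
  dens <- density(d, bw = bandwidth, from = 0, to = max(d) + 4 * bandwidth,
                  n = 1024)
  y <- dens$y; x <- dens$x
  is_peak <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                 y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  peaks <- x[is_peak & y >= min_peak_frac * max(y)]
  if (length(peaks) == 0) peaks <- x[which.max(y)]
  valleys <- numeric(0)
  if (length(peaks) > 1) {
    pk_idx <- vapply(peaks, function(p) which.min(abs(x - p)), 0L)
    valleys <- vapply(seq_len(length(peaks) - 1L), function(i) {
      span <- pk_idx[i]:pk_idx[i + 1L]
      x[span[which.min(y[span])]]
    }, 0)
  }
  # refine the first peak to the median of its class members
  lo <- 0
  hi <- if (length(valleys)) valleys[1] else Inf
  members <- d[d > lo & d < hi]
  c_hat <- if (length(members)) median(members) else peaks[1]
  structure(list(c = c_hat, peaks = peaks, valleys = valleys,
                 low_confidence = length(peaks) < 2,
                 bandwidth = bandwidth),
            class = "ploidy_baseline")
}

#' @export
print.ploidy_baseline <- function(x, ...) {
  cat(sprintf("<ploidy_baseline> unit c = %.2f, %d peak(s)%s\n", x$c,
              length(x$peaks),
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Classify gene copy number against the per-copy unit
#'
#' `k_hat = round(depth / c)`, clamped to `[0, k_max]`: a gene at the unit
#' depth is hemizygous (one copy), at three units triploid, and so on; a
#' gene below half a unit is called deleted (k = 0).
#'
#' @param mean_depth numeric vector of per-gene mean depths.
#' @param baseline a `ploidy_baseline` or the numeric unit `c`.
#' @param k_max clamp ceiling (values above are truncated, mirroring the
#'   pooling of extreme coverage classes).
#' @return integer vector of copy-number estimates.
#' @export
classify_gene_copy_number <- function(mean_depth, baseline, k_max = 8L) {
  c_unit <- if (inherits(baseline, "ploidy_baseline")) baseline$c else baseline
  check_that(is.numeric(c_unit) && c_unit > 0, "unit c must be positive")
  pmin(as.integer(k_max), pmax(0L, as.integer(round(mean_depth / c_unit))))
}

#' Flag genes with coverage similar to their flanking genes
#'
#' A gene is "similar to flanking" when its mean depth lies within a
#' relative tolerance of the depth of its nearest annotated neighbour on at
#' least one side: a gene matching one side still belongs to a contiguous
#' coverage block (segment boundaries fall between genes, so block-interior
#' genes match both sides and boundary genes one).  Chromosome-terminal
#' genes are compared to their single neighbour; single-gene chromosomes
#' get `NA`.
#'
#' @param gene_depths data.frame from [gene_mean_depths()] (must be, or
#'   will be, ordered by chromosome and start).
#' @param tau relative tolerance (default 0.2, i.e. within 20\%).
#' @return the input with a logical `similar_to_flanking` column.
#' @export
flag_flanking_similarity <- function(gene_depths, tau = 0.2) {
  check_that(tau > 0, "tau must be positive")
  gd <- gene_depths[order(gene_depths$chrom, gene_depths$start), ,
                    drop = FALSE]
  flag <- rep(NA, nrow(gd))
  for (chrom in unique(gd$chrom)) {
    sel <- which(gd$chrom == chrom)
    n <- length(sel)
    if (n < 2) next
    d <- gd$mean_depth[sel]
    left <- c(NA, d[-n]); right <- c(d[-1], NA)
    close_to <- function(nb) {
      ifelse(is.na(nb), FALSE,
             ifelse(nb > 0, abs(d - nb) / nb <= tau, d == nb))
    }
    flag[sel] <- close_to(left) | close_to(right)
  }
  gd$similar_to_flanking <- flag
  gd
}

#' Chondrome to plastome coverage ratio
#'
#' Mean depth over the mitochondrial replicon(s) divided by mean depth over
#' the plastid replicon(s); optionally expressed as fold change against a
#' reference ratio (e.g. the ratio observed in native plants).
#'
#' @param track a `coverage_track`.
#' @param chondrome_ids,plastome_ids sequence ids of each compartment.
#' @param reference_ratio optional baseline ratio for a fold-change report.
#' @return list with `ratio`, mean depths, and `fold_change` (NA when no
#'   reference is given).
#' @export
organelle_coverage_ratio <- function(track, chondrome_ids, plastome_ids,
                                     reference_ratio = NULL) {
  check_that(all(chondrome_ids %in% names(track)) &&
               all(plastome_ids %in% names(track)),
             "organelle replicons missing from coverage track")
  mean_of <- function(ids) {
    v <- unlist(track[ids], use.names = FALSE)
    sum(as.numeric(v)) / length(v)
  }
  mc <- mean_of(chondrome_ids)
  mp <- mean_of(plastome_ids)
  check_that(mp > 0, "zero plastome coverage: ratio undefined")
  list(ratio = mc / mp, chondrome_mean = mc, plastome_mean = mp,
       fold_change = if (is.null(reference_ratio)) NA_real_
                     else (mc / mp) / reference_ratio)
}

#' Write zero-coverage regions as BED (0-based half-open)
#' @param regions output of [find_zero_coverage_regions()].
#' @param path output path.
#' @export
write_zero_regions_bed <- function(regions, path) {
  dt <- data.table::data.table(chrom = regions$chrom,
                               start = regions$start - 1L,
                               end = regions$end)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
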