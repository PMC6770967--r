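#' Plant a segmental copy-number map
#'
#' Partitions every chromosome into contiguous segments carrying an integer
#' haplophase copy number `k`.  The culture genome this emulates is mostly
#' triploid with hemizygous and pentaploid blocks and a few completely
#' deleted regions, so the default copy states are {0, 1, 2, 3, 5} with
#' weights favouring k = 3.
#'
#' Two modes:
#' \itemize{
#'   \item explicit: pass `segments` (chrom, start, end, k; 1-based closed)
#'     covering each listed chromosome exactly, no gaps or overlaps;
#'   \item random: segment lengths drawn i.i.d. exponential with mean
#'     `seg_mean_len` (last segment truncated at the chromosome end) and
#'     `k` drawn from `k_values` with `k_weights`.
#' }
#'
#' @param chrom_lengths named lengths (or an `sc_reference`).
#' @param segments optional explicit segment data.frame.
#' @param seg_mean_len mean random segment length in bp.
#' @param k_values,k_weights copy states and sampling weights (random mode).
#' @param k_max maximum admissible copy number.
#' @param seed integer seed (random mode).
#' @return data.frame of class `copy_map`: chrom, start, end, k
#'   (1-based closed; one or more rows per chromosome, partitioning it).
#' @export
#' @examples
#' cm <- plant_copy_map(c(chr1 = 1e5), seg_mean_len = 2e4, seed = 1)
#' table(cm$k)
plant_copy_map <- function(chrom_lengths,
                           segments = NULL,
                           seg_mean_len = 5e5,
                           k_values = c(0L, 1L, 2L, 3L, 5L),
                           k_weights = c(0.02, 0.15, 0.13, 0.50, 0.20),
                           k_max = 8L,
                           seed = NULL) {
  lens <- reference_lengths(chrom_lengths)
  if (!is.null(segments)) {
    check_that(all(c("chrom", "start", "end", "k") %in% names(segments)),
               "segments needs columns chrom, start, end, k")
    check_that(all(segments$chrom %in% names(lens)),
               "segment chromosome absent from reference")
    check_that(all(segments$k >= 0), "copy numbers must be >= 0")
    check_that(all(segments$k <= k_max), "copy number exceeds k_max")
    out <- segments[order(match(segments$chrom, names(lens)),
                          segments$start), , drop = FALSE]
    for (chrom in unique(out$chrom)) {
      s <- out[out$chrom == chrom, , drop = FALSE]
      check_that(s$start[1] == 1L, "segments on %s must start at 1", chrom)
      check_that(s$end[nrow(s)] == lens[[chrom]],
                 "segments on %s must end at the chromosome end (%d)",
                 chrom, lens[[chrom]])
      check_that(all(s$end >= s$start), "empty segment on %s", chrom)
      if (nrow(s) > 1) {
        check_that(all(s$start[-1] == head(s$end, -1) + 1L),
                   "segments on %s have gaps or overlaps", chrom)
      }
    }
    rownames(out) <- NULL
    class(out) <- c("copy_map", "data.frame")
    return(out)
  }
  check_that(length(k_values) == length(k_weights) && all(k_weights >= 0),
             "k_values and k_weights must match")
  check_that(all(k_values >= 0 & k_values <= k_max),
             "k_values must lie in [0, k_max]")
  with_seed(seed, {
    out <- list()
    for (chrom in names(lens)) {
      L <- lens[[chrom]]
      pos <- 1L
      while (pos <= L) {
        len <- max(1L, as.integer(ceiling(stats::rexp(1, 1 / seg_mean_len))))
        end <- min(L, pos + len - 1L)
        k <- sample(k_values, 1L, prob = k_weights)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = end, k = k,
          stringsAsFactors = FALSE)
        pos <- end + 1L
      }
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    class(out) <- c("copy_map", "data.frame")
    out
  })
}

#' Copy number at given positions
#' @keywords internal
#' @noRd
copy_at <- function(copy_map, chrom, pos) {
  k <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    seg <- copy_map[copy_map$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    idx <- findInterval(pos[sel], seg$start)
    ok <- idx >= 1 & pos[sel] <= seg$end[pmax(idx, 1L)]
    kk <- rep(NA_real_, sum(sel))
    kk[ok] <- seg$k[idx[ok]]
    k[sel] <- kk
  }
  k
}

#' Write a copy map as BED with a copy-number column
#'
#' BED is 0-based half-open per the format standard; column 4 is the name
#' (`segNNN`), column 5 the copy number.
#' @param copy_map a `copy_map`.
#' @param path output path.
#' @export
write_copy_bed <- function(copy_map, path) {
  dt <- data.table::data.table(
    chrom = copy_map$chrom,
    start = copy_map$start - 1L,
    end = copy_map$end,
    name = sprintf("seg%04d", seq_len(nrow(copy_map))),
    k = copy_map$k)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a copy map written by [write_copy_bed()]
#' @param path BED file with a copy column.
#' @return a `copy_map` data.frame (1-based closed).
#' @export
read_copy_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "name", "k"))
  out <- data.frame(chrom = dt$chrom, start = dt$start + 1L, end = dt$end,
                    k = dt$k, stringsAsFactors = FALSE)
  class(out) <- c("copy_map", "data.frame")
  out
}
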