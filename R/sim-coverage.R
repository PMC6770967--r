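#' Depth noise model
#'
#' Parameterises how sequencing depth is simulated around the per-copy depth
#' unit `c`: expected depth at a base inside a k-copy segment is `k * c`,
#' with Poisson noise by default or negative binomial noise with the given
#' dispersion (`size` parameter; smaller = noisier).  Organelle replicons
#' sit outside the nuclear copy map; their expected depth is
#' `multiplier * c` with the same noise family.  The defaults emulate the
#' ~50-fold per-copy unit of the study's culture genome and its roughly
#' 10-fold elevated chondrome:plastome coverage ratio.
#'
#' @param c per-copy depth unit (reads per base contributed by one copy).
#' @param family "poisson" or "nbinom".
#' @param dispersion negative-binomial size (ignored for Poisson).
#' @param organelle_multipliers named depth multipliers (in units of `c`)
#'   for organelle replicons.
#' @param rna_depth expected RNA read total per expressed variant site,
#'   used by [simulate_rna_counts()].
#' @return object of class `noise_model`.
#' @export
noise_model <- function(c = 50,
                        family = c("poisson", "nbinom"),
                        dispersion = 10,
                        organelle_multipliers = c(plastome = 4, chondrome = 40),
                        rna_depth = 300) {
  family <- match.arg(family)
  check_that(c > 0, "per-copy depth unit must be positive")
  check_that(rna_depth >= 0, "rna_depth must be >= 0")
  if (family == "nbinom") check_that(dispersion > 0, "dispersion must be > 0")
  structure(list(c = c, family = family, dispersion = dispersion,
                 organelle_multipliers = organelle_multipliers,
                 rna_depth = rna_depth),
            class = "noise_model")
}

sample_depth <- function(n, mu, noise) {
  if (mu <= 0) return(integer(n))
  if (noise$family == "poisson") {
    rpois(n, mu)
  } else {
    stats::rnbinom(n, size = noise$dispersion, mu = mu)
  }
}

#' Simulate a per-base coverage track from a copy map
#'
#' Each base in a k-copy segment draws its depth independently with mean
#' `k * c`; k = 0 segments are exactly zero.  Organelle replicons (named in
#' `organelles` and present in `chrom_lengths`) use the noise model's
#' multipliers instead of the copy map.
#'
#' @param copy_map a `copy_map` (nuclear segments).
#' @param noise a [noise_model()].
#' @param chrom_lengths named lengths or an `sc_reference`; defaults to the
#'   extent of the copy map.
#' @param organelles character vector of organelle sequence ids to simulate
#'   via `noise$organelle_multipliers` (taken from the reference if one is
#'   supplied).
#' @param seed integer seed.
#' @return a `coverage_track`: named list of per-base integer depth vectors.
#' @export
#' @examples
#' cm <- plant_copy_map(c(chr1 = 2000),
#'                      segments = data.frame(chrom = "chr1", start = 1,
#'                                            end = 2000, k = 2))
#' tr <- simulate_coverage(cm, noise_model(c = 50), seed = 1)
#' mean(tr$chr1)
simulate_coverage <- function(copy_map, noise, chrom_lengths = NULL,
                              organelles = NULL, seed = NULL) {
  check_that(inherits(noise, "noise_model"), "noise must be a noise_model")
  if (inherits(chrom_lengths, "sc_reference")) {
    organelles <- organelles %||% chrom_lengths$organelles
    chrom_lengths <- reference_lengths(chrom_lengths)
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(copy_map$end, copy_map$chrom), max, 0)
    # preserve copy-map chromosome order
    chrom_lengths <- chrom_lengths[unique(copy_map$chrom)]
  }
  with_seed(seed, {
    track <- list()
    for (chrom in names(chrom_lengths)) {
      L <- chrom_lengths[[chrom]]
      if (!is.null(organelles) && chrom %in% organelles) {
        mult <- noise$organelle_multipliers[[chrom]] %||% 1
        track[[chrom]] <- sample_depth(L, mult * noise$c, noise)
        next
      }
      seg <- copy_map[copy_map$chrom == chrom, , drop = FALSE]
      check_that(nrow(seg) > 0, "no copy-map segments for %s", chrom)
      d <- integer(L)
      for (i in seq_len(nrow(seg))) {
        idx <- seg$start[i]:seg$end[i]
        d[idx] <- sample_depth(length(idx), seg$k[i] * noise$c, noise)
      }
      track[[chrom]] <- d
    }
    structure(track, class = "coverage_track")
  })
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d sequence(s), %.0f bases, mean depth %.1f\n",
              length(x), sum(lengths(x)),
              sum(vapply(x, function(v) sum(as.numeric(v)), 0)) /
                max(1, sum(lengths(x)))))
  invisible(x)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal depth are collapsed into single intervals (0-based
#' half-open, per the format standard).
#' @param track a `coverage_track`.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  parts <- lapply(names(track), function(chrom) {
    r <- rle(track[[chrom]])
    end <- cumsum(r$lengths)
    data.table::data.table(chrom = chrom, start = end - r$lengths,
                           end = end, depth = r$values)
  })
  data.table::fwrite(data.table::rbindlist(parts), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a per-base depth track
#'
#' Accepts bedGraph (4 columns: chrom, 0-based start, end, depth) or a
#' 3-column per-base TSV (chrom, 1-based position, depth) and expands to a
#' per-base `coverage_track`.  Positions not covered by any interval get
#' depth 0.
#'
#' @param path input file.
#' @param chrom_lengths named lengths (or `sc_reference`); defaults to the
#'   maximum covered coordinate per chromosome.
#' @return a `coverage_track`.
#' @export
read_depth <- function(path, chrom_lengths = NULL) {
  dt <- data.table::fread(path, header = FALSE)
  check_that(ncol(dt) %in% c(3L, 4L),
             "depth file must have 3 (TSV) or 4 (bedGraph) columns")
  if (!is.null(chrom_lengths)) chrom_lengths <- reference_lengths(chrom_lengths)
  track <- list()
  if (ncol(dt) == 4L) {
    names(dt) <- c("chrom", "start", "end", "depth")
    for (chrom in unique(dt$chrom)) {
      s <- dt[dt$chrom == chrom, ]
      L <- if (!is.null(chrom_lengths)) chrom_lengths[[chrom]] else max(s$end)
      d <- integer(L)
      for (i in seq_len(nrow(s))) {
        if (s$start[i] + 1L <= L) {
          d[(s$start[i] + 1L):min(L, s$end[i])] <- s$depth[i]
        }
      }
      track[[chrom]] <- d
    }
  } else {
    names(dt) <- c("chrom", "pos", "depth")
    for (chrom in unique(dt$chrom)) {
      s <- dt[dt$chrom == chrom, ]
      L <- if (!is.null(chrom_lengths)) chrom_lengths[[chrom]] else max(s$pos)
      d <- integer(L)
      d[s$pos] <- s$depth
      track[[chrom]] <- d
    }
  }
  if (!is.null(chrom_lengths)) {
    for (chrom in setdiff(names(chrom_lengths), names(track))) {
      track[[chrom]] <- integer(chrom_lengths[[chrom]])
    }
    track <- track[names(chrom_lengths)]
  }
  structure(track, class = "coverage_track")
}
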