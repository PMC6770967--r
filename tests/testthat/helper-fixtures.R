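# shared in-code fixtures and independent oracles

# coverage track from plain vectors
make_track <- function(...) {
  structure(lapply(list(...), as.integer), class = "coverage_track")
}

# biallelic variant table from parallel vectors of ref/alt depths
make_variants <- function(ad_ref, ad_alt, chrom = "chr1",
                          pos = seq_along(ad_ref), ref = "A", alt = "T") {
  n <- length(ad_ref)
  variant_table(chrom = rep_len(chrom, n), pos = pos,
                ref = rep_len(ref, n), alt = rep_len(alt, n),
                dp = ad_ref + ad_alt,
                ad = lapply(seq_len(n), function(i) c(ad_ref[i], ad_alt[i])))
}

# single-segment copy map over one chromosome
one_segment_map <- function(len, k, chrom = "chr1") {
  plant_copy_map(setNames(len, chrom),
                 segments = data.frame(chrom = chrom, start = 1,
                                       end = len, k = k))
}

# hand-built single-gene reference: one chromosome, one plus- or
# minus-strand gene with the given CDS (given 5'->3' on the gene strand)
gene_fixture <- function(cds, strand = "+", pad = 30L, seed = 42) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  glen <- nchar(cds)
  genomic <- if (strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  } else cds
  chrom_seq <- paste0(paste(sample(bases, pad, replace = TRUE), collapse = ""),
                      genomic,
                      paste(sample(bases, pad, replace = TRUE), collapse = ""))
  list(sequences = Biostrings::DNAStringSet(c(chr1 = chrom_seq)),
       cds = data.frame(gene_id = "g1", chrom = "chr1", start = pad + 1L,
                        end = pad + glen, strand = strand,
                        stringsAsFactors = FALSE),
       start = pad + 1L, end = pad + glen)
}

# independent effect oracle: rebuild the full mutant CDS and translate it.
# Only valid for SNVs inside the CDS of a gene_fixture().
oracle_snv_effect <- function(fix, pos, alt) {
  chrom_seq <- as.character(fix$sequences[[1]])
  mutant <- chrom_seq
  substr(mutant, pos, pos) <- alt
  get_prot <- function(s) {
    cds <- substr(s, fix$start, fix$end)
    if (fix$cds$strand == "-") {
      cds <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    }
    strsplit(as.character(
      Biostrings::translate(Biostrings::DNAString(cds),
                            no.init.codon = TRUE)), "")[[1]]
  }
  p0 <- get_prot(chrom_seq); p1 <- get_prot(mutant)
  changed <- which(p0 != p1)
  if (length(changed) == 0) "synonymous"
  else if (any(p1[changed] == "*")) "stop_gain"
  else "missense"
}

# independent zygosity oracle: literal transcription of the rule
oracle_zygosity <- function(ad, dp, r_min = 5, f_min = 0.05) {
  dom <- max(ad)
  dom_idx <- which(ad == dom)[1]
  others <- ad[-dom_idx]
  if (any(others >= r_min & others / dp >= f_min)) "deviating_frequency"
  else "homozygous"
}

# independent zero-coverage oracle: naive linear scan
oracle_zero_regions <- function(depth, L_min) {
  out <- NULL
  run_start <- NA
  for (i in seq_along(depth)) {
    if (depth[i] == 0) {
      if (is.na(run_start)) run_start <- i
    } else if (!is.na(run_start)) {
      if (i - run_start > L_min) out <- rbind(out, c(run_start, i - 1L))
      run_start <- NA
    }
  }
  if (!is.na(run_start) && length(depth) - run_start + 1L > L_min) {
    out <- rbind(out, c(run_start, length(depth)))
  }
  out
}

# independent exact Mann-Whitney oracle: enumerate all group labelings
oracle_mwu <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(N, n1)
  Us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  eps <- 1e-9
  p <- min(1, 2 * min(mean(Us <= U_obs + eps), mean(Us >= U_obs - eps)))
  list(U = U_obs, p = p)
}
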