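#' Specify a synthetic culture genome
#'
#' Describes the stand-in reference genome from which a truth-labelled
#' aneuploid culture genome is simulated: nuclear chromosome lengths, the
#' number of single-exon protein-coding genes to place, gene and intergenic
#' length ranges, strandedness, nucleotide composition, and optional small
#' organelle replicons (a plastome and a chondrome stand-in) whose depth is
#' controlled independently of the nuclear copy map.
#'
#' Every gene carries one CDS spanning the full gene body whose length is a
#' positive multiple of 3, beginning with a start codon and ending with a
#' stop codon (strand-aware).  Genes never overlap.
#'
#' @param chrom_lengths named integer vector of nuclear chromosome lengths
#'   in bp (names become sequence ids).
#' @param n_genes number of genes to place across nuclear chromosomes,
#'   proportional to chromosome length.
#' @param gene_length_range length-2 vector, min/max gene (= CDS) length in
#'   bp; lengths are rounded down to multiples of 3 (minimum 9 bp:
#'   start + one codon + stop).
#' @param intergenic_range length-2 vector, min/max intergenic spacer in bp.
#' @param strand_prob probability that a gene lies on the plus strand.
#' @param base_probs named probabilities for A/C/G/T in intergenic sequence
#'   (default approximates the ~36\% GC of the A. thaliana nuclear genome).
#' @param organelles logical; append `"plastome"` and `"chondrome"`
#'   replicons (no genes) so organelle depth ratios can be simulated.
#' @param organelle_lengths named lengths of the organelle stand-ins.
#' @param seed integer seed recorded in the spec and used by
#'   [generate_reference()].
#'
#' @return an object of class `genome_spec`.
#' @export
#' @examples
#' spec <- genome_spec(c(chr1 = 50000), n_genes = 5, seed = 1)
#' ref <- generate_reference(spec)
#' ref$genes
genome_spec <- function(chrom_lengths,
                        n_genes,
                        gene_length_range = c(300L, 3000L),
                        intergenic_range = c(200L, 2000L),
                        strand_prob = 0.5,
                        base_probs = c(A = 0.32, C = 0.18, G = 0.18, T = 0.32),
                        organelles = FALSE,
                        organelle_lengths = c(plastome = 20000L,
                                              chondrome = 35000L),
                        seed = NULL) {
  check_that(length(chrom_lengths) >= 1 && all(chrom_lengths >= 1),
             "all chromosome lengths must be positive")
  check_that(!is.null(names(chrom_lengths)) && !anyNA(names(chrom_lengths)) &&
               !anyDuplicated(names(chrom_lengths)),
             "chrom_lengths must have unique names")
  check_that(n_genes >= 0, "n_genes must be non-negative")
  check_that(length(gene_length_range) == 2 &&
               gene_length_range[1] >= 9 && diff(gene_length_range) >= 0,
             "gene_length_range must be [min >= 9, max]")
  check_that(length(intergenic_range) == 2 && intergenic_range[1] >= 1,
             "intergenic_range must be [min >= 1, max]")
  check_that(strand_prob >= 0 && strand_prob <= 1, "strand_prob in [0,1]")
  check_that(setequal(names(base_probs), c("A", "C", "G", "T")) &&
               all(base_probs >= 0) && sum(base_probs) > 0,
             "base_probs must be named A/C/G/T non-negative weights")
  structure(list(
    chrom_lengths = setNames(as.integer(chrom_lengths), names(chrom_lengths)),
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    intergenic_range = as.integer(intergenic_range),
    strand_prob = strand_prob,
    base_probs = base_probs[c("A", "C", "G", "T")] / sum(base_probs),
    organelles = isTRUE(organelles),
    organelle_lengths = setNames(as.integer(organelle_lengths),
                                 names(organelle_lengths)),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "genome_spec")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# all 61 sense codons (used for CDS interiors)
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, STOP_CODONS)
}

# random CDS of n_codons codons: ATG + sense codons + stop
random_cds <- function(n_codons) {
  stopifnot(n_codons >= 3)
  paste0("ATG",
         paste(sample(sense_codons(), n_codons - 2L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

#' Generate a synthetic reference genome and gene annotation
#'
#' Builds random chromosome sequences, packs non-overlapping single-exon
#' genes (one CDS per gene, multiple-of-3 length, start/stop codons,
#' strand-aware), and returns both in memory.  Use [write_reference()] to
#' emit FASTA and GFF3.  Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [genome_spec()].
#' @return an object of class `sc_reference`: a list with `sequences`
#'   (a [Biostrings::DNAStringSet]), `genes` (data.frame with gene_id,
#'   chrom, start, end, strand; 1-based closed), `organelles` (character
#'   vector of organelle sequence ids) and `spec`.
#' @export
generate_reference <- function(spec) {
  check_that(inherits(spec, "genome_spec"), "spec must be a genome_spec")
  with_seed(spec$seed %||% NULL, {
    lens <- spec$chrom_lengths
    # distribute genes proportional to chromosome length (largest remainder)
    share <- lens / sum(lens) * spec$n_genes
    n_per <- floor(share)
    rem <- spec$n_genes - sum(n_per)
    if (rem > 0) {
      ord <- order(share - n_per, decreasing = TRUE)
      n_per[ord[seq_len(rem)]] <- n_per[ord[seq_len(rem)]] + 1L
    }

    bases <- c("A", "C", "G", "T")
    seqs <- character(0)
    genes <- list()
    gi <- 0L
    for (chrom in names(lens)) {
      L <- lens[[chrom]]
      chars <- sample(bases, L, replace = TRUE, prob = spec$base_probs)
      ng <- n_per[[chrom]]
      if (ng > 0) {
        pos <- 1L
        for (j in seq_len(ng)) {
          gap <- sample(spec$intergenic_range[1]:spec$intergenic_range[2], 1L)
          glen_raw <- sample(spec$gene_length_range[1]:spec$gene_length_range[2], 1L)
          glen <- max(9L, (glen_raw %/% 3L) * 3L)
          start <- pos + gap
          end <- start + glen - 1L
          if (end > L) {
            stop(sprintf(paste0("cannot fit %d genes on %s (%d bp): gene %d ",
                                "would end at %d"), ng, chrom, L, j, end),
                 call. = FALSE)
          }
          strand <- if (runif(1) < spec$strand_prob) "+" else "-"
          cds <- random_cds(glen %/% 3L)
          if (strand == "-") {
            cds <- as.character(
              Biostrings::reverseComplement(Biostrings::DNAString(cds)))
          }
          chars[start:end] <- strsplit(cds, "", fixed = TRUE)[[1]]
          gi <- gi + 1L
          genes[[gi]] <- data.frame(
            gene_id = sprintf("g%05d", gi), chrom = chrom,
            start = start, end = end, strand = strand,
            stringsAsFactors = FALSE)
          pos <- end + 1L
        }
      }
      seqs[[chrom]] <- paste(chars, collapse = "")
    }
    organelle_ids <- character(0)
    if (spec$organelles) {
      for (org in names(spec$organelle_lengths)) {
        seqs[[org]] <- paste(
          sample(bases, spec$organelle_lengths[[org]], replace = TRUE,
                 prob = spec$base_probs), collapse = "")
        organelle_ids <- c(organelle_ids, org)
      }
    }
    genes <- if (gi > 0) do.call(rbind, genes) else data.frame(
      gene_id = character(0), chrom = character(0), start = integer(0),
      end = integer(0), strand = character(0), stringsAsFactors = FALSE)
    structure(list(
      sequences = Biostrings::DNAStringSet(seqs),
      genes = genes,
      organelles = organelle_ids,
      spec = spec
    ), class = "sc_reference")
  })
}

#' @export
print.sc_reference <- function(x, ...) {
  cat(sprintf("<sc_reference> %d sequence(s), %d gene(s)%s\n",
              length(x$sequences), nrow(x$genes),
              if (length(x$organelles))
                paste0(", organelles: ",
                       paste(x$organelles, collapse = ", ")) else ""))
  invisible(x)
}

#' Sequence lengths of a reference (named integer vector)
#' @param ref an `sc_reference` or a named vector of lengths.
#' @export
reference_lengths <- function(ref) {
  if (inherits(ref, "sc_reference")) {
    setNames(Biostrings::width(ref$sequences), names(ref$sequences))
  } else {
    check_that(is.numeric(ref) && !is.null(names(ref)),
               "need an sc_reference or named lengths")
    ref
  }
}

#' Write reference FASTA and GFF3
#'
#' GFF3 carries gene, mRNA and CDS features (one transcript per gene, CDS
#' phase 0), 1-based coordinates per the format standard.
#'
#' @param ref an `sc_reference`.
#' @param fasta,gff output paths.
#' @return invisibly, a list with the two paths.
#' @export
write_reference <- function(ref, fasta, gff) {
  check_that(inherits(ref, "sc_reference"), "ref must be an sc_reference")
  Biostrings::writeXStringSet(ref$sequences, filepath = fasta, width = 80L)
  lens <- reference_lengths(ref)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(lens), lens))
  g <- ref$genes
  if (nrow(g) > 0) {
    feature_lines <- unlist(lapply(seq_len(nrow(g)), function(i) {
      id <- g$gene_id[i]
      base <- sprintf("%s\tsomaclone\t%%s\t%d\t%d\t.\t%s\t%%s\t%%s",
                      g$chrom[i], g$start[i], g$end[i], g$strand[i])
      c(sprintf(base, "gene", ".", sprintf("ID=%s", id)),
        sprintf(base, "mRNA", ".", sprintf("ID=%s.1;Parent=%s", id, id)),
        sprintf(base, "CDS", "0",
                sprintf("ID=%s.1.cds;Parent=%s.1", id, id)))
    }))
    lines <- c(lines, feature_lines)
  }
  writeLines(lines, gff)
  invisible(list(fasta = fasta, gff = gff))
}

#' Read a gene/CDS annotation from GFF3
#'
#' Uses rtracklayer for parsing, then reduces the annotation to the gene
#' table this package works with: one row per gene with its CDS span(s).
#' Multi-part CDS chains are retained as multiple rows in the `cds`
#' component (ordered 5' to 3' on the genome).
#'
#' @param path GFF3 file.
#' @return list with `genes` (gene_id, chrom, start, end, strand) and
#'   `cds` (gene_id, chrom, start, end, strand), both 1-based closed.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  types <- as.character(df$type)
  gene_rows <- df[types == "gene", , drop = FALSE]
  cds_rows <- df[types == "CDS", , drop = FALSE]
  gene_id_of <- function(rows) {
    id <- as.character(rows$ID)
    # CDS rows: resolve via Parent (mRNA id "gene.1" -> "gene")
    if (!nrow(rows)) return(character(0))
    id
  }
  genes <- data.frame(
    gene_id = as.character(gene_rows$ID),
    chrom = as.character(gene_rows$seqnames),
    start = gene_rows$start, end = gene_rows$end,
    strand = as.character(gene_rows$strand), stringsAsFactors = FALSE)
  parent <- if (nrow(cds_rows)) {
    vapply(cds_rows$Parent, function(p) sub("\\.1$", "", p[1]), "")
  } else character(0)
  cds <- data.frame(
    gene_id = parent,
    chrom = as.character(cds_rows$seqnames),
    start = cds_rows$start, end = cds_rows$end,
    strand = as.character(cds_rows$strand), stringsAsFactors = FALSE)
  cds <- cds[order(cds$gene_id, cds$start), , drop = FALSE]
  list(genes = genes, cds = cds)
}
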