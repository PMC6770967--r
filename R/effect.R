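#' Simplified variant effect annotation
#'
#' A deliberately small effect model (a stand-in for full annotators such
#' as SnpEff): one transcript per gene, CDS-only effects.  An SNV inside a
#' CDS is translated in its codon context, strand-aware, under the standard
#' genetic code: a newly introduced stop codon is `stop_gain`, any other
#' amino-acid change `missense` (including loss of an existing stop, which
#' full annotators report separately), an unchanged amino acid
#' `synonymous`.  An InDel overlapping a CDS is `frameshift` when the
#' inserted/deleted length is not a multiple of 3, else `inframe_indel`.
#' Variants touching no CDS are `noncoding`.  Impact is `high` exactly for
#' stop_gain and frameshift.
#'
#' Affected reference span conventions: SNV = its base; deletion = the
#' deleted bases (excluding the anchor base of the VCF representation);
#' insertion = the anchor base only.
#'
#' For multi-allelic records every alternative allele is annotated and the
#' record row reports the most severe (high > moderate > low > none).
#'
#' @param variants a `variant_table`.
#' @param annotation list with a `cds` data.frame (gene_id, chrom, start,
#'   end, strand) as returned by [read_annotation()], or an
#'   `sc_reference` (whose genes are single-CDS).
#' @param sequences reference sequences ([Biostrings::DNAStringSet] or an
#'   `sc_reference`).
#' @return data.frame: chrom, pos, ref, alt (the annotated allele),
#'   gene_id (NA if noncoding), effect, impact — one row per variant
#'   record, `variant_table` order.
#' @export
annotate_effect <- function(variants, annotation, sequences) {
  if (inherits(sequences, "sc_reference")) sequences <- sequences$sequences
  cds <- effect_cds_table(annotation)
  models <- build_cds_models(cds, sequences)
  cds_gr <- GenomicRanges::GRanges(cds$chrom,
                                   IRanges::IRanges(cds$start, cds$end))
  n <- nrow(variants)
  if (n == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene_id = character(0), effect = character(0),
                      impact = character(0), stringsAsFactors = FALSE))
  }

  # verify ref alleles against the genome, one string conversion per chrom
  for (chrom in unique(variants$chrom)) {
    sel <- which(variants$chrom == chrom)
    cs <- as.character(sequences[[chrom]])
    obs <- substring(cs, variants$pos[sel],
                     variants$pos[sel] + nchar(variants$ref[sel]) - 1L)
    bad <- which(obs != variants$ref[sel])
    check_that(length(bad) == 0,
               "reference allele mismatch at %s:%d (%s vs genome %s)",
               chrom, variants$pos[sel][bad[1]],
               variants$ref[sel][bad[1]], obs[bad[1]])
  }

  # expand multi-allelic records to one row per alternative allele
  alt_list <- strsplit(variants$alt, ",", fixed = TRUE)
  idx <- rep.int(seq_len(n), lengths(alt_list))
  alt <- unlist(alt_list, use.names = FALSE)
  pos <- variants$pos[idx]
  ref <- variants$ref[idx]
  rl <- nchar(ref); al <- nchar(alt)
  span_start <- ifelse(al < rl, pos + 1L, pos)
  span_end <- ifelse(al > rl, pos, pos + rl - 1L)
  q <- GenomicRanges::GRanges(variants$chrom[idx],
                              IRanges::IRanges(span_start, span_end))
  hit <- GenomicRanges::findOverlaps(q, cds_gr, select = "first")

  gene_id <- ifelse(is.na(hit), NA_character_, cds$gene_id[hit])
  effect <- character(length(idx))
  effect[is.na(hit)] <- "noncoding"
  is_indel <- !is.na(hit) & rl != al
  effect[is_indel] <- ifelse(abs(rl - al)[is_indel] %% 3L != 0L,
                             "frameshift", "inframe_indel")
  is_mnv <- !is.na(hit) & rl == al & rl > 1L
  effect[is_mnv] <- "missense"   # multi-base substitution: not codon-modelled
  for (j in which(!is.na(hit) & rl == al & rl == 1L)) {
    snv <- snv_effect(models[[gene_id[j]]], pos[j], alt[j])
    if (is.na(snv)) {             # fell in a CDS gap of a multi-part chain
      gene_id[j] <- NA_character_
      effect[j] <- "noncoding"
    } else {
      effect[j] <- snv
    }
  }
  impact <- unname(c(stop_gain = "high", frameshift = "high",
                     missense = "moderate", inframe_indel = "moderate",
                     synonymous = "low", noncoding = "none")[effect])

  # collapse back to one row per record: keep the most severe allele
  sev <- c(none = 0, low = 1, moderate = 2, high = 3)[impact]
  ord <- order(idx, -sev)
  first <- !duplicated(idx[ord])
  keep <- ord[first]
  data.frame(chrom = variants$chrom[idx[keep]], pos = pos[keep],
             ref = ref[keep], alt = alt[keep], gene_id = gene_id[keep],
             effect = effect[keep], impact = impact[keep],
             stringsAsFactors = FALSE)
}

# effect of a single-base substitution inside a gene's CDS model
snv_effect <- function(model, pos, alt) {
  rel <- cds_relative_pos(model, pos)
  if (is.na(rel)) return(NA_character_)
  base_new <- if (model$strand == "-") COMPLEMENT[[alt]] else alt
  codon_i <- (rel - 1L) %/% 3L
  within <- (rel - 1L) %% 3L + 1L
  codon_old <- substr(model$cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  codon_new <- codon_old
  substr(codon_new, within, within) <- base_new
  aa_old <- GENETIC_CODE_TABLE[[codon_old]]
  aa_new <- GENETIC_CODE_TABLE[[codon_new]]
  if (aa_new == "*" && aa_old != "*") "stop_gain"
  else if (aa_new != aa_old) "missense"
  else "synonymous"
}

# normalise annotation input to a cds data.frame
effect_cds_table <- function(annotation) {
  if (inherits(annotation, "sc_reference")) {
    g <- annotation$genes
    return(data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
                      end = g$end, strand = g$strand,
                      stringsAsFactors = FALSE))
  }
  if (is.list(annotation) && !is.null(annotation$cds)) return(annotation$cds)
  check_that(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                   names(annotation)), "invalid CDS annotation")
  annotation
}

# per-gene CDS model: ordered parts + strand-oriented CDS sequence
build_cds_models <- function(cds, sequences) {
  models <- list()
  for (gid in unique(cds$gene_id)) {
    parts <- cds[cds$gene_id == gid, , drop = FALSE]
    parts <- parts[order(parts$start), , drop = FALSE]
    seq_parts <- vapply(seq_len(nrow(parts)), function(j) {
      as.character(Biostrings::subseq(sequences[[parts$chrom[j]]],
                                      parts$start[j], parts$end[j]))
    }, "")
    cds_seq <- paste(seq_parts, collapse = "")
    strand <- parts$strand[1]
    if (strand == "-") {
      cds_seq <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(cds_seq)))
    }
    models[[gid]] <- list(parts = parts, strand = strand, cds_seq = cds_seq)
  }
  models
}

# genomic position -> 1-based position within the strand-oriented CDS
cds_relative_pos <- function(model, pos) {
  parts <- model$parts
  plus_off <- 0L
  rel <- NA_integer_
  for (j in seq_len(nrow(parts))) {
    if (pos >= parts$start[j] && pos <= parts$end[j]) {
      rel <- plus_off + (pos - parts$start[j] + 1L)
      break
    }
    plus_off <- plus_off + (parts$end[j] - parts$start[j] + 1L)
  }
  if (is.na(rel)) return(NA_integer_)
  if (model$strand == "-") nchar(model$cds_seq) - rel + 1L else rel
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# standard genetic code as a plain lookup (fast path for per-SNV translation)
GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

#' Genes hit by at least one high-impact variant
#'
#' @param effects output of [annotate_effect()].
#' @return list with `genes` (sorted unique gene ids) and `count`.
#' @export
genes_with_high_impact <- function(effects) {
  g <- sort(unique(effects$gene_id[effects$impact == "high" &
                                     !is.na(effects$gene_id)]))
  list(genes = g, count = length(g))
}
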