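#' Build a pipeline run configuration
#'
#' One object holding every tunable of the analysis, with defaults equal to
#' the study's stated values where one exists (5 reads / 5\% zygosity
#' bounds, 2 kb flank, 20\% deviation, 100 bp zero-coverage minimum,
#' 100 kb density blocks, per-copy unit 50) and documented gap-filling
#' choices elsewhere.  The default simulation describes a 5 Mbp
#' two-chromosome nuclear genome with 300 genes, copy states {0,1,2,3,5}
#' and organelle stand-ins.
#'
#' @param outdir output directory for all stage files.
#' @param seed integer master seed; each stage derives its own sub-seed.
#' @param chrom_lengths,n_genes,organelles simulated genome shape.
#' @param seg_mean_len,k_values,k_weights copy-map randomisation.
#' @param c_unit,noise_family,dispersion depth noise model.
#' @param snv_rate,indel_rate,carrier_rule variant planting.
#' @param rna_depth RNA reads per expressed variant site.
#' @param r_min,f_min,flank,max_dev zygosity/filter thresholds.
#' @param L_min zero-coverage minimum length (strict).
#' @param block_size variant-density block (bp).
#' @param tau flanking-similarity relative tolerance.
#' @param k_max copy-number clamp.
#' @param window coverage overview window (bp).
#' @param exact_limit Mann-Whitney exact-enumeration limit.
#' @param min_rna_depth minimum RNA depth for an ASE record.
#' @return object of class `run_config`.
#' @export
run_config <- function(outdir = tempfile("somaclone_run_"),
                       seed = 1L,
                       chrom_lengths = c(chr1 = 3e6, chr2 = 2e6),
                       n_genes = 300L,
                       organelles = TRUE,
                       seg_mean_len = 4e5,
                       k_values = c(0L, 1L, 2L, 3L, 5L),
                       k_weights = c(0.02, 0.15, 0.13, 0.50, 0.20),
                       c_unit = 50,
                       noise_family = "poisson",
                       dispersion = 10,
                       snv_rate = 5e-4,
                       indel_rate = 5e-4,
                       carrier_rule = "single",
                       rna_depth = 300,
                       r_min = 5L, f_min = 0.05, flank = 2000L,
                       max_dev = 0.20,
                       L_min = 100L,
                       block_size = 100000L,
                       tau = 0.2,
                       k_max = 8L,
                       window = 10000L,
                       exact_limit = 10L,
                       min_rna_depth = 10L) {
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              chrom_lengths = chrom_lengths, n_genes = as.integer(n_genes),
              organelles = isTRUE(organelles),
              seg_mean_len = seg_mean_len, k_values = k_values,
              k_weights = k_weights, c_unit = c_unit,
              noise_family = noise_family, dispersion = dispersion,
              snv_rate = snv_rate, indel_rate = indel_rate,
              carrier_rule = carrier_rule, rna_depth = rna_depth,
              r_min = as.integer(r_min), f_min = f_min,
              flank = as.integer(flank), max_dev = max_dev,
              L_min = as.integer(L_min),
              block_size = as.integer(block_size), tau = tau,
              k_max = as.integer(k_max), window = as.integer(window),
              exact_limit = as.integer(exact_limit),
              min_rna_depth = as.integer(min_rna_depth))
  # reuse the type constructors for validation
  zygosity_thresholds(cfg$r_min, cfg$f_min, cfg$flank, cfg$max_dev)
  check_that(cfg$L_min >= 1 && cfg$block_size >= 1 && cfg$tau > 0 &&
               cfg$k_max >= 1 && cfg$window >= 1,
             "invalid threshold configuration")
  structure(cfg, class = "run_config")
}

#' Serialise / restore a run configuration (lossless JSON round trip)
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)  # keep names in JSON
  jsonlite::write_json(cfg, path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$chrom_lengths <- unlist(raw$chrom_lengths)
  raw$k_weights <- as.numeric(raw$k_weights)
  do.call(run_config, raw)
}

#' Run the full analysis pipeline on a simulated culture genome
#'
#' Orchestrates simulate -> coverage/ploidy -> zygosity -> effects/InDel
#' frames -> allele-specific expression, writes every stage output under
#' `config$outdir` (FASTA, GFF3, bedGraph, VCF, BED, TSV, JSON) and
#' returns a consolidated run report with a cross-stage conservation
#' ledger.  Rerunning with an identical configuration and seed reproduces
#' all output files byte-identically (no timestamps are embedded).
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return object of class `run_report` (also written as `report.json`
#'   and `report.txt` in the output directory).
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  check_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  path <- function(f) file.path(config$outdir, f)
  say("somaclone pipeline: seed %d, outdir %s", config$seed, config$outdir)
  say("thresholds: r_min=%d f_min=%.2f flank=%d max_dev=%.2f L_min=%d",
      config$r_min, config$f_min, config$flank, config$max_dev,
      config$L_min)

  ## stage 1: simulate ------------------------------------------------------
  spec <- genome_spec(config$chrom_lengths, config$n_genes,
                      organelles = config$organelles,
                      seed = derive_seed(config$seed, "reference"))
  ref <- generate_reference(spec)
  write_reference(ref, path("genome.fasta"), path("annotation.gff3"))
  nuclear <- setdiff(names(reference_lengths(ref)), ref$organelles)
  cm <- plant_copy_map(reference_lengths(ref)[nuclear],
                       seg_mean_len = config$seg_mean_len,
                       k_values = config$k_values,
                       k_weights = config$k_weights,
                       k_max = config$k_max,
                       seed = derive_seed(config$seed, "copy_map"))
  write_copy_bed(cm, path("copy_map.bed"))
  noise <- noise_model(c = config$c_unit, family = config$noise_family,
                       dispersion = config$dispersion,
                       rna_depth = config$rna_depth)
  track <- simulate_coverage(cm, noise, reference_lengths(ref),
                             organelles = ref$organelles,
                             seed = derive_seed(config$seed, "coverage"))
  write_bedgraph(track, path("coverage.bedgraph"))
  truth <- plant_variants(ref, cm, snv_rate = config$snv_rate,
                          indel_rate = config$indel_rate,
                          carrier_rule = config$carrier_rule,
                          seed = derive_seed(config$seed, "variants"))
  write_truth_tsv(truth, path("truth_variants.tsv"))
  variants <- emit_vcf(truth, track,
                       seed = derive_seed(config$seed, "vcf"))
  write_vcf(variants, path("variants.vcf"), reference_lengths(ref),
            seed = config$seed)
  rna <- simulate_rna_counts(truth, rna_depth = config$rna_depth,
                             seed = derive_seed(config$seed, "rna"))
  write_rna_counts(rna, path("rna_counts.tsv"))
  say("simulated: %d genes, %d segments, %d truth variants",
      nrow(ref$genes), nrow(cm), nrow(truth))

  ## stage 2: coverage / ploidy --------------------------------------------
  gd <- gene_mean_depths(track, ref$genes)
  baseline <- estimate_ploidy_baseline(gd$mean_depth)
  gd$k_hat <- classify_gene_copy_number(gd$mean_depth, baseline,
                                        k_max = config$k_max)
  gd <- flag_flanking_similarity(gd, tau = config$tau)
  data.table::fwrite(gd, path("gene_copy_estimates.tsv"), sep = "\t")
  nuclear_track <- track[nuclear]
  class(nuclear_track) <- "coverage_track"
  zcr <- find_zero_coverage_regions(nuclear_track, L_min = config$L_min)
  write_zero_regions_bed(zcr, path("zero_coverage.bed"))
  wc <- windowed_mean_coverage(nuclear_track, config$window)
  data.table::fwrite(wc, path("window_coverage.tsv"), sep = "\t")
  org_ratio <- if (length(ref$organelles) >= 2) {
    organelle_coverage_ratio(track, "chondrome", "plastome")
  } else NULL
  say("coverage: unit c = %.2f, %d zero-coverage regions", baseline$c,
      nrow(zcr))

  ## stage 3: zygosity ------------------------------------------------------
  thr <- zygosity_thresholds(config$r_min, config$f_min, config$flank,
                             config$max_dev)
  usable <- variants[variants$dp > 0, , drop = FALSE]
  n_zero_dp <- nrow(variants) - nrow(usable)
  filt <- coverage_deviation_filter(usable, track, thr)
  pass <- usable[filt$status == "pass", , drop = FALSE]
  classes <- classify_zygosity(pass, thr)
  dens <- variant_density(pass, classes, config$block_size,
                          reference_lengths(ref)[nuclear])
  data.table::fwrite(dens, path("variant_density.tsv"), sep = "\t")
  snvs <- pass[variant_type(pass) == "SNV", , drop = FALSE]
  spectrum <- if (nrow(snvs)) {
    substitution_spectrum(snvs)
  } else NULL
  ratio <- snv_indel_ratio(pass)
  cov_hist <- if (nrow(pass)) {
    coverage_histogram_at_variants(pass, track, classes)
  } else NULL
  write_vcf(pass, path("variants_classified.vcf"),
            reference_lengths(ref), seed = config$seed,
            info = sprintf("ZYG=%s", classes))
  # deviating fraction on both denominators (the filter ordering is not
  # fully specified by the source analysis, so report both)
  classes_all <- classify_zygosity(usable, thr)
  say("zygosity: %d/%d pass filter, %.1f%% deviating", nrow(pass),
      nrow(usable),
      100 * mean(classes == "deviating_frequency"))

  ## stage 4: effects / InDel frames ---------------------------------------
  effects <- annotate_effect(pass, ref, ref$sequences)
  data.table::fwrite(effects, path("effects.tsv"), sep = "\t")
  hi <- genes_with_high_impact(effects)
  genome_len <- sum(reference_lengths(ref)[nuclear])
  frames <- indel_frame_analysis(pass, ref, genome_len)
  say("effects: %d high-impact genes; %d/%d InDels inside CDS",
      hi$count, frames$n_inside, frames$n_total)

  ## stage 5: allele-specific expression ------------------------------------
  ase <- collect_ase(pass, effects, rna,
                     min_rna_depth = config$min_rna_depth)
  data.table::fwrite(as.data.frame(ase), path("ase_records.tsv"),
                     sep = "\t")
  contrast <- if (nrow(ase) >= 2) {
    ase_contrast(ase, exact_limit = config$exact_limit)
  } else NULL
  say("ase: %d records", nrow(ase))

  ## report ------------------------------------------------------------------
  cfg_path <- write_config(config, path("config.json"))
  report <- structure(list(
    version = as.character(packageVersion("somaclone")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    counts = list(
      genes = nrow(ref$genes),
      copy_segments = nrow(cm),
      truth_variants = nrow(truth),
      vcf_records = nrow(variants),
      zero_depth_records = n_zero_dp,
      variants_filtered = sum(filt$status != "pass"),
      variants_pass = nrow(pass),
      homozygous = sum(classes == "homozygous"),
      deviating_frequency = sum(classes == "deviating_frequency"),
      zero_coverage_regions = nrow(zcr),
      high_impact_genes = hi$count,
      high_impact_variants = sum(effects$impact == "high"),
      ase_records = nrow(ase),
      gene_copy_classes = as.list(table(gd$k_hat))),
    stats = list(
      baseline_c = baseline$c,
      baseline_low_confidence = baseline$low_confidence,
      frac_similar_to_flanking = mean(gd$similar_to_flanking, na.rm = TRUE),
      organelle_ratio = if (!is.null(org_ratio)) org_ratio$ratio
                        else NA_real_,
      deviating_fraction_pass = if (nrow(pass))
        mean(classes == "deviating_frequency") else NA_real_,
      deviating_fraction_prefilter = if (nrow(usable))
        mean(classes_all == "deviating_frequency") else NA_real_,
      snv_indel_ratio = ratio,
      cg_to_at_share = if (!is.null(spectrum)) spectrum$cg_to_at_share
                       else NA_real_,
      coverage_mode_homozygous = if (!is.null(cov_hist))
        cov_hist$mode[["homozygous"]] else NA_real_,
      coverage_mode_deviating = if (!is.null(cov_hist))
        cov_hist$mode[["deviating_frequency"]] else NA_real_,
      frac_div3_inside = frames$frac_div3_inside,
      frac_div3_outside = frames$frac_div3_outside,
      indel_density_ratio = frames$density_ratio,
      frame_test_p = frames$test$p_value,
      ase_rna_p = if (!is.null(contrast)) contrast$rna_test$p_value
                  else NA_real_,
      ase_genomic_p = if (!is.null(contrast))
        contrast$genomic_test$p_value else NA_real_,
      ase_rna_alt_share = if (!is.null(contrast)) contrast$rna_alt_share
                          else NA_real_),
    conservation = list(
      variants_in = nrow(usable),
      filtered_plus_classified_equals_in =
        sum(filt$status != "pass") + nrow(pass) == nrow(usable),
      classified_equals_hom_plus_dev =
        sum(classes == "homozygous") +
          sum(classes == "deviating_frequency") == nrow(pass),
      effects_cover_pass = nrow(effects) == nrow(pass),
      ase_subset_of_high_impact =
        nrow(ase) <= sum(effects$impact == "high"))
  ), class = "run_report")
  jsonlite::write_json(unclass(report), path("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(utils::capture.output(print(report)), path("report.txt"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("somaclone run report (version ", x$version, ", seed ", x$seed,
      ")\n", sep = "")
  cat("counts:\n")
  for (nm in names(x$counts)) {
    v <- x$counts[[nm]]
    if (is.list(v)) v <- paste(names(v), unlist(v), sep = ":",
                               collapse = " ")
    cat(sprintf("  %-28s %s\n", nm, paste(v, collapse = " ")))
  }
  cat("stats:\n")
  for (nm in names(x$stats)) {
    v <- x$stats[[nm]]
    if (is.list(v)) v <- paste(names(v), unlist(v), sep = ":",
                               collapse = " ")
    cat(sprintf("  %-28s %s\n", nm,
                paste(format(v, digits = 4), collapse = " ")))
  }
  cat("conservation:\n")
  for (nm in names(x$conservation)) {
    cat(sprintf("  %-38s %s\n", nm, x$conservation[[nm]]))
  }
  invisible(x)
}

#' Validate cross-consistency of an input file bundle
#'
#' Checks that the FASTA, GFF3, VCF and depth files describe the same
#' genome: chromosome names and lengths agree, coordinates are in range
#' and sorted, and every gene's CDS chain has a length divisible by 3.
#' Always returns a report rather than raising.
#'
#' @param fasta,gff,vcf,depth file paths (any may be NULL to skip).
#' @return list with `ok` and a data.frame `problems` (component,
#'   problem).
#' @export
validate_inputs <- function(fasta = NULL, gff = NULL, vcf = NULL,
                            depth = NULL) {
  problems <- list()
  note <- function(component, problem) {
    problems[[length(problems) + 1L]] <<- data.frame(
      component = component, problem = problem, stringsAsFactors = FALSE)
  }
  lens <- NULL
  for (p in c(fasta, gff, vcf, depth)) {
    if (!file.exists(p)) note(basename(p), "file does not exist")
  }
  if (!is.null(fasta) && file.exists(fasta)) {
    seqs <- tryCatch(Biostrings::readDNAStringSet(fasta),
                     error = function(e) NULL)
    if (is.null(seqs)) note("fasta", "unreadable FASTA") else {
      lens <- setNames(Biostrings::width(seqs),
                       sub("\\s.*$", "", names(seqs)))
    }
  }
  if (!is.null(gff) && file.exists(gff)) {
    ann <- tryCatch(read_annotation(gff), error = function(e) NULL)
    if (is.null(ann)) note("gff", "unreadable GFF3") else {
      if (!is.null(lens)) {
        bad <- setdiff(unique(ann$genes$chrom), names(lens))
        for (b in bad) note("gff", sprintf("chromosome %s absent from FASTA", b))
        inlen <- ann$genes$chrom %in% names(lens)
        over <- inlen & ann$genes$end > lens[ann$genes$chrom]
        if (any(over)) {
          note("gff", sprintf("%d gene(s) extend beyond chromosome end",
                              sum(over)))
        }
      }
      if (nrow(ann$cds)) {
        cds_len <- tapply(ann$cds$end - ann$cds$start + 1, ann$cds$gene_id,
                          sum)
        bad3 <- names(cds_len)[cds_len %% 3 != 0]
        for (b in bad3) {
          note("gff", sprintf("CDS length of %s not divisible by 3", b))
        }
      }
    }
  }
  if (!is.null(vcf) && file.exists(vcf)) {
    v <- tryCatch(suppressWarnings(read_vcf(vcf)),
                  error = function(e) NULL)
    if (is.null(v)) note("vcf", "unreadable VCF") else if (!is.null(lens)) {
      bad <- setdiff(unique(v$chrom), names(lens))
      for (b in bad) note("vcf", sprintf("chromosome %s absent from FASTA", b))
      inlen <- v$chrom %in% names(lens)
      over <- inlen & v$pos > lens[v$chrom]
      if (any(over)) {
        note("vcf", sprintf("%d record(s) beyond chromosome end", sum(over)))
      }
    }
  }
  if (!is.null(depth) && file.exists(depth)) {
    tr <- tryCatch(read_depth(depth), error = function(e) NULL)
    if (is.null(tr)) note("depth", "unreadable depth track") else if (
      !is.null(lens)) {
      for (chrom in names(tr)) {
        if (!chrom %in% names(lens)) {
          note("depth", sprintf("chromosome %s absent from FASTA", chrom))
        } else if (length(tr[[chrom]]) != lens[[chrom]]) {
          note("depth", sprintf(
            "track length %d on %s does not match FASTA length %d",
            length(tr[[chrom]]), chrom, lens[[chrom]]))
        }
      }
    }
  }
  problems <- if (length(problems)) do.call(rbind, problems) else
    data.frame(component = character(0), problem = character(0),
               stringsAsFactors = FALSE)
  list(ok = nrow(problems) == 0, problems = problems)
}
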