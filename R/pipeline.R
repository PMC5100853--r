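# Pipeline module: end-to-end orchestration with provenance-stamped TSV
# outputs, plus a fixture-free demo mode running on simulated libraries.

#' Default pipeline stage parameters
#'
#' All defaults are the analysis constants used throughout the package:
#' phred >= 20 on 100% of bases, 18-30 nt inserts, RPM > 1 in >= 6 libraries
#' for expression filtering, >= 10 mean RPM for clustering/selection, k = 5
#' expression classes, FDR <= 0.05.
#'
#' @return named list of parameters.
#' @export
pipeline_params <- function() {
  list(q_min = 20, len_min = 18, len_max = 30, max_mm = 3,
       rpm_min = 1, rpm_min_libraries = 6, cluster_rpm_min = 10,
       k = 5, max_fdr = 0.05)
}

#' Run the small-RNA pipeline end to end
#'
#' Stages: preprocess (adapter/quality/length/collapse, optional in-silico
#' depletion) -> align + priority class annotation -> isomiR classification
#' (canonical / noncanonical / NTA) -> RPM + TMM + NB-GLM differential
#' expression (mutant vs wild type at each embryonic timepoint) ->
#' expression-class clustering and subset selection.  Every stage writes a
#' provenance-stamped TSV under `out_dir`.  With an incomplete design
#' (missing sample sets), the DE and clustering stages are skipped with a
#' warning while per-library outputs are still produced.
#'
#' @param manifest data.frame with `library_id`, `genotype`, `timepoint`,
#'   `replicate`, `fastq` (paths), or the path of such a TSV.
#' @param bundle a `ReferenceBundle` (or directory written by
#'   [write_reference()]).
#' @param adapter 3' adapter sequence.
#' @param out_dir output directory.
#' @param params stage parameters, see [pipeline_params()].
#' @param blocklist optional FASTA/character of sequences to deplete.
#' @param seed recorded in output provenance (the pipeline itself is
#'   deterministic).
#' @return list with per-library results and all stage tables.
#' @export
run_pipeline <- function(manifest, bundle, adapter, out_dir,
                         params = pipeline_params(), blocklist = NULL,
                         seed = NA) {
  if (is.character(manifest)) manifest <- read_stage_tsv(manifest)
  req <- c("library_id", "genotype", "timepoint", "replicate", "fastq")
  stopifnot(all(req %in% names(manifest)))
  if (is.character(bundle)) bundle <- read_reference(bundle)
  missing_fq <- !file.exists(manifest$fastq)
  if (any(missing_fq)) {
    stop("stage preprocess: missing FASTQ input(s): ",
         paste(manifest$fastq[missing_fq], collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(params, list(seed = seed, adapter = adapter))
  log_msg <- function(...) message(sprintf("[mirmzt] %s", sprintf(...)))

  index <- build_index(bundle$genome)
  mirna <- bundle$mirna
  n_lib <- nrow(manifest)
  libs <- manifest$library_id

  counts <- list(
    canonical = matrix(0, nrow(mirna), n_lib,
                       dimnames = list(mirna$mirna_id, libs)),
    noncanonical = matrix(0, nrow(mirna), n_lib,
                          dimnames = list(mirna$mirna_id, libs)),
    nta = matrix(0, nrow(mirna), n_lib,
                 dimnames = list(mirna$mirna_id, libs))
  )
  lib_sizes <- stats::setNames(numeric(n_lib), libs)
  stats_rows <- comp_rows <- vector("list", n_lib)
  per_library <- list()

  for (i in seq_len(n_lib)) {
    id <- libs[i]
    log_msg("preprocess %s (adapter=%s q>=%d len %d-%d)", id, adapter,
            params$q_min, params$len_min, params$len_max)
    proc <- process_fastq(manifest$fastq[i], adapter, params$q_min,
                          params$len_min, params$len_max)
    if (!is.null(blocklist)) proc <- deplete_sequences(proc, blocklist)
    hits <- query_index(index, proc$reads$sequence)
    ann <- annotate_reads(proc$reads, bundle, hits = hits)
    calls <- classify_reads(proc$reads, mirna, index, hits = hits)
    iso <- quantify_isoforms(calls, mirna$mirna_id)
    for (ii in colnames(iso)) counts[[ii]][, id] <- iso[, ii]
    mapped <- sum(ann$annotation$count[ann$annotation$class != "unmapped"])
    nta_reads <- sum(calls$count[calls$isoform == "nta"] *
                       calls$weight[calls$isoform == "nta"])
    lib_sizes[id] <- mapped + nta_reads
    stats_rows[[i]] <- cbind(library_id = id, proc$stats)
    cm <- class_composition(ann$annotation)
    comp_rows[[i]] <- cbind(library_id = id, cm)
    per_library[[id]] <- list(stats = proc$stats, annotation = ann,
                              calls = calls)
  }

  write_stage_tsv(do.call(rbind, stats_rows),
                  file.path(out_dir, "processing_stats.tsv"), meta)
  write_stage_tsv(do.call(rbind, comp_rows),
                  file.path(out_dir, "class_composition.tsv"), meta)

  iso_rpm <- lapply(counts, rpm, lib_sizes = lib_sizes)
  for (ii in names(counts)) {
    write_stage_tsv(data.frame(mirna_id = rownames(counts[[ii]]),
                               counts[[ii]], check.names = FALSE),
                    file.path(out_dir, sprintf("counts_%s.tsv", ii)), meta)
  }

  design <- manifest[, c("library_id", "genotype", "timepoint", "replicate")]
  have_sets <- unique(design[, c("genotype", "timepoint")])
  complete <- nrow(have_sets) == 6 &&
    all(table(design$genotype, design$timepoint) ==
          max(design$replicate))

  result <- list(manifest = manifest, params = params, counts = counts,
                 iso_rpm = iso_rpm, lib_sizes = lib_sizes,
                 per_library = per_library, out_dir = out_dir)

  if (!complete) {
    warning("incomplete design: DE and clustering stages skipped")
    return(result)
  }

  summary_tab <- isoform_summary(iso_rpm, design)
  write_stage_tsv(summary_tab, file.path(out_dir, "isoform_summary.tsv"),
                  meta)

  # differential expression on canonical counts
  log_msg("differential expression (TMM + NB-GLM LRT, FDR <= %.2f)",
          params$max_fdr)
  can <- counts$canonical
  keep <- filter_expressed(rpm(can, lib_sizes), params$rpm_min,
                           params$rpm_min_libraries)
  can_f <- can[keep, , drop = FALSE]
  norm <- tmm_factors(can_f, lib_sizes)
  group <- sprintf("%s.%s", design$genotype, design$timepoint)
  de <- list(
    F0_2h = nb_glm_lrt(can_f, group, c("mut.F0_2h", "wt.F0_2h"),
                       lib_sizes, norm),
    F2_4h = nb_glm_lrt(can_f, group, c("mut.F2_4h", "wt.F2_4h"),
                       lib_sizes, norm)
  )
  for (nm in names(de)) {
    write_stage_tsv(de[[nm]], file.path(out_dir, sprintf("de_%s.tsv", nm)),
                    c(meta, list(contrast = nm)))
  }

  # expression classes on canonical sample-set means
  set_means <- sample_set_means(iso_rpm$canonical, design)
  sel <- select_canonical_for_clustering(set_means,
                                         params$cluster_rpm_min)
  clust <- NULL
  if (length(sel) >= params$k) {
    clust <- cluster_classes(set_means[sel, , drop = FALSE], params$k)
    cs <- class_summary(clust$classes, set_means[sel, , drop = FALSE])
    write_stage_tsv(data.frame(mirna_id = names(clust$classes),
                               class = unname(clust$classes)),
                    file.path(out_dir, "expression_classes.tsv"), meta)
    write_stage_tsv(cs, file.path(out_dir, "class_summary.tsv"), meta)
  } else {
    warning("too few expressed canonical miRNAs to cluster")
  }

  iso_set_means <- lapply(iso_rpm, sample_set_means, design = design)
  noncan_sel <- select_noncanonical_subset(iso_set_means)
  nta_sel <- select_nta_subset(iso_set_means)
  down <- select_downregulated_mirnas(de, set_means, params$max_fdr,
                                      params$cluster_rpm_min)
  write_stage_tsv(noncan_sel,
                  file.path(out_dir, "noncanonical_subset.tsv"), meta)
  write_stage_tsv(nta_sel, file.path(out_dir, "nta_subset.tsv"), meta)
  write_stage_tsv(data.frame(mirna_id = down),
                  file.path(out_dir, "downregulated_mirnas.tsv"), meta)

  c(result, list(isoform_summary = summary_tab, de = de,
                 norm_factors = norm, set_means = set_means,
                 classes = clust, downregulated = down,
                 noncanonical_subset = noncan_sel, nta_subset = nta_sel))
}

#' Load a reference bundle from a directory written by [write_reference()]
#'
#' @param dir directory containing `genome.fa`, `mirna.gff3` and the BED/
#'   FASTA layers.
#' @return a `ReferenceBundle`.
#' @export
read_reference <- function(dir) {
  genome <- .read_fasta(file.path(dir, "genome.fa"))
  mirna <- build_mirna_refs(file.path(dir, "mirna.gff3"),
                            file.path(dir, "hairpin.fa"),
                            file.path(dir, "mature.fa"))
  layers <- list(
    structural = .read_bed(file.path(dir, "structural.bed")),
    cisnat = .read_bed(file.path(dir, "cisnat.bed")),
    te = .read_bed(file.path(dir, "te_copies.bed")),
    exon = .read_bed(file.path(dir, "exon.bed")),
    intron = .read_bed(file.path(dir, "intron.bed"))
  )
  st <- layers$structural
  if (length(st)) {
    S4Vectors::mcols(st)$subtype <-
      sub("_.*$", "", sub("^rRNA_2S$", "rRNA", S4Vectors::mcols(st)$name))
    layers$structural <- st
  }
  cn <- layers$cisnat
  if (length(cn)) {
    S4Vectors::mcols(cn)$pair <- sub("_[AB]$", "", S4Vectors::mcols(cn)$name)
    layers$cisnat <- cn
  }
  structure(list(
    chrom = names(genome)[1], genome = genome, mirna = mirna,
    layers = layers,
    clusters = .read_bed(file.path(dir, "pirna_clusters.bed")),
    te_consensus = .read_fasta(file.path(dir, "te_consensus.fa")),
    free = GenomicRanges::GRanges(), paths = NULL
  ), class = "ReferenceBundle")
}

#' Simulate an experiment and run the full pipeline on it (demo mode)
#'
#' @param out_dir working directory (simulation under `sim/`, pipeline
#'   outputs under `out/`).
#' @param config a [simulation_config()]; its seed drives everything.
#' @return list with `sim` (simulation) and `run` (pipeline results).
#' @export
run_demo <- function(out_dir, config = simulation_config()) {
  sim <- simulate_experiment(config, file.path(out_dir, "sim"))
  run <- run_pipeline(sim$manifest, sim$bundle, config$adapter,
                      file.path(out_dir, "out"), seed = config$seed)
  list(sim = sim, run = run)
}
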