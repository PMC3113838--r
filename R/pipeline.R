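# End-to-end plumbing: a configuration object, a simulator that writes a
# complete self-consistent input bundle to disk, and a driver that runs
# enrichment -> classification -> (for the mitochondria-enriched set)
# genome scanning, structural features and conservation scoring, writing
# one results directory.

#' Pipeline configuration
#'
#' @param scans character vector of spot-table (TSV) paths.
#' @param genome path to the genome FASTA (or NULL to skip scanning).
#' @param annotation path to a GFF3 annotation (or NULL; hits are then
#'   labeled "unannotated" with a warning).
#' @param mirnas path to a mature-miRNA FASTA keyed by probe id.
#' @param precursors path to a pre-miRNA FASTA keyed by probe id.
#' @param conservation path to a conservation TSV (mirna/species/orders).
#' @param cutoff fold-of-enrichment cutoff (> 1; default 1.5).
#' @param k,seed_start,strands,composition seed-scan parameters.
#' @param max_dx CCF maximum shift (pixels).
#' @param seed master RNG seed for everything stochastic.
#' @param out_dir output directory.
#' @return a `pipeline_config` list, validated.
#' @export
pipeline_config <- function(scans = NULL, genome = NULL, annotation = NULL,
                            mirnas = NULL, precursors = NULL,
                            conservation = NULL,
                            cutoff = 1.5, k = 7, seed_start = 1,
                            strands = "both", composition = "genome",
                            max_dx = 20, seed = 1, out_dir = tempfile("mitomir_run_")) {
  if (cutoff <= 1) stop("cutoff must be > 1", call. = FALSE)
  if (k < 4) stop("seed length k must be >= 4", call. = FALSE)
  structure(list(scans = scans, genome = genome, annotation = annotation,
                 mirnas = mirnas, precursors = precursors,
                 conservation = conservation, cutoff = cutoff, k = k,
                 seed_start = seed_start, strands = strands,
                 composition = composition, max_dx = max_dx,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Simulate a complete input bundle with known ground truth
#'
#' Writes, under `dir`: three spot tables (`scan_1.tsv` ...), mature and
#' precursor FASTA files for the planted mitochondria-enriched probes, a
#' genome FASTA with one planted seed site per planted probe plus a GFF3
#' annotation, a dual-channel image pair, a conservation table, and CSV
#' truth tables. The bundle is sufficient to exercise every pipeline stage
#' offline, and equal seeds give byte-identical bundles.
#'
#' @param dir output directory (created if needed).
#' @param design an [array_design()]; default full-size layout.
#' @param n_arrays number of replicate scans (default 3).
#' @param n_mito,n_cyto,noise_cv passed to [planted_truth()].
#' @param genome_length synthetic genome length (default 16569, the size of
#'   the human mitochondrial genome).
#' @param seed master RNG seed.
#' @return (invisibly) a [pipeline_config()] pointing at the bundle, with
#'   the truth tables attached as attribute `"truth"`.
#' @export
simulate_inputs <- function(dir, design = array_design(), n_arrays = 3,
                            n_mito = 13, n_cyto = 44, noise_cv = 0.1,
                            genome_length = 16569, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- planted_truth(design, n_mito = n_mito, n_cyto = n_cyto,
                         noise_cv = noise_cv, seed = seed)
  scans <- gen_array_scans(design, truth, n_arrays = n_arrays, seed = seed + 1)
  scan_paths <- vapply(seq_along(scans), function(i) {
    p <- file.path(dir, sprintf("scan_%d.tsv", i))
    write_spot_table(scans[[i]], p)
    p
  }, character(1))

  # one mature miRNA + precursor hairpin per planted mito probe, with the
  # mature 5' heptamer planted as a target site on the synthetic genome
  mito_ids <- truth$mito_ids
  mature <- with_seed_if(seed + 2, stats::setNames(vapply(mito_ids, function(id) {
    paste(sample(RNA_BASES, 22, replace = TRUE), collapse = "")
  }, character(1)), mito_ids))
  precursor <- with_seed_if(seed + 3, stats::setNames(vapply(mito_ids, function(id) {
    gen_hairpin(stem_len = 12, loop_len = 8, gc_fraction = 0.6)
  }, character(1)), mito_ids))
  write_fasta(mature, file.path(dir, "mature.fa"))
  write_fasta(precursor, file.path(dir, "precursor.fa"))

  positions <- with_seed_if(seed + 4,
    sort(sample(seq_len(genome_length - 10), length(mito_ids))))
  planted_sites <- data.frame(
    seed = substr(unname(mature), 1, 7),
    position = positions,
    strand = rep(c("+", "-"), length.out = length(mito_ids)),
    mirna_id = mito_ids, stringsAsFactors = FALSE)
  gsim <- gen_genome_with_sites(genome_length, planted = planted_sites,
                                circular = TRUE, features = 12,
                                seed = seed + 5)
  write_fasta(stats::setNames(gsim$genome$seq, gsim$genome$accession),
              file.path(dir, "genome.fa"))
  write_annotation_gff3(gsim$annotation, file.path(dir, "annotation.gff3"))
  utils::write.csv(gsim$truth, file.path(dir, "genome_truth.csv"),
                   row.names = FALSE)

  imgs <- gen_coloc_images(coloc_fraction = 0.8, shift = 0, noise = 0.02,
                           seed = seed + 6)
  write_channel_image(imgs$green, file.path(dir, "green.tif"))
  write_channel_image(imgs$red, file.path(dir, "red.tif"))

  cons_src <- system.file("extdata", "mitomir_conservation.tsv",
                          package = "mitomir")
  file.copy(cons_src, file.path(dir, "conservation.tsv"), overwrite = TRUE)

  utils::write.csv(
    data.frame(probe_id = names(truth$fold), true_fold = unname(truth$fold),
               planted_class = ifelse(names(truth$fold) %in% truth$mito_ids, "mito",
                                ifelse(names(truth$fold) %in% truth$cyto_ids,
                                       "cyto", "none"))),
    file.path(dir, "array_truth.csv"), row.names = FALSE)

  cfg <- pipeline_config(scans = scan_paths,
                         genome = file.path(dir, "genome.fa"),
                         annotation = file.path(dir, "annotation.gff3"),
                         mirnas = file.path(dir, "mature.fa"),
                         precursors = file.path(dir, "precursor.fa"),
                         conservation = file.path(dir, "conservation.tsv"),
                         seed = seed, out_dir = file.path(dir, "results"))
  attr(cfg, "truth") <- list(array = truth, genome = gsim$truth,
                             mirna_sites = planted_sites)
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Enrichment classification of the spot tables, then — for the probes
#' called mitochondria-enriched that have a sequence in the miRNA FASTA —
#' genome seed scanning, structural features and conservation scoring.
#' All result CSVs, plus a run log recording the configuration, are written
#' under `config$out_dir`. Stage failures abort with the stage name; files
#' already written are retained.
#'
#' @param config a [pipeline_config()].
#' @return list with `enrichment`, `heatmap`, `scan` (or NULL), `features`
#'   (or NULL), `conservation` (or NULL), and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run_log.txt")
  log_lines <- c(sprintf("mitomir %s pipeline run, R %s",
                         as.character(utils::packageVersion("mitomir")),
                         paste(R.version$major, R.version$minor, sep = ".")),
                 "configuration:",
                 vapply(names(unclass(config)), function(nm) {
                   sprintf("  %s = %s", nm,
                           paste(format(config[[nm]]), collapse = ", "))
                 }, character(1)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("FAILED at stage '%s': %s",
                                      name, conditionMessage(e))), log_path)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  enr <- stage("enrichment", {
    if (is.null(config$scans) || length(config$scans) == 0)
      stop("no scan files configured")
    scans <- lapply(config$scans, read_spot_table)
    enrich_scans(scans, cutoff = config$cutoff)
  })
  utils::write.csv(as.data.frame(enr), file.path(out, "enrichment.csv"),
                   row.names = FALSE)
  heat <- stage("heatmap", heatmap_table(enr, file = file.path(out, "log2_matrix.csv")))

  mito_ids <- enr$probe_id[enr$class == "mito"]
  scan_res <- NULL; feats <- NULL; cons <- NULL

  if (!is.null(config$genome) && !is.null(config$mirnas)) {
    scan_res <- stage("targeting", {
      genome <- read_genome_fasta(config$genome)
      mirnas <- read_mirna_fasta(config$mirnas)
      panel <- mirnas[names(mirnas) %in% mito_ids]
      if (length(panel) == 0) panel <- mirnas
      ann <- NULL
      if (!is.null(config$annotation) && file.exists(config$annotation)) {
        ann <- read_annotation_gff3(config$annotation)
      } else {
        # scan_panel itself warns that hits will be labeled 'unannotated'
        log_lines <- c(log_lines, "warning: annotation missing, labels 'unannotated'")
      }
      scan_panel(panel, genome, annotation = ann, k = config$k,
                 seed_start = config$seed_start, strands = config$strands,
                 composition = config$composition)
    })
    utils::write.csv(scan_res$table, file.path(out, "seed_scan.csv"),
                     row.names = FALSE)
  }

  if (!is.null(config$mirnas) && !is.null(config$precursors)) {
    feats <- stage("features", {
      mature <- read_mirna_fasta(config$mirnas)
      pre <- read_mirna_fasta(config$precursors)
      feature_table(mature[names(mature) %in% names(pre)], pre)
    })
    utils::write.csv(feats, file.path(out, "features.csv"), row.names = FALSE)
  }

  if (!is.null(config$conservation)) {
    cons <- stage("conservation",
                  score_conservation(read_conservation_table(config$conservation)))
    utils::write.csv(cons, file.path(out, "conservation.csv"), row.names = FALSE)
  }

  writeLines(c(log_lines, "status: complete"), log_path)
  list(enrichment = enr, heatmap = heat, scan = scan_res, features = feats,
       conservation = cons, out_dir = out)
}
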