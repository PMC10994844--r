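# Pipeline orchestration: one configuration object drives all stages,
# every run writes a manifest with parameters, seeds and checksums, and a
# fixed seed makes reruns bit-identical for the deterministic stages.

#' Default pipeline configuration
#'
#' A fully-defaulted configuration is valid; every stage block names the
#' defaults of the corresponding functions.
#'
#' @return nested named list
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "bactatlas_out",
    inputs = list(fasta = NULL, gff = NULL, coverage_dir = NULL,
                  coverage_prefix = "coverage", counts = NULL,
                  conditions = NULL, fitness = NULL, gene_sets = NULL),
    tss = list(min_height = 10, min_enrichment = 2, cluster_window = 3,
               pseudocount = 1, upstream_window = 300,
               antisense_flank = 100),
    terminator = list(stem_range = c(5, 12), loop_range = c(3, 8),
                      max_stem_mismatches = 1, min_u_tail = 4,
                      window = 50, min_drop = 0.5, min_upstream_cov = 10),
    operon = list(max_gap = 300, min_joining_cov = 5),
    srna = list(min_cov = 5, min_len = 30, merge_gap = 10, max_len = 500,
                keep_frac = 0.5, curation_window = 50, cov_change_min = 2,
                length_range = c(30, 500), energy_threshold = -0.05),
    inverton = list(arm_min = 12, arm_max = 25, spacer_min = 30,
                    spacer_max = 1000, gc_min = 0.15, gc_max = 0.85,
                    promoter_window = 50),
    expression = list(cpm_threshold = 0.6635, lfc_cut = 2, fdr_cut = 0.05,
                      contrast = NULL, n_perm = 2000, min_set_size = 10,
                      exempt_sets = character(0L)),
    integrate = list(min_set_size = 10)
  )
}

#' @noRd
.validate_config <- function(config, template = default_config(),
                             path = "config") {
  unknown <- setdiff(names(config), names(template))
  .assert(length(unknown) == 0L, "unknown ", path, " key(s): ",
          paste(unknown, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
          is.list(config[[nm]]))
      .validate_config(config[[nm]], template[[nm]],
                       paste0(path, "$", nm))
  }
  invisible(TRUE)
}

#' Load and validate a pipeline configuration
#'
#' @param config a nested list, or path to a YAML file; missing keys take
#'   their defaults, unknown keys are rejected
#' @return the merged configuration list
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validate_config(config)
  merged <- default_config()
  for (nm in names(config)) {
    if (is.list(merged[[nm]]) && is.list(config[[nm]])) {
      for (k in names(config[[nm]])) merged[[nm]][[k]] <- config[[nm]][[k]]
    } else merged[[nm]] <- config[[nm]]
  }
  merged
}

#' @noRd
.stage_log <- function(stage, ...) {
  kv <- c(...)
  message(sprintf("[%s] %s", stage,
                  paste(names(kv), unname(kv), sep = "=",
                        collapse = " ")))
}

#' Run the annotation and analysis pipeline
#'
#' Reads the configured inputs, runs TSS detection and classification,
#' terminator prediction, operon assembly, sRNA discovery and curation,
#' inverton scanning with promoter integration, and (when count data are
#' configured) expression filtering, differential testing, enrichment and
#' fitness categorization. Stage outputs are written under the configured
#' output directory together with a manifest of parameters, seeds and
#' checksums. On stage failure a `FAILED` marker naming the stage is left
#' in the output directory and the error is rethrown.
#'
#' @param config list or YAML path (see [load_config()])
#' @return invisibly, a list with the main result objects and the manifest
#'   path
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_config(config)
  outdir <- cfg$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  stage <- "setup"
  res <- list()
  tryCatch({
    stage <- "read_inputs"
    .assert(!is.null(cfg$inputs$fasta) && !is.null(cfg$inputs$gff),
            "config$inputs needs at least fasta and gff")
    replicons <- read_fasta(cfg$inputs$fasta)
    genes <- read_gff3(cfg$inputs$gff, nchar(replicons))
    genome <- genome_bundle(
      replicons, genes[, c("id", "replicon", "start", "end", "strand",
                           "biotype")],
      provenance = list(checksums = .file_checksums(
        c(cfg$inputs$fasta, cfg$inputs$gff))))
    .stage_log(stage, n_replicons = length(replicons),
               n_genes = nrow(genes))

    coverage <- NULL
    if (!is.null(cfg$inputs$coverage_dir)) {
      coverage <- read_bedgraph(cfg$inputs$coverage_dir,
                                .replicon_lengths(genome),
                                prefix = cfg$inputs$coverage_prefix)
    }

    tss <- NULL
    operons <- list()
    if (!is.null(coverage)) {
      stage <- "tss"
      p <- cfg$tss
      tss <- detect_tss(coverage, p$min_height, p$min_enrichment,
                        p$cluster_window, p$pseudocount)
      tss <- classify_tss(tss, genome$genes, p$upstream_window,
                          p$antisense_flank)
      .stage_log(stage, n_tss = nrow(tss))

      stage <- "terminators"
      p <- cfg$terminator
      hairpin <- do.call(rbind, lapply(names(replicons), function(rep) {
        rbind(find_hairpin_terminators(replicons[[rep]], "+",
                                       p$stem_range[1]:p$stem_range[2],
                                       p$loop_range[1]:p$loop_range[2],
                                       p$max_stem_mismatches, p$min_u_tail,
                                       replicon = rep),
              find_hairpin_terminators(replicons[[rep]], "-",
                                       p$stem_range[1]:p$stem_range[2],
                                       p$loop_range[1]:p$loop_range[2],
                                       p$max_stem_mismatches, p$min_u_tail,
                                       replicon = rep))
      }))
      drops <- find_coverage_drop_terminators(coverage, genome$genes,
                                              p$window, p$min_drop,
                                              p$min_upstream_cov)
      terminators <- rbind(hairpin, drops)
      .stage_log(stage, n_hairpin = nrow(hairpin),
                 n_coverage_drop = nrow(drops))

      stage <- "operons"
      p <- cfg$operon
      # coverage-corroborated terminators gate the joining; hairpin-only
      # predictions are annotation, not joining evidence
      operons <- assemble_operons(genome$genes, tss, drops, coverage,
                                  p$max_gap, p$min_joining_cov)
      .stage_log(stage, n_operons = length(operons))

      stage <- "srna"
      p <- cfg$srna
      psites <- detect_processing_sites(coverage)
      cands <- derive_srna_candidates(coverage, tss, psites,
                                      min_len = p$min_len,
                                      max_len = p$max_len,
                                      keep_frac = p$keep_frac,
                                      min_cov = p$min_cov)
      srnas <- classify_srnas(cands, tss, psites, genome$genes, operons,
                              terminators)
      cur <- curate_srnas(srnas[!is.na(srnas$class), , drop = FALSE],
                          tss, psites, genome$genes, terminators,
                          coverage, genome, window = p$curation_window,
                          cov_change_min = p$cov_change_min,
                          length_range = p$length_range,
                          energy_threshold = p$energy_threshold)
      .stage_log(stage, n_candidates = nrow(cands),
                 n_accepted = nrow(cur$accepted),
                 n_rejected = nrow(cur$rejected))

      stage <- "write_annotation"
      ann <- rbind(
        data.frame(replicon = tss$replicon, start = tss$pos,
                   end = tss$pos, strand = tss$strand, biotype = "TSS",
                   id = tss$id,
                   class = vapply(tss$classes, function(d)
                     paste(unique(d$class), collapse = ","),
                     character(1L)),
                   stringsAsFactors = FALSE),
        data.frame(replicon = terminators$replicon,
                   start = terminators$start, end = terminators$end,
                   strand = terminators$strand, biotype = "terminator",
                   id = sprintf("term%04d", seq_len(nrow(terminators))),
                   class = terminators$method, stringsAsFactors = FALSE),
        if (length(operons) > 0L) {
          ot <- operon_table(operons)
          data.frame(replicon = ot$replicon, start = ot$start,
                     end = ot$end, strand = ot$strand, biotype = "operon",
                     id = ot$id, class = "operon",
                     stringsAsFactors = FALSE)
        },
        if (nrow(cur$accepted) > 0L)
          data.frame(replicon = cur$accepted$replicon,
                     start = cur$accepted$start, end = cur$accepted$end,
                     strand = cur$accepted$strand, biotype = "ncRNA",
                     id = cur$accepted$id, class = cur$accepted$class,
                     stringsAsFactors = FALSE))
      write_gff3(ann, file.path(outdir, "annotation.gff3"))
      write_records_tsv(tss_classes_table(tss),
                        file.path(outdir, "tss.tsv"))
      write_records_tsv(terminators, file.path(outdir, "terminators.tsv"))
      write_records_tsv(operon_table(operons),
                        file.path(outdir, "operons.tsv"))
      write_records_tsv(rbind(cur$accepted, cur$rejected),
                        file.path(outdir, "srnas.tsv"))
      res$tss <- tss
      res$terminators <- terminators
      res$operons <- operons
      res$srnas <- cur
    }

    stage <- "invertons"
    p <- cfg$inverton
    irs <- do.call(rbind, lapply(names(replicons), function(rep) {
      find_inverted_repeats(replicons[[rep]], p$arm_min, p$arm_max,
                            p$spacer_min, p$spacer_max, replicon = rep)
    }))
    irs_f <- filter_inverted_repeats(irs, p$gc_min, p$gc_max)
    if (!is.null(tss))
      irs_f <- flag_promoter_invertons(irs_f, tss, p$promoter_window)
    write_inverton_bed(irs_f, file.path(outdir, "invertons.bed"))
    write_records_tsv(irs_f, file.path(outdir, "invertons.tsv"))
    .stage_log(stage, n_ir = nrow(irs), n_kept = nrow(irs_f),
               n_promoter = sum(irs_f$promoter_flag %in% TRUE))
    res$invertons <- irs_f

    if (!is.null(cfg$inputs$counts)) {
      stage <- "expression"
      p <- cfg$expression
      em <- read_counts_tsv(cfg$inputs$counts, cfg$inputs$conditions)
      kept <- filter_expressed(em, p$cpm_threshold)
      emf <- expr_matrix(em$counts[kept, , drop = FALSE], em$conditions,
                         em$lib_sizes)
      contrast <- p$contrast
      if (is.null(contrast)) {
        conds <- unique(emf$conditions)
        .assert(length(conds) >= 2L, "need >= 2 conditions for DE")
        contrast <- c(conds[2L], conds[1L])
      }
      de <- significant_de(nb_de_test(emf, contrast), p$lfc_cut, p$fdr_cut)
      write_records_tsv(de, file.path(outdir, "de_results.tsv"))
      .stage_log(stage, n_filtered = length(kept),
                 n_up = sum(de$call == "up"), n_down = sum(de$call == "down"))
      res$de <- de
      if (!is.null(cfg$inputs$gene_sets)) {
        sets <- read_gmt(cfg$inputs$gene_sets)
        enr <- preranked_gsea(rank_metric(de), sets, n_perm = p$n_perm,
                              min_size = p$min_set_size,
                              exempt_sets = p$exempt_sets,
                              seed = .child_seed(cfg$seed, 7L))
        write_records_tsv(enr, file.path(outdir, "enrichment.tsv"))
        .stage_log("gsea", n_sets = nrow(enr))
        res$enrichment <- enr
      }
      res$expr <- emf
    }

    if (!is.null(cfg$inputs$fitness)) {
      stage <- "fitness"
      ft <- read_fitness_tsv(cfg$inputs$fitness)
      cat_fit <- categorize_fitness(ft)
      write_records_tsv(cat_fit$summary,
                        file.path(outdir, "fitness_summary.tsv"))
      if (!is.null(res$expr)) {
        pr <- prioritize_srnas(cat_fit$summary, res$expr)
        write_records_tsv(pr, file.path(outdir, "fitness_priorities.tsv"))
        res$priorities <- pr
      }
      .stage_log(stage,
                 n_significant_srnas = sum(cat_fit$summary$any_significant))
      res$fitness <- cat_fit
    }

    stage <- "manifest"
    outputs <- list.files(outdir, full.names = TRUE)
    outputs <- outputs[!grepl("manifest\\.yaml$", outputs)]
    manifest <- list(
      package = "bactatlas",
      version = as.character(utils::packageVersion("bactatlas")),
      seed = cfg$seed,
      parameters = cfg[setdiff(names(cfg), c("inputs", "outdir"))],
      inputs = .file_checksums(unlist(cfg$inputs[
        !vapply(cfg$inputs, is.null, logical(1L))])),
      outputs = .file_checksums(outputs))
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
    res$manifest <- file.path(outdir, "manifest.yaml")
    invisible(res)
  }, error = function(e) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Build a self-contained synthetic demonstration dataset
#'
#' One command produces a 50-kb genome with 20 genes in 10 operon blocks,
#' 40 planted TSSs (10 primary, 6 secondary, 9 sRNA-borne, 15 orphan),
#' 10 terminators, 12 sRNAs across the five sub-classes, 8 inverted
#' repeats (including mismatched arms and a homopolymeric decoy), TEX+/
#' TEX- coverage tracks, a 500-gene count matrix with planted fold changes
#' and one planted regulon, gene sets, and an 80 x 100 fitness table with
#' 5 planted hits -- plus truth tables and a digest file for
#' reproducibility checks.
#'
#' @param seed RNG seed; all stage seeds derive from it
#' @param outdir output directory
#' @return invisibly, a list with `genome`, `truth`, `coverage`, `expr`,
#'   `fitness` and the file manifest
#' @export
make_demo <- function(seed, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  gg <- generate_genome(.child_seed(seed, 1L), c(chr = 50000L),
                        n_genes = 20L, mean_gene_len = 900L,
                        block_sizes = c(3L, 2L, 2L, 1L, 2L, 3L, 1L, 2L,
                                        2L, 2L))
  ir_specs <- list(
    list(arm_len = 12, mismatches = 0, spacer_len = 100),
    list(arm_len = 13, mismatches = 1, spacer_len = 150),
    list(arm_len = 15, mismatches = 0, spacer_len = 80),
    list(arm_len = 16, mismatches = 1, spacer_len = 200),
    list(arm_len = 18, mismatches = 0, spacer_len = 120),
    list(arm_len = 20, mismatches = 2, spacer_len = 250),
    list(arm_len = 22, mismatches = 1, spacer_len = 60),
    list(arm_len = 15, mismatches = 0, spacer_len = 90,
         homopolymeric = TRUE))
  pi <- plant_inverted_repeats(gg$genome, ir_specs,
                               .child_seed(seed, 2L), gg$truth)
  truth <- plant_transcripts(pi$genome, pi$truth, .child_seed(seed, 3L),
                             n_srna = c(intergenic = 4, antisense = 3,
                                        utr5 = 2, utr3 = 2,
                                        intra_operonic = 1),
                             n_secondary = 6, n_orphan = 15)
  coverage <- simulate_drnaseq_coverage(pi$genome, truth,
                                        enrichment_factor = 10,
                                        tss_height = 100, noise_rate = 0.1,
                                        terminator_drop = 0.9,
                                        seed = .child_seed(seed, 4L))
  conds <- stats::setNames(rep(c("control", "bile", "mucin", "cold"),
                               each = 2L),
                           sprintf("s%02d", 1:8))
  de_truth <- c(stats::setNames(rep(4, 40), sprintf("G%04d", 1:40)),
                stats::setNames(rep(-4, 40), sprintf("G%04d", 41:80)))
  sim <- simulate_counts(500L, conds, libsizes = 3e6, dispersion = 0.05,
                         planted_de = de_truth, de_condition = "bile",
                         planted_regulons = list(
                           list(n_genes = 30, target_cor = 0.9,
                                amplitude = 2)),
                         seed = .child_seed(seed, 5L))
  ft_hits <- data.frame(
    srna = sprintf("sRNA%03d", c(3, 11, 24, 57, 66)),
    experiment = sprintf("exp%03d", c(5, 12, 40, 71, 88)),
    fit = c(-2.5, -1.2, 0.8, -3.0, 1.5),
    t = c(6, 6, 6, 6, 6), stringsAsFactors = FALSE)
  ft <- simulate_fitness_table(80L, 100L, ft_hits,
                               seed = .child_seed(seed, 6L))
  sets <- c(list(regulon01 = sim$truth$regulons$regulon01),
            with_seed(.child_seed(seed, 8L), {
              stats::setNames(lapply(1:10, function(i)
                sample(sprintf("G%04d", 1:500), 15L)),
                sprintf("random%02d", 1:10))
            }))

  write_fasta(pi$genome$replicons, file.path(outdir, "genome.fasta"))
  write_gff3(pi$genome$genes[, c("replicon", "start", "end", "strand",
                                 "biotype", "id")],
             file.path(outdir, "genes.gff3"))
  write_bedgraph(coverage, file.path(outdir, "coverage"))
  write_counts_tsv(sim$expr, file.path(outdir, "counts.tsv"),
                   file.path(outdir, "conditions.tsv"))
  write_fitness_tsv(ft$table, file.path(outdir, "fitness.tsv"))
  write_gmt(sets, file.path(outdir, "genesets.gmt"))
  tdir <- file.path(outdir, "truth")
  if (!dir.exists(tdir)) dir.create(tdir)
  write_records_tsv(truth$tss, file.path(tdir, "tss.tsv"))
  write_records_tsv(truth$terminators, file.path(tdir, "terminators.tsv"))
  write_records_tsv(truth$srnas, file.path(tdir, "srnas.tsv"))
  write_records_tsv(truth$irs, file.path(tdir, "inverted_repeats.tsv"))
  write_records_tsv(truth$processing_sites,
                    file.path(tdir, "processing_sites.tsv"))
  ops <- do.call(rbind, lapply(seq_along(truth$operons), function(i)
    data.frame(operon = sprintf("block%02d", i),
               replicon = truth$operons[[i]]$replicon,
               strand = truth$operons[[i]]$strand,
               genes = paste(truth$operons[[i]]$genes, collapse = ";"),
               stringsAsFactors = FALSE)))
  write_records_tsv(ops, file.path(tdir, "operons.tsv"))
  write_records_tsv(data.frame(gene = names(de_truth),
                               log2fc = unname(de_truth)),
                    file.path(tdir, "de.tsv"))
  files <- sort(list.files(outdir, recursive = TRUE, full.names = TRUE))
  files <- files[!grepl("digests\\.txt$", files)]
  digests <- unname(tools::md5sum(files))
  rel <- sub(paste0("^", outdir, "/?"), "", files)
  writeLines(sprintf("%s  %s", digests, rel),
             file.path(outdir, "digests.txt"))
  invisible(list(genome = pi$genome, truth = truth, coverage = coverage,
                 expr = sim$expr, expr_truth = sim$truth,
                 fitness = ft$table, fitness_truth = ft$truth,
                 gene_sets = sets, files = files))
}
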