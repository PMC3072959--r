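# End-to-end orchestration: classify -> characterize -> dup-origin ->
# enrich, with every intermediate artifact written as TSV and a
# machine-readable run manifest (parameters, package version, file
# checksums) so a run is re-derivable from its manifest alone.

#' Pipeline configuration
#'
#' @param manifest Path to a species manifest (TSV/YAML).
#' @param gff,proteins,cds Paths to the focal gene models.
#' @param ests Optional EST FASTA (transcript support + enrichment).
#' @param expression Optional named list of expression list paths
#'   (`queen`, `worker`, `full` or another two-label contrast plus `full`).
#' @param contrast The two biased labels of the expression contrast.
#' @param outdir Output directory.
#' @param params [alignment_params()] for homology searches.
#' @param cutoff Homology E-value cutoff.
#' @param stages Character subset of
#'   `c("classify", "characterize", "dup_origin", "enrich")`.
#' @param hit_tables Optional precomputed hit tables (see
#'   [build_presence_absence()]); when supplied the built-in engine is
#'   skipped and a provenance note recorded in the run manifest.
#' @param seed Seed recorded in the manifest (no pipeline stage is
#'   stochastic; the seed matters only when the inputs were generated).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, gff, proteins, cds = NULL, ests = NULL,
                            expression = NULL,
                            contrast = c("queen", "worker"),
                            outdir, params = alignment_params(),
                            cutoff = params$evalue_cutoff,
                            stages = c("classify", "characterize",
                                       "dup_origin", "enrich"),
                            hit_tables = NULL, seed = NULL) {
  stopifnot(cutoff > 0)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(manifest = manifest, gff = gff, proteins = proteins,
                 cds = cds, ests = ests, expression = expression,
                 contrast = contrast, outdir = outdir, params = params,
                 cutoff = cutoff, stages = stages, hit_tables = hit_tables,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full TRG pipeline
#'
#' Executes the configured stages in order. Artifacts written to the output
#' directory: `presence_absence.tsv` (genes x species, cells A/P/G),
#' `classification.tsv`, `class_counts.tsv`, `characteristics.tsv`,
#' `class_summary.tsv`, `duplication.tsv`, `enrichment.tsv`,
#' `contingency_observed.tsv`, and `run_manifest.json`. A stage failure
#' aborts with the stage name; artifacts written by the failed stage are
#' renamed with a `.partial` suffix, earlier stages' artifacts are kept.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with the in-memory objects
#'   (`presence`, `report`, `characteristics`, `summary`, `duplication`,
#'   `enrichment`) and `files` (paths of everything written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  files <- character(0)
  log <- function(...) message("[trgstrat] ", ...)

  manifest <- read_species_manifest(config$manifest)
  proteins <- read_fasta(config$proteins)
  cds <- if (!is.null(config$cds)) read_fasta(config$cds) else NULL
  genes <- read_gff3(config$gff, proteins = proteins, cds = cds)
  est_db <- if (!is.null(config$ests)) read_fasta(config$ests) else NULL
  log(length(genes), " focal genes, ", nrow(manifest) - 1,
      " comparison species")

  result <- list(files = character(0))
  stage_files <- character(0)
  run_stage <- function(name, code) {
    stage_files <<- character(0)
    tryCatch(code, error = function(e) {
      for (f in stage_files) if (file.exists(f))
        file.rename(f, paste0(f, ".partial"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(df, f) {
    path <- out(f)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    stage_files <<- c(stage_files, path)
    files <<- c(files, path)
    path
  }

  pa <- NULL; report <- NULL
  if ("classify" %in% config$stages) {
    run_stage("classify", {
      pa <- build_presence_absence(genes, manifest,
                                   search = config$hit_tables,
                                   params = config$params,
                                   cutoff = config$cutoff)
      report <- classify_all(pa)
      emit(data.frame(gene_id = rownames(pa$code), pa$code,
                      check.names = FALSE), "presence_absence.tsv")
      emit(as.data.frame(report), "classification.tsv")
      emit(data.frame(class = names(report$counts),
                      count = unname(report$counts)), "class_counts.tsv")
      log("classified: ", paste(sprintf("%s=%d", names(report$counts),
                                        report$counts), collapse = " "))
    })
    result$presence <- pa
    result$report <- report
  }

  if ("characterize" %in% config$stages) {
    run_stage("characterize", {
      chars <- characteristics_table(genes, est_db = est_db)
      result$characteristics <- chars
      emit(chars, "characteristics.tsv")
      if (!is.null(report)) {
        cls_sum <- summarize_by_class(chars, report$classes)
        result$summary <- cls_sum
        emit(cls_sum, "class_summary.tsv")
      }
    })
  }

  if ("dup_origin" %in% config$stages) {
    if (is.null(report)) stop("dup_origin stage requires classify")
    run_stage("dup_origin", {
      recs <- duplication_origin_records(genes, report, pa,
                                         params = config$params,
                                         cutoff = config$cutoff)
      dup_df <- data.frame(
        gene_id = vapply(recs, `[[`, character(1), "trg_id"),
        class = vapply(recs, `[[`, character(1), "trg_class"),
        n_paralogs = vapply(recs, function(r) length(r$paralog_ids),
                            integer(1)),
        conserved_paralog = vapply(recs, `[[`, logical(1),
                                   "conserved_paralog"),
        row.names = NULL, stringsAsFactors = FALSE)
      result$duplication <- list(records = recs,
                                  rates = duplication_rate_by_class(recs))
      emit(dup_df, "duplication.tsv")
      emit(result$duplication$rates, "duplication_rates.tsv")
    })
  }

  if ("enrich" %in% config$stages && !is.null(config$expression)) {
    if (is.null(report)) stop("enrich stage requires classify")
    run_stage("enrich", {
      expr <- read_expression_lists(config$expression,
                                    contrast = config$contrast)
      est_ids <- unique(unlist(lapply(expr, `[[`, "id"), use.names = FALSE))
      gene_of <- setNames(rep(NA_character_, length(est_ids)), est_ids)
      for (e in est_ids) {
        gene_of[e] <- as.character(map_est_to_genes(est_db[[e]], proteins,
          gene_of = setNames(sub("\\.t\\d+$", "", names(proteins)),
                             names(proteins))))
      }
      aln <- data.frame(est_id = est_ids, gene_id = unname(gene_of),
                        accepted = !is.na(gene_of), stringsAsFactors = FALSE)
      sets <- build_gene_sets(expr, aln)
      ct <- build_contingency(report$classes, sets, collapse = "orphan")
      res <- chi_square(ct, yates = FALSE)
      dev <- percentage_deviations(ct)
      result$enrichment <- list(table = ct, test = res, deviations = dev)
      emit(data.frame(row = rownames(ct$observed), ct$observed,
                      check.names = FALSE), "contingency_observed.tsv")
      emit(data.frame(statistic = res$statistic, df = res$df,
                      p_value = res$p_value), "enrichment.tsv")
      log(sprintf("enrichment: chi-square %.3f df %d p %.3g",
                  res$statistic, res$df, res$p_value))
    })
  }

  manifest_json <- list(
    package = "trgstrat",
    version = as.character(utils::packageVersion("trgstrat")),
    seed = config$seed,
    cutoff = config$cutoff,
    params = list(gap_open = config$params$gap_open,
                  gap_extend = config$params$gap_extend,
                  ungapped = config$params$ungapped,
                  lambda = config$params$lambda,
                  kappa = config$params$kappa),
    stages = config$stages,
    engine = if (is.null(config$hit_tables)) "built-in"
             else "external hit tables",
    inputs = list(manifest = config$manifest, gff = config$gff,
                  proteins = config$proteins),
    checksums = as.list(tools::md5sum(files))
  )
  mj <- out("run_manifest.json")
  jsonlite::write_json(manifest_json, mj, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, mj)
  result$files <- files
  structure(result, class = "pipeline_result")
}

#' Reproduce the caste-expression enrichment statistics from published counts
#'
#' Recomputes, from the shipped table of published honey-bee gene counts by
#' homology class (queen/worker/no-difference brain expression after
#' Grozinger et al. 2007; nurse/forager after Alaux et al. 2009;
#' hypopharyngeal-gland ESTs), the headline enrichment statistics: the
#' orphan vs non-orphan chi-square over the queen/worker/no-difference
#' columns (df = 2, uncorrected), the 2x2 nurse/forager chi-square with
#' Yates continuity correction, the per-cell percentage deviations, and the
#' orphan share of each expression column.
#'
#' @param counts_file Path to a counts TSV with columns `panel`, `class`,
#'   `group`, `count` (defaults to the copy shipped with the package).
#' @return List with `queen_worker` (an `enrichment_result`),
#'   `nurse_forager` (Yates-corrected `enrichment_result`), `deviations`
#'   (of the queen/worker table), `orphan_percent` (per group), and the
#'   two `contingency_table`s.
#' @export
reproduce_caste_enrichment <- function(
    counts_file = system.file("extdata", "honeybee_caste_class_counts.tsv",
                              package = "trgstrat")) {
  counts <- read.delim(counts_file, stringsAsFactors = FALSE)
  if (!all(c("panel", "class", "group", "count") %in% names(counts)))
    stop("malformed counts file: need panel, class, group, count columns")
  if (any(is.na(counts$count)) || any(counts$count < 0))
    stop("malformed counts file: counts must be non-negative integers")

  panel_table <- function(panel, groups) {
    sub <- counts[counts$panel == panel, , drop = FALSE]
    if (nrow(sub) == 0) stop("counts file lacks panel '", panel, "'")
    obs <- sapply(groups, function(g) {
      gsub <- sub[sub$group == g, , drop = FALSE]
      v <- gsub$count[match(HOMOLOGY_CLASSES, gsub$class)]
      if (anyNA(v)) stop("panel '", panel, "', group '", g,
                         "': missing class counts")
      v
    })
    rownames(obs) <- HOMOLOGY_CLASSES
    orphan <- obs["orphan", ]
    rbind(orphan = orphan, non_orphan = colSums(obs) - orphan)
  }

  qw <- panel_table("queen_worker", c("queen", "worker", "no_difference"))
  nf <- panel_table("nurse_forager", c("nurse", "forager"))
  ct_qw <- contingency_from_observed(qw)
  ct_nf <- contingency_from_observed(nf)
  res_qw <- chi_square(ct_qw, yates = FALSE)
  res_nf <- chi_square(ct_nf, yates = TRUE)
  list(queen_worker = res_qw,
       nurse_forager = res_nf,
       deviations = percentage_deviations(ct_qw),
       orphan_percent = 100 * qw["orphan", ] / colSums(qw),
       orphan_percent_nurse_forager = 100 * nf["orphan", ] / colSums(nf),
       table_queen_worker = ct_qw,
       table_nurse_forager = ct_nf)
}
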