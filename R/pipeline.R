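#' Run the full recessive-burden pipeline
#'
#' Orchestrates the stages in dependency order — variant classification, RG
#' calling, consanguinity classification, mutability burden testing,
#' contribution estimation and (optionally) founder statistics and lineage
#' specificity — over either an in-memory cohort or files on disk, writing
#' per-stage TSV outputs plus a JSON manifest (package version, seed, input
#' checksums, stage timings) into `out_dir`.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{cohort}{an `rb_cohort`, or NULL to read files.}
#'     \item{vcf, ped, annotation, mutability}{input paths (used when
#'       `cohort` is NULL; `mutability` may also be a tibble).}
#'     \item{f_table}{tibble (`sample`, `f`) or TSV path; falls back to
#'       `marker_set` (an `rb_marker_set`) for ROH-based estimation, else
#'       the contribution stage is skipped.}
#'     \item{cooccurrence}{optional co-occurrence panel for singletons.}
#'     \item{gene_sets}{optional named list of gene-symbol vectors.}
#'     \item{expression}{optional expression tibble or TSV for the
#'       specificity stage.}
#'     \item{founder_counts}{optional list(n_hom_alt=, n_het=, n_hom_ref=).}
#'     \item{seed}{integer seed (default 1).}
#'     \item{bootstrap}{bootstrap replicates for the contribution CI
#'       (default 200).}
#'   }
#' @param out_dir output directory.
#' @return list of stage results (rg, rates, consanguinity, model,
#'   enrichment, contribution, founder, specificity, report), invisibly
#'   written to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  seed <- config$seed %||% 1L
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(stage, start) {
    timings[[stage]] <<- round(as.numeric(Sys.time() - start, units = "secs"), 3)
  }

  # ---- inputs ---------------------------------------------------------------
  s <- tic()
  checksums <- list()
  if (!is.null(config$cohort)) {
    cohort <- config$cohort
    variants <- cohort$variants
    pedigree <- cohort$pedigree
    genotypes <- cohort$genotypes
    mutability <- cohort$mutability
  } else {
    for (f in c("vcf", "ped", "annotation", "mutability")) {
      if (is.character(config[[f]]) && !file.exists(config[[f]])) {
        abort(sprintf("input validation: %s file '%s' not found", f, config[[f]]))
      }
    }
    variants <- read_annotation(config$annotation)
    pedigree <- read_pedigree(config$ped)
    genotypes <- read_genotypes_vcf(config$vcf)
    mutability <- if (is.character(config$mutability)) {
      read_mutability(config$mutability)
    } else {
      as_tibble(config$mutability)
    }
    cohort <- list(genotypes = genotypes, pedigree = pedigree,
                   variants = variants, mutability = mutability)
    checksums <- lapply(config[c("vcf", "ped", "annotation")],
                        function(p) unname(tools::md5sum(p)))
  }
  if (!"class" %in% names(variants)) variants <- classify_variants(variants)
  cohort$variants <- variants
  if (is.null(mutability)) abort("input validation: mutability table missing")
  toc("load", s)

  probands <- pedigree$sample[pedigree$phenotype == 2L]
  results <- list()

  # ---- RG calling -----------------------------------------------------------
  s <- tic()
  inform("stage rg_calling")
  rg <- tryCatch(
    call_recessive_genotypes(genotypes, variants, pedigree,
                             cooccurrence = config$cooccurrence,
                             class = "damaging"),
    error = function(e) abort(sprintf("stage rg_calling failed: %s",
                                      conditionMessage(e))))
  results$rg <- rg
  readr::write_tsv(rg, file.path(out_dir, "rg_table.tsv"))
  results$rates <- tabulate_rg_rates(rg, n_samples = length(probands),
                                     gene_sets = config$gene_sets)
  readr::write_tsv(results$rates, file.path(out_dir, "rg_rates.tsv"))
  toc("rg_calling", s)

  # ---- consanguinity --------------------------------------------------------
  s <- tic()
  f_table <- NULL
  if (!is.null(config$f_table)) {
    f_table <- if (is.character(config$f_table)) {
      readr::read_tsv(config$f_table, show_col_types = FALSE, progress = FALSE)
    } else {
      as_tibble(config$f_table)
    }
  } else if (!is.null(config$marker_set)) {
    inform("stage consanguinity (ROH estimation)")
    f_table <- tryCatch(
      estimate_f(config$marker_set),
      error = function(e) abort(sprintf("stage consanguinity failed: %s",
                                        conditionMessage(e))))
  }
  if (!is.null(f_table)) {
    results$consanguinity <- classify_consanguinity(f_table)
    readr::write_tsv(results$consanguinity,
                     file.path(out_dir, "consanguinity.tsv"))
    if (!is.null(config$gene_sets$known)) {
      results$known_gene_table <- consanguinity_gene_set_table(
        rg, results$consanguinity, config$gene_sets$known)
      readr::write_tsv(results$known_gene_table,
                       file.path(out_dir, "known_gene_consanguinity.tsv"))
    }
  }
  toc("consanguinity", s)

  # ---- burden ---------------------------------------------------------------
  s <- tic()
  inform("stage burden")
  counts <- count(rg, gene = .data$gene, name = "observed")
  results$model <- tryCatch(
    fit_expected_model(counts, mutability, n = length(probands)),
    error = function(e) abort(sprintf("stage burden failed: %s",
                                      conditionMessage(e))))
  enr <- gene_burden_test(results$model) |>
    adjust_multiplicity(n_genes = nrow(mutability)) |>
    arrange(.data$p_value)
  results$enrichment <- enr
  readr::write_tsv(enr, file.path(out_dir, "gene_enrichment.tsv"))
  if (!is.null(config$gene_sets)) {
    set_rows <- purrr::imap(config$gene_sets, function(genes, nm) {
      genes <- intersect(genes, results$model$fitted$gene)
      if (length(genes) == 0) return(NULL)
      gene_set_test(results$model, genes, observed = rg, set_name = nm)
    })
    results$set_enrichment <- bind_rows(set_rows)
    readr::write_tsv(results$set_enrichment,
                     file.path(out_dir, "set_enrichment.tsv"))
  }
  toc("burden", s)

  # ---- contribution ---------------------------------------------------------
  s <- tic()
  if (!is.null(f_table)) {
    inform("stage contribution")
    results$contribution <- tryCatch(
      contribution_table(cohort, f_table, B = config$bootstrap %||% 200,
                         seed = seed),
      error = function(e) abort(sprintf("stage contribution failed: %s",
                                        conditionMessage(e))))
    readr::write_tsv(results$contribution,
                     file.path(out_dir, "contribution.tsv"))
  }
  toc("contribution", s)

  # ---- founder --------------------------------------------------------------
  if (!is.null(config$founder_counts)) {
    inform("stage founder")
    results$founder <- founder_report(config$founder_counts,
                                      shared = config$founder_shared,
                                      n_chromosomes = config$founder_chromosomes)
    jsonlite::write_json(results$founder,
                         file.path(out_dir, "founder_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # ---- lineage specificity --------------------------------------------------
  if (!is.null(config$expression)) {
    inform("stage specificity")
    expr <- if (is.character(config$expression)) {
      read_expression(config$expression)
    } else {
      config$expression
    }
    norm <- ratio_of_max(expr)
    results$specificity <- specific_genes(norm, fold = config$fold %||% 5)
    results$clustering <- upgma_cluster(norm)
    readr::write_tsv(results$specificity,
                     file.path(out_dir, "lineage_specificity.tsv"))
  }

  # ---- report + manifest ----------------------------------------------------
  results$report <- pipeline_report(results, n_probands = length(probands))
  for (nm in names(results$report)) {
    readr::write_tsv(results$report[[nm]],
                     file.path(out_dir, paste0("report_", nm, ".tsv")))
  }
  manifest <- list(
    package = "recburden",
    version = as.character(utils::packageVersion("recburden")),
    seed = seed,
    n_probands = length(probands),
    inputs_md5 = checksums,
    timings_sec = timings,
    total_sec = round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Assemble cohort summary tables from pipeline results
#'
#' @param results list of stage results from [run_pipeline()].
#' @param n_probands proband count for the rate table.
#' @param top_k number of top-ranked genes in the gene table (default 30).
#' @return named list of tibbles: `rates` (cohort RG counts and
#'   per-individual rates), `top_genes` (highest-ranked binomial results),
#'   and `contribution` when available.
#' @export
pipeline_report <- function(results, n_probands, top_k = 30) {
  out <- list()
  out$rates <- results$rates %||%
    tabulate_rg_rates(results$rg %||% empty_rg(), n_samples = max(n_probands, 1L))
  if (!is.null(results$enrichment)) {
    out$top_genes <- results$enrichment |>
      arrange(.data$p_value) |>
      slice_head(n = top_k)
  }
  if (!is.null(results$contribution)) {
    out$contribution <- mutate(results$contribution,
                               fraction_pct = 100 * .data$fraction)
  }
  out
}
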