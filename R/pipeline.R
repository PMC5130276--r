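#' Configure a full discovery-validation run
#'
#' @param cohorts A list; each element is a list with fields `name`,
#'   `role` (`"discovery"` or `"validation"`; exactly one cohort must be
#'   the discovery series), `data` (an `expression_study` for probe-level
#'   cohorts or a `gene_matrix` for cohorts that arrive already
#'   gene-summarized), and optionally `covariates` (default: none for the
#'   discovery series, `"smoking"` for validation series, mirroring the
#'   asymmetry of a near-all-smoker discovery cohort versus mixed-smoking
#'   validation cohorts).
#' @param out_dir Output directory for all tables and the run log.
#' @param seed Integer master seed; permutation sub-seeds are derived from
#'   it deterministically.
#' @param preprocess A [preprocess_config()] applied to probe-level
#'   cohorts.
#' @param fdr_threshold Significance threshold used in discovery and
#'   validation.
#' @param n_permutations Label-permutation cycles for the discovery null
#'   (0 disables the permutation stage).
#' @param gene_sets Optional `gene_set_collection` for the enrichment
#'   stage (`NULL` disables it).
#' @param gsea_permutations Phenotype permutations for enrichment
#'   significance.
#' @param set_size Length-2 inclusive size window for [filter_sets()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohorts, out_dir, seed,
                       preprocess = preprocess_config(),
                       fdr_threshold = 0.05,
                       n_permutations = 100,
                       gene_sets = NULL,
                       gsea_permutations = 100,
                       set_size = c(15, 500)) {
  roles <- vapply(cohorts, function(co) co$role, character(1))
  if (sum(roles == "discovery") != 1)
    stop("exactly one cohort must have role 'discovery'")
  if (!all(roles %in% c("discovery", "validation")))
    stop("cohort roles must be 'discovery' or 'validation'")
  structure(list(cohorts = cohorts, out_dir = out_dir,
                 seed = as.integer(seed), preprocess = preprocess,
                 fdr_threshold = fdr_threshold,
                 n_permutations = n_permutations,
                 gene_sets = gene_sets,
                 gsea_permutations = gsea_permutations,
                 set_size = set_size),
            class = "run_config")
}

#' Run the full discovery-validation analysis for both variables
#'
#' Executes, for each analysis arm (sex, then age): preprocessing of the
#' discovery series (detection filter, probe collapse, quantile
#' normalization, batch adjustment), genome-wide per-gene association,
#' the label-permutation null, candidate re-testing in every validation
#' cohort, the concordant-direction intersection with chromosomal
#' annotation, and (when gene sets are supplied) enrichment analysis with
#' an enrichment-map edge list. All tables are written under
#' `config$out_dir/<variable>/` with provenance headers; a run log is
#' written at the top level. Identical seeds give identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list (per variable) with elements
#'   `discovery` (association_table), `permutation`
#'   (permutation_summary or NULL), `cohort_results`, `report`
#'   (validation_report or NULL), `annotation`, `enrichment`, `map`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logit <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    writeLines(msg, log_con)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  logit("run_full_analysis, seed ", config$seed)

  ## preprocess every cohort once (shared by both arms)
  mats <- list()
  roles <- character()
  covars <- list()
  for (co in config$cohorts) {
    mats[[co$name]] <- stage(paste0("preprocess:", co$name), {
      if (inherits(co$data, "expression_study"))
        preprocess_study(co$data, config$preprocess)
      else if (inherits(co$data, "gene_matrix")) co$data
      else stop("cohort data must be an expression_study or gene_matrix")
    })
    roles[co$name] <- co$role
    covars[[co$name]] <- if (!is.null(co$covariates)) co$covariates
      else if (co$role == "validation") "smoking" else character()
    logit("preprocessed ", co$name, ": ", nrow(mats[[co$name]]$expr),
          " samples x ", ncol(mats[[co$name]]$expr), " genes")
  }
  disc_name <- names(roles)[roles == "discovery"]
  disc <- mats[[disc_name]]

  results <- list()
  for (arm_i in seq_along(c("sex", "age"))) {
    variable <- c("sex", "age")[arm_i]
    arm_dir <- file.path(config$out_dir, variable)
    dir.create(arm_dir, showWarnings = FALSE)
    cfg_disc <- association_config(variable, covars[[disc_name]],
                                   config$fdr_threshold)

    assoc <- stage("association", fit_associations(disc, cfg_disc))
    write_association(assoc, file.path(arm_dir, "associations_discovery.tsv"),
                      seed = config$seed, config = config[c("fdr_threshold")])
    candidates <- assoc$gene[assoc$fdr < config$fdr_threshold]
    logit(variable, ": ", length(candidates), " discovery candidates")

    perm <- NULL
    if (config$n_permutations > 0) {
      perm <- stage("permutation",
        permutation_null(disc, cfg_disc, candidates,
                         n_permutations = config$n_permutations,
                         seed = config$seed + 1000L * arm_i))
      .write_tsv(data.frame(cycle = seq_along(perm$counts),
                            n_significant = perm$counts),
                 file.path(arm_dir, "permutations.tsv"),
                 .provenance_header(config$seed))
      .write_tsv(data.frame(gene = names(perm$per_gene_null_freq),
                            n_cycles_significant = perm$per_gene_null_freq),
                 file.path(arm_dir, "null_freq.tsv"),
                 .provenance_header(config$seed))
      logit(variable, ": permutation null, ", perm$n_zero, "/",
            perm$n_permutations, " zero cycles, expected count ",
            format(perm$expected_count, digits = 4),
            " (labels shuffled without stratification)")
    }

    cohort_results <- list()
    report <- NULL
    annotation <- NULL
    if (length(candidates) > 0 && any(roles == "validation")) {
      for (nm in names(roles)[roles == "validation"]) {
        cfg_val <- association_config(variable, covars[[nm]],
                                      config$fdr_threshold)
        cr <- stage(paste0("validation:", nm),
                    test_candidates(mats[[nm]], cfg_val, candidates))
        cohort_results[[nm]] <- cr
        write_association(cr$table,
                          file.path(arm_dir, paste0("validated_", nm, ".tsv")),
                          seed = config$seed)
      }
      report <- stage("intersection",
                      intersect_concordant(assoc, cohort_results,
                                           config$fdr_threshold))
      .write_tsv(data.frame(gene = report$common_set),
                 file.path(arm_dir, "common_set.tsv"))
      .write_tsv(data.frame(gene = report$contra_regulated),
                 file.path(arm_dir, "contra_regulated.tsv"))
      .write_tsv(data.frame(region = names(report$venn_counts),
                            count = report$venn_counts),
                 file.path(arm_dir, "venn_counts.tsv"))
      annotation <- annotate_chromosomal(
        report$common_set, disc$genes,
        setNames(assoc$direction, assoc$gene))
      logit(variable, ": common set of ", length(report$common_set),
            " genes; ", length(report$contra_regulated), " contra-regulated")
    }

    enrichment <- NULL
    map <- NULL
    if (!is.null(config$gene_sets)) {
      coll <- filter_sets(config$gene_sets, colnames(disc$expr),
                          config$set_size[1], config$set_size[2])
      if (length(coll$sets) > 0) {
        enrichment <- stage("gsea",
          enrichment_significance(disc, cfg_disc, coll,
                                  n_permutations = config$gsea_permutations,
                                  seed = config$seed + 5000L * arm_i))
        .write_tsv(as.data.frame(enrichment),
                   file.path(arm_dir, "enrichment.tsv"),
                   .provenance_header(config$seed))
        map <- build_enrichment_map(enrichment, coll, config$fdr_threshold)
        edges <- igraph::as_data_frame(map, what = "edges")
        .write_tsv(edges, file.path(arm_dir, "enrichment_map_edges.tsv"))
        logit(variable, ": ", sum(enrichment$fdr < config$fdr_threshold),
              " enriched sets of ", nrow(enrichment), " tested")
      }
    }

    results[[variable]] <- list(discovery = assoc, permutation = perm,
                                cohort_results = cohort_results,
                                report = report, annotation = annotation,
                                enrichment = enrichment, map = map)
  }
  logit("done")
  invisible(results)
}
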