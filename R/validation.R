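#' Re-test discovery candidates in one validation cohort
#'
#' Fits the association model on the cohort (with the cohort's covariates,
#' e.g. smoking), restricts the result to the candidate genes present on
#' the cohort's platform, and applies the Benjamini-Hochberg adjustment
#' across exactly that candidate subset — not genome-wide — because only
#' those hypotheses are being re-tested. Candidates missing from the
#' platform are recorded.
#'
#' @param gm The cohort's `gene_matrix`.
#' @param cfg An [association_config()].
#' @param candidates Non-empty character vector of discovery candidates.
#' @return An object of class `cohort_result`: list with `cohort`, `table`
#'   (an `association_table` over the tested candidates, FDR within the
#'   subset), `n_candidates_tested`, `missing_candidates`.
#' @export
test_candidates <- function(gm, cfg, candidates) {
  stopifnot(inherits(gm, "gene_matrix"), length(candidates) > 0)
  present <- intersect(candidates, colnames(gm$expr))
  missing <- setdiff(candidates, present)
  if (length(present) == 0) stop("no candidate genes present in the cohort")
  sub <- gm
  sub$expr <- gm$expr[, present, drop = FALSE]
  sub$genes <- gm$genes[match(present, gm$genes$gene), , drop = FALSE]
  tab <- fit_associations(sub, cfg)   # BH within the candidate subset
  structure(list(cohort = unique(gm$samples$cohort)[1],
                 table = tab,
                 n_candidates_tested = length(present),
                 missing_candidates = missing),
            class = "cohort_result")
}

#' Intersect cohort results requiring concordant direction
#'
#' A candidate is *validated* in a cohort when its subset-wise FDR is below
#' `threshold` **and** its coefficient has the same sign as in the
#' discovery series. Genes significant in some cohort with the opposite
#' sign are *contra-regulated*: they are recorded separately and excluded
#' from every validated list (and hence from the common set). The common
#' set is the intersection of the per-cohort validated lists. Venn region
#' counts are tallied over "significant (FDR < threshold) in dataset d"
#' membership across the discovery series and all cohorts.
#'
#' @param discovery An `association_table` from the discovery series
#'   (defines the candidate directions); only rows for the candidates are
#'   used.
#' @param cohorts List of [test_candidates()] results.
#' @param threshold FDR threshold (default 0.05).
#' @return An object of class `validation_report`: list with `validated`
#'   (named list of per-cohort validated gene vectors), `common_set`,
#'   `contra_regulated`, `venn_counts` (named vector, names are dataset
#'   bitmask strings in the order discovery, cohorts...), `datasets`,
#'   `threshold`.
#' @export
intersect_concordant <- function(discovery, cohorts, threshold = 0.05) {
  stopifnot(inherits(discovery, "association_table"), length(cohorts) > 0)
  candidates <- unique(unlist(lapply(cohorts, function(cr)
    c(cr$table$gene, cr$missing_candidates))))
  disc <- discovery[match(candidates, discovery$gene), , drop = FALSE]
  if (anyNA(disc$gene))
    stop("cohorts tested genes absent from the discovery table")
  disc_dir <- setNames(sign(disc$beta), disc$gene)

  validated <- list()
  contra <- character()
  sig_sets <- list(discovery = candidates)  # candidates are discovery hits
  for (cr in cohorts) {
    tab <- cr$table
    sig <- tab$fdr < threshold
    dir_ok <- sign(tab$beta) == disc_dir[tab$gene] & sign(tab$beta) != 0
    if (any(sig & sign(tab$beta) == 0))
      message("gene(s) with zero coefficient treated as non-concordant in ",
              cr$cohort)
    validated[[cr$cohort]] <- tab$gene[sig & dir_ok]
    contra <- union(contra, tab$gene[sig & !dir_ok])
    sig_sets[[cr$cohort]] <- tab$gene[sig]
  }
  ## contra-regulated genes are globally excluded from validated lists
  validated <- lapply(validated, setdiff, y = contra)
  common <- Reduce(intersect, validated)

  ## n-way Venn bookkeeping over significance membership
  member <- do.call(cbind, lapply(sig_sets, function(s) candidates %in% s))
  mask <- apply(member, 1, function(b) paste(as.integer(b), collapse = ""))
  in_any <- rowSums(member) > 0
  venn <- table(mask[in_any])
  venn_counts <- setNames(as.integer(venn), names(venn))

  structure(list(validated = validated,
                 common_set = common,
                 contra_regulated = sort(contra),
                 venn_counts = venn_counts,
                 datasets = names(sig_sets),
                 threshold = threshold),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report (FDR <", x$threshold, ")\n")
  for (nm in names(x$validated))
    cat("  ", nm, ": ", length(x$validated[[nm]]), " validated\n", sep = "")
  cat("  common set:", length(x$common_set), "genes\n")
  cat("  contra-regulated:", length(x$contra_regulated), "genes\n")
  invisible(x)
}

#' Chromosomal bookkeeping for a validated gene set
#'
#' Counts how a gene set distributes over autosomes (also reporting the
#' number of distinct autosomes), the non-pseudoautosomal X and Y, and the
#' pseudoautosomal regions (chromosome coded `"X;Y"`); optionally tallies
#' up- and down-regulated genes from supplied directions.
#'
#' @param genes Character vector of gene symbols (may be empty).
#' @param gene_annotation A data.frame with columns `gene` and
#'   `chromosome`; every queried gene must be present.
#' @param direction Optional named numeric/integer vector of effect signs
#'   (positive = up in the first group / with age).
#' @return A list with `n_genes`, `autosomal`, `n_distinct_autosomes`,
#'   `x_linked`, `y_linked`, `pseudoautosomal`, and (when `direction` is
#'   given) `up`, `down`.
#' @export
#' @examples
#' cat25 <- sex_gene_catalog()
#' annotate_chromosomal(cat25$gene,
#'                      data.frame(gene = cat25$gene,
#'                                 chromosome = cat25$chromosome),
#'                      setNames(sign(cat25$fold_change), cat25$gene))
annotate_chromosomal <- function(genes, gene_annotation, direction = NULL) {
  if (length(genes) == 0) {
    out <- list(n_genes = 0L, autosomal = 0L, n_distinct_autosomes = 0L,
                x_linked = 0L, y_linked = 0L, pseudoautosomal = 0L)
    if (!is.null(direction)) out <- c(out, list(up = 0L, down = 0L))
    return(out)
  }
  idx <- match(genes, gene_annotation$gene)
  if (anyNA(idx))
    stop("unannotated gene(s): ",
         paste(genes[is.na(idx)], collapse = ", "))
  chrom <- as.character(gene_annotation$chromosome[idx])
  auto <- chrom %in% as.character(1:22)
  out <- list(
    n_genes = length(genes),
    autosomal = sum(auto),
    n_distinct_autosomes = length(unique(chrom[auto])),
    x_linked = sum(chrom == "X"),
    y_linked = sum(chrom == "Y"),
    pseudoautosomal = sum(chrom == "X;Y"))
  if (!is.null(direction)) {
    d <- direction[genes]
    out$up <- sum(d > 0, na.rm = TRUE)
    out$down <- sum(d < 0, na.rm = TRUE)
  }
  out
}
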