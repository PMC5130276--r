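#' Preprocessing configuration
#'
#' @param detection_p_cutoff A probe is "detected" in a sample when its
#'   detection p-value is below this cutoff (default 0.01).
#' @param min_detected_fraction Probes detected in fewer than this fraction
#'   of samples are removed; the boundary is kept (detected fraction >=
#'   cutoff retains the probe). Default 0.10.
#' @param normalization `"quantile"` or `"none"`.
#' @param combat Whether the pipeline applies empirical-Bayes batch
#'   adjustment after normalization.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(detection_p_cutoff = 0.01,
                              min_detected_fraction = 0.10,
                              normalization = c("quantile", "none"),
                              combat = TRUE) {
  stopifnot(detection_p_cutoff > 0, detection_p_cutoff < 1,
            min_detected_fraction >= 0, min_detected_fraction <= 1)
  structure(list(detection_p_cutoff = detection_p_cutoff,
                 min_detected_fraction = min_detected_fraction,
                 normalization = match.arg(normalization),
                 combat = isTRUE(combat)),
            class = "preprocess_config")
}

## per-probe fraction of samples with detection p below cutoff
.detection_rates <- function(study, cutoff) {
  colMeans(study$detection_p < cutoff)
}

#' Filter probes by annotation and detection rate
#'
#' Retains exactly the probes that (a) map to a gene symbol and (b) are
#' detected (detection p below `cfg$detection_p_cutoff`) in at least
#' `cfg$min_detected_fraction` of samples. Probe order is preserved.
#'
#' @param study An `expression_study`.
#' @param cfg A [preprocess_config()].
#' @return The filtered `expression_study`.
#' @export
filter_probes <- function(study, cfg = preprocess_config()) {
  stopifnot(inherits(study, "expression_study"))
  if (!identical(dim(study$expr), dim(study$detection_p)))
    stop("expr and detection_p must have identical dimensions")
  annotated <- !is.na(study$probe_map$gene_symbol) &
    nzchar(study$probe_map$gene_symbol)
  rate <- .detection_rates(study, cfg$detection_p_cutoff)
  keep <- annotated & rate >= cfg$min_detected_fraction
  if (!any(keep))
    warning("all probes removed by filtering")
  study$expr <- study$expr[, keep, drop = FALSE]
  study$detection_p <- study$detection_p[, keep, drop = FALSE]
  study$probe_map <- study$probe_map[keep, , drop = FALSE]
  rownames(study$probe_map) <- NULL
  study
}

#' Collapse probes to one representative per gene
#'
#' When several probes map to the same gene, keeps the probe with the
#' highest detection rate (fraction of samples with detection p below the
#' cutoff); ties are broken by the lexicographically smallest probe id.
#'
#' @param study A filtered `expression_study`.
#' @param cfg A [preprocess_config()] (supplies the detection cutoff).
#' @return An object of class `gene_matrix`: list with `expr` (samples x
#'   genes), `samples`, and `genes` (gene, chromosome, probe_id,
#'   detection_rate of the retained probe).
#' @export
collapse_probes <- function(study, cfg = preprocess_config()) {
  stopifnot(inherits(study, "expression_study"))
  rate <- .detection_rates(study, cfg$detection_p_cutoff)
  pm <- study$probe_map
  ## order by gene, then rate (desc), then probe id: first row per gene wins
  ord <- order(pm$gene_symbol, -rate, pm$probe_id)
  first <- ord[!duplicated(pm$gene_symbol[ord])]
  first <- sort(first)  # keep original probe order
  genes <- data.frame(gene = pm$gene_symbol[first],
                      chromosome = pm$chromosome[first],
                      probe_id = pm$probe_id[first],
                      detection_rate = rate[first],
                      stringsAsFactors = FALSE)
  expr <- study$expr[, first, drop = FALSE]
  colnames(expr) <- genes$gene
  structure(list(expr = expr, samples = study$samples, genes = genes),
            class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat("gene_matrix:", nrow(x$expr), "samples x", ncol(x$expr), "genes\n")
  invisible(x)
}

#' Quantile normalization across samples
#'
#' Forces every sample's value distribution onto the across-sample mean
#' order-statistic distribution; within-sample ranks are preserved and tied
#' values receive the mean of the tied reference values. A single-sample
#' matrix is returned unchanged. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param gm A `gene_matrix`.
#' @return The normalized `gene_matrix`.
#' @export
quantile_normalize <- function(gm) {
  stopifnot(inherits(gm, "gene_matrix"))
  if (anyNA(gm$expr)) stop("missing values are not supported")
  if (nrow(gm$expr) < 2) return(gm)
  norm <- t(limma::normalizeQuantiles(t(gm$expr), ties = TRUE))
  dimnames(norm) <- dimnames(gm$expr)
  gm$expr <- norm
  gm
}

#' Empirical-Bayes batch adjustment
#'
#' Removes additive (location) and multiplicative (scale) batch effects by
#' the parametric empirical-Bayes location-scale method: gene-wise
#' standardization, method-of-moments hyperprior estimation across genes,
#' iterative shrinkage of per-batch location and scale parameters, and
#' back-transformation. Delegates to [sva::ComBat()]. By default no
#' biological covariates are protected; pass a design-matrix fragment via
#' `covariates` to protect them.
#'
#' @param gm A `gene_matrix`.
#' @param batch Per-sample batch labels; defaults to the `batch` column of
#'   the sample sheet.
#' @param covariates Optional numeric matrix (samples x columns) of
#'   covariates to retain, or `NULL`.
#' @return The adjusted `gene_matrix`.
#' @export
combat_adjust <- function(gm, batch = gm$samples$batch, covariates = NULL) {
  stopifnot(inherits(gm, "gene_matrix"))
  batch <- as.character(batch)
  tab <- table(batch)
  if (length(tab) < 2) stop("combat_adjust requires at least 2 batches")
  if (any(tab < 2)) stop("every batch needs at least 2 samples")
  mod <- NULL
  if (!is.null(covariates)) {
    mod <- cbind(Intercept = 1, as.matrix(covariates))
    full <- cbind(mod, model.matrix(~ batch)[, -1, drop = FALSE])
    if (qr(full)$rank < ncol(full))
      stop("covariates are confounded with batch (singular design)")
  }
  out <- utils::capture.output(
    adj <- suppressMessages(
      sva::ComBat(dat = t(gm$expr), batch = batch, mod = mod,
                  par.prior = TRUE, prior.plots = FALSE)))
  gm$expr <- t(adj)
  gm
}

#' One-call probe-to-gene preprocessing
#'
#' Applies [filter_probes()], [collapse_probes()], [quantile_normalize()]
#' (if configured) and [combat_adjust()] (if configured and the study has
#' more than one batch) in the standard order.
#'
#' @param study An `expression_study`.
#' @param cfg A [preprocess_config()].
#' @return A `gene_matrix`.
#' @export
preprocess_study <- function(study, cfg = preprocess_config()) {
  gm <- collapse_probes(filter_probes(study, cfg), cfg)
  if (cfg$normalization == "quantile") gm <- quantile_normalize(gm)
  if (cfg$combat && length(unique(gm$samples$batch)) > 1)
    gm <- combat_adjust(gm)
  gm
}
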