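#' Describe a cohort to be simulated
#'
#' A `cohort_spec` captures the design of one clinical series: how many
#' samples, the sex split, per-sex age ranges, the smoking-status mix, and
#' how samples are divided into processing batches.
#'
#' @param name Cohort label.
#' @param n_samples Total number of samples.
#' @param n_male Number of male samples (the rest are female).
#' @param age_range_male,age_range_female Length-2 numeric, min and max age
#'   in years; ages are drawn uniformly over the range.
#' @param smoking_levels Named numeric vector of proportions over smoking
#'   categories (subset of `current`, `former`, `never`, `unknown`); must
#'   sum to 1.
#' @param batch_sizes Integer vector of per-batch sample counts summing to
#'   `n_samples`.
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' cohort_spec("toy", 20, 12, c(40, 80), c(40, 80), c(current = 1), 20)
cohort_spec <- function(name, n_samples, n_male,
                        age_range_male, age_range_female,
                        smoking_levels = c(current = 1),
                        batch_sizes = n_samples) {
  n_samples <- as.integer(n_samples)
  n_male <- as.integer(n_male)
  batch_sizes <- as.integer(batch_sizes)
  if (n_male > n_samples)
    stop("n_male (", n_male, ") exceeds n_samples (", n_samples, ")")
  if (abs(sum(smoking_levels) - 1) > 1e-9)
    stop("smoking_levels proportions must sum to 1")
  if (is.null(names(smoking_levels)) ||
      !all(names(smoking_levels) %in% c("current", "former", "never", "unknown")))
    stop("smoking_levels must be named with current/former/never/unknown")
  if (sum(batch_sizes) != n_samples)
    stop("batch_sizes must sum to n_samples")
  for (rng in list(age_range_male, age_range_female)) {
    if (length(rng) != 2 || any(rng <= 0) || rng[1] >= rng[2])
      stop("age ranges must be positive with min < max")
  }
  structure(
    list(name = as.character(name), n_samples = n_samples, n_male = n_male,
         age_range_male = as.numeric(age_range_male),
         age_range_female = as.numeric(age_range_female),
         smoking_levels = smoking_levels, batch_sizes = batch_sizes),
    class = "cohort_spec")
}

#' Ground-truth effect sizes for the simulator
#'
#' An `effect_truth` object holds, per gene, the parameters of the
#' generative model: baseline log2 intensity, male-minus-female log2
#' difference, per-year age slope, per-smoking-level log2 shifts, residual
#' noise SD, number of probes, detectable-sample fraction, and chromosome.
#' Genes on chromosome `"Y"` are special-cased: females do not carry them,
#' so female values are drawn from a dedicated low-mean background
#' distribution rather than from the linear model.
#'
#' @param gene Character vector of gene symbols (unique).
#' @param chromosome Chromosome per gene: `"1"`..`"22"`, `"X"`, `"Y"`, or
#'   the pseudoautosomal code `"X;Y"`.
#' @param baseline_log2 Mean log2 intensity per gene.
#' @param sex_log2fc Male-minus-female log2 difference (for Y genes, the
#'   male level above the female background mean).
#' @param age_slope Change in log2 intensity per year of age.
#' @param residual_sd Per-gene residual noise SD (> 0).
#' @param n_probes Probes per gene (>= 1).
#' @param expressed_fraction Fraction of samples in which the gene's first
#'   probe is detectable; additional probes decay geometrically (factor
#'   0.9) so the collapse-by-detection-rate rule has a deterministic
#'   winner.
#' @param smoking_shift Either `NULL` (no smoking effect) or a numeric
#'   matrix genes x levels (colnames from `current`, `former`, `unknown`)
#'   of additive log2 shifts relative to never-smokers.
#' @param background_mean,background_sd Parameters of the background
#'   intensity distribution used for female values of Y-linked genes.
#' @return An object of class `effect_truth` (a data.frame with
#'   attributes).
#' @export
effect_truth <- function(gene, chromosome,
                         baseline_log2 = 8, sex_log2fc = 0, age_slope = 0,
                         residual_sd = 0.2, n_probes = 1L,
                         expressed_fraction = 1,
                         smoking_shift = NULL,
                         background_mean = 6, background_sd = 0.2) {
  n <- length(gene)
  if (anyDuplicated(gene)) stop("gene symbols must be unique")
  df <- data.frame(
    gene = as.character(gene),
    chromosome = rep_len(as.character(chromosome), n),
    baseline_log2 = rep_len(baseline_log2, n),
    sex_log2fc = rep_len(sex_log2fc, n),
    age_slope = rep_len(age_slope, n),
    residual_sd = rep_len(residual_sd, n),
    n_probes = rep_len(as.integer(n_probes), n),
    expressed_fraction = rep_len(expressed_fraction, n),
    stringsAsFactors = FALSE)
  ok_chr <- c(as.character(1:22), "X", "Y", "X;Y")
  if (!all(df$chromosome %in% ok_chr))
    stop("chromosome labels must be 1..22, X, Y or X;Y")
  if (any(df$residual_sd <= 0)) stop("residual_sd must be positive")
  if (any(df$n_probes < 1L)) stop("n_probes must be >= 1")
  if (any(df$expressed_fraction < 0 | df$expressed_fraction > 1))
    stop("expressed_fraction must lie in [0, 1]")
  if (!is.null(smoking_shift)) {
    smoking_shift <- as.matrix(smoking_shift)
    if (nrow(smoking_shift) != n)
      stop("smoking_shift must have one row per gene")
    if (!all(colnames(smoking_shift) %in% c("current", "former", "unknown")))
      stop("smoking_shift columns must be current/former/unknown")
  }
  structure(df, smoking_shift = smoking_shift,
            background_mean = background_mean,
            background_sd = background_sd,
            class = c("effect_truth", "data.frame"))
}

#' Per-batch location-scale effects for the simulator
#'
#' Batch effects follow the location-scale model that empirical-Bayes batch
#' adjustment is designed to remove: each batch adds `location` to every
#' probe of a gene and multiplies the residual SD by `scale`.
#'
#' @param n_batches Number of batches.
#' @param n_genes Number of genes.
#' @param location Additive log2 offsets: scalar, per-batch vector, or a
#'   full batches x genes matrix.
#' @param scale Multiplicative factors on residual SD (> 0), same recycling
#'   rules.
#' @return An object of class `batch_effects` with matrices `location` and
#'   `scale` (batches x genes).
#' @export
batch_effects <- function(n_batches, n_genes, location = 0, scale = 1) {
  expand <- function(x, what) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(n_batches, n_genes)))
        stop(what, " matrix must be n_batches x n_genes")
      return(x)
    }
    if (length(x) == 1) x <- rep(x, n_batches)
    if (length(x) != n_batches)
      stop(what, " must be scalar, per-batch, or a full matrix")
    matrix(x, n_batches, n_genes)
  }
  loc <- expand(location, "location")
  sc <- expand(scale, "scale")
  if (any(sc <= 0)) stop("scale factors must be positive")
  structure(list(location = loc, scale = sc, n_batches = n_batches),
            class = "batch_effects")
}

#' Simulate a probe-level expression study
#'
#' Draws a samples x probes matrix of log2 intensities from the additive
#' model
#' \deqn{y = \beta_0 + \beta_{sex}[male] + \beta_{age} \cdot age +
#'   \beta_{smk} + \gamma_{batch} + \epsilon,\quad
#'   \epsilon \sim N(0, (\sigma_g \delta_{batch})^2)}
#' except for Y-linked genes, whose female values come from the background
#' intensity distribution (females do not carry the gene). Matched
#' detection p-values are small (< 0.01) for detectable sample-probe pairs
#' and uniform on (0.01, 1) otherwise, so the expected detected fraction
#' per probe equals its `expressed_fraction`.
#'
#' @param spec A [cohort_spec()].
#' @param truth An [effect_truth()].
#' @param batches A [batch_effects()] with `n_batches ==
#'   length(spec$batch_sizes)`; `NULL` means no batch effects.
#' @param seed Integer seed; identical seeds give identical studies. The
#'   caller's RNG state is preserved.
#' @return An object of class `expression_study`: list with `expr`
#'   (samples x probes), `detection_p` (same shape), `samples`
#'   (sample_id, sex, age_years, smoking, batch, cohort), `probe_map`
#'   (probe_id, gene_symbol, chromosome).
#' @export
#' @examples
#' spec <- cohort_spec("toy", 30, 18, c(40, 80), c(40, 80))
#' truth <- effect_truth(c("G1", "G2"), c("1", "X"), sex_log2fc = c(0, 1))
#' st <- generate_study(spec, truth, seed = 1)
#' dim(st$expr)
generate_study <- function(spec, truth, batches = NULL, seed) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(truth, "effect_truth"))
  n <- spec$n_samples
  n_batch <- length(spec$batch_sizes)
  G <- nrow(truth)
  if (is.null(batches)) batches <- batch_effects(n_batch, G)
  if (batches$n_batches != n_batch)
    stop("batch count mismatch: spec has ", n_batch, " batches, batches has ",
         batches$n_batches)
  if (ncol(batches$location) != G)
    stop("gene universe mismatch between truth and batches")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  ## sample sheet
  sex <- c(rep("M", spec$n_male), rep("F", n - spec$n_male))
  age <- numeric(n)
  age[sex == "M"] <- runif(spec$n_male, spec$age_range_male[1],
                           spec$age_range_male[2])
  age[sex == "F"] <- runif(n - spec$n_male, spec$age_range_female[1],
                           spec$age_range_female[2])
  smoking <- sample(names(spec$smoking_levels), n, replace = TRUE,
                    prob = spec$smoking_levels)
  batch <- sample(rep(seq_len(n_batch), spec$batch_sizes))
  samples <- data.frame(
    sample_id = sprintf("%s_S%04d", spec$name, seq_len(n)),
    sex = sex, age_years = round(age, 1), smoking = smoking,
    batch = paste0("b", batch), cohort = spec$name,
    stringsAsFactors = FALSE)

  ## per-gene mean matrix (samples x genes)
  male <- as.numeric(sex == "M")
  mu <- matrix(truth$baseline_log2, n, G, byrow = TRUE)
  mu <- mu + outer(male, truth$sex_log2fc)
  mu <- mu + outer(samples$age_years, truth$age_slope)
  smk <- attr(truth, "smoking_shift")
  if (!is.null(smk)) {
    for (lev in colnames(smk))
      mu[smoking == lev, ] <- sweep(mu[smoking == lev, , drop = FALSE], 2,
                                    smk[, lev], "+")
  }
  mu <- mu + batches$location[batch, , drop = FALSE]
  sd_mat <- sweep(batches$scale[batch, , drop = FALSE], 2,
                  truth$residual_sd, "*")

  ## Y-linked genes: females at background intensity (location shift and
  ## scale still apply; arrays measure background batch-wise too)
  y_genes <- which(truth$chromosome == "Y")
  if (length(y_genes) > 0) {
    fem <- which(sex == "F")
    bg_mean <- attr(truth, "background_mean")
    bg_sd <- attr(truth, "background_sd")
    for (g in y_genes) {
      mu[fem, g] <- bg_mean + batches$location[batch[fem], g]
      sd_mat[fem, g] <- bg_sd * batches$scale[batch[fem], g]
    }
  }

  ## expand genes to probes: extra probes share effects, independent noise
  probe_gene <- rep(seq_len(G), truth$n_probes)
  probe_rank <- unlist(lapply(truth$n_probes, seq_len), use.names = FALSE)
  probe_id <- sprintf("%s_p%d", truth$gene[probe_gene], probe_rank)
  P <- length(probe_id)
  expr <- mu[, probe_gene, drop = FALSE] +
    matrix(rnorm(n * P), n, P) * sd_mat[, probe_gene, drop = FALSE]
  dimnames(expr) <- list(samples$sample_id, probe_id)

  ## detection p-values; later probes of a gene detect less often so the
  ## highest-detection-rate collapse rule has a well-defined winner
  frac <- truth$expressed_fraction[probe_gene] * 0.9^(probe_rank - 1)
  detected <- matrix(runif(n * P), n, P) <
    matrix(frac, n, P, byrow = TRUE)
  detection_p <- matrix(runif(n * P, 0.01, 1), n, P)
  detection_p[detected] <- runif(sum(detected), 0, 0.01)
  dimnames(detection_p) <- dimnames(expr)

  probe_map <- data.frame(
    probe_id = probe_id,
    gene_symbol = truth$gene[probe_gene],
    chromosome = truth$chromosome[probe_gene],
    stringsAsFactors = FALSE)

  structure(list(expr = expr, detection_p = detection_p,
                 samples = samples, probe_map = probe_map),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study:", nrow(x$expr), "samples x", ncol(x$expr),
      "probes (", length(unique(x$probe_map$gene_symbol)), "genes )\n")
  cat("  cohort:", unique(x$samples$cohort), " batches:",
      paste(sort(unique(x$samples$batch)), collapse = ", "), "\n")
  invisible(x)
}

#' Planted truth built from the validated gene catalogs
#'
#' Builds an [effect_truth()] containing the 25 validated sex-associated
#' genes (signed fold changes converted to log2 differences) and the 22
#' validated age-associated genes (per-year slopes used directly), plus a
#' chosen number of null background genes. The planted genes carry their
#' catalog chromosomes (17 X, 1 Y, 2 pseudoautosomal among the sex genes);
#' background genes are spread over the autosomes and X.
#'
#' @param n_background_genes Number of additional genes with all effects
#'   zero.
#' @param seed Integer seed for the randomized baselines and background
#'   annotations.
#' @param residual_sd Residual SD given to the planted genes.
#' @return An [effect_truth()] with `47 + n_background_genes` rows.
#' @export
#' @examples
#' tr <- default_truth_from_tables(0, seed = 1)
#' nrow(tr)                 # 47
#' sum(tr$chromosome == "X")  # 17
default_truth_from_tables <- function(n_background_genes, seed = 1,
                                      residual_sd = 0.2) {
  stopifnot(n_background_genes >= 0)
  sex_cat <- sex_gene_catalog()
  age_cat <- age_gene_catalog()
  signed <- sex_cat$fold_change
  sex_fc <- sign(signed) * log2(abs(signed))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  n_bg <- as.integer(n_background_genes)
  gene <- c(sex_cat$gene, age_cat$gene,
            if (n_bg > 0) sprintf("BG%05d", seq_len(n_bg)))
  chrom <- c(sex_cat$chromosome, age_cat$chromosome,
             if (n_bg > 0) sample(c(as.character(1:22), "X"), n_bg,
                                  replace = TRUE,
                                  prob = c(rep(0.95 / 22, 22), 0.05)))
  n_all <- length(gene)
  baseline <- rnorm(n_all, 8, 1.5)
  tr <- effect_truth(
    gene = gene, chromosome = chrom, baseline_log2 = baseline,
    sex_log2fc = c(sex_fc, rep(0, nrow(age_cat) + n_bg)),
    age_slope = c(rep(0, nrow(sex_cat)), age_cat$estimate, rep(0, n_bg)),
    residual_sd = c(rep(residual_sd, 47), runif(n_bg, 0.1, 0.5)),
    expressed_fraction = c(rep(1, 47),
                           if (n_bg > 0) runif(n_bg, 0.05, 1)))
  ## RPS4Y1-like Y genes: male level sits sex_log2fc above the female
  ## background, so the baseline is anchored at the background mean
  y <- tr$chromosome == "Y"
  tr$baseline_log2[y] <- attr(tr, "background_mean")
  tr
}

#' Cohort designs emulating the study series
#'
#' `discovery_cohort_spec()` describes a 284-sample discovery series
#' (202 males, 82 females, ages 36-85 / 40-83, essentially all smokers,
#' processed in two batches of 206 and 78). `validation_cohort_specs()`
#' returns the three single-batch validation series with balanced sex and
#' mixed smoking status (Laval n = 409, UBC n = 339, Groningen n = 363).
#'
#' @return A [cohort_spec()], or a named list of three.
#' @export
discovery_cohort_spec <- function() {
  cohort_spec("discovery", 284, 202,
              age_range_male = c(36, 85), age_range_female = c(40, 83),
              smoking_levels = c(current = 283 / 284, never = 1 / 284),
              batch_sizes = c(206, 78))
}

#' @rdname discovery_cohort_spec
#' @export
validation_cohort_specs <- function() {
  list(
    laval = cohort_spec("laval", 409, 229,
                        age_range_male = c(30, 82),
                        age_range_female = c(33, 84),
                        smoking_levels = c(current = 90, former = 283,
                                           never = 36) / 409),
    ubc = cohort_spec("ubc", 339, 182,
                      age_range_male = c(11, 85),
                      age_range_female = c(4, 82),
                      smoking_levels = c(current = 98, former = 163,
                                         never = 26, unknown = 52) / 339),
    groningen = cohort_spec("groningen", 363, 193,
                            age_range_male = c(6, 83),
                            age_range_female = c(8, 75),
                            smoking_levels = c(current = 57, former = 185,
                                               never = 100, unknown = 21) / 363)
  )
}
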