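#' Association analysis configuration
#'
#' @param variable `"sex"` (dichotomous, female = 0 / male = 1) or `"age"`
#'   (continuous, years).
#' @param covariates Character vector of sample-sheet columns to adjust
#'   for (e.g. `"smoking"`), or empty. Categorical covariates enter as
#'   indicator columns; for smoking the reference level is never-smoker
#'   and samples with smoking `"unknown"` (or `NA` in any covariate) are
#'   dropped with a message.
#' @param fdr_threshold Significance threshold on the BH-adjusted p-value.
#' @return An object of class `association_config`.
#' @export
association_config <- function(variable = c("sex", "age"),
                               covariates = character(),
                               fdr_threshold = 0.05) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  structure(list(variable = match.arg(variable),
                 covariates = as.character(covariates),
                 fdr_threshold = fdr_threshold),
            class = "association_config")
}

## ---- design construction -------------------------------------------------

## Returns list(X = design matrix with intercept first and the variable of
## interest second, keep = logical of retained samples, var_col = 2)
.build_design <- function(samples, cfg) {
  for (col in c(cfg$variable, cfg$covariates)) {
    col <- if (col == "sex") "sex" else if (col == "age") "age_years" else col
    if (!col %in% names(samples))
      stop("sample sheet lacks column '", col, "'")
  }
  keep <- rep(TRUE, nrow(samples))
  if ("smoking" %in% cfg$covariates)
    keep <- keep & !is.na(samples$smoking) & samples$smoking != "unknown"
  for (col in cfg$covariates)
    if (col != "smoking") keep <- keep & !is.na(samples[[col]])
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " sample(s) dropped for missing/unknown covariates")
  s <- samples[keep, , drop = FALSE]

  v <- if (cfg$variable == "sex") {
    as.numeric(s$sex == "M")
  } else {
    as.numeric(s$age_years)
  }
  if (length(unique(v)) < 2) stop("variable of interest is constant")
  X <- cbind("(Intercept)" = 1, variable = v)
  for (col in cfg$covariates) {
    x <- s[[col]]
    if (is.numeric(x)) {
      X <- cbind(X, setNames(data.frame(x), col))
    } else {
      levs <- unique(as.character(x))
      levs <- c(intersect("never", levs), sort(setdiff(levs, "never")))
      f <- factor(as.character(x), levels = levs)
      if (nlevels(f) > 1) {
        mm <- model.matrix(~ f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(col, "_", levels(f)[-1])
        X <- cbind(X, mm)
      }
    }
  }
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X) + 1)
    stop("too few samples for the design (need n > p + 1)")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  list(X = X, keep = keep, var_col = 2L)
}

## ---- matrix OLS ----------------------------------------------------------

## OLS of every column of Y on X; returns the coefficient of interest with
## classical (unmoderated) standard errors and two-sided t-test p-values.
.ols_matrix <- function(X, Y, coef = 2L) {
  n <- nrow(X); p <- ncol(X)
  XtXinv <- solve(crossprod(X))
  B <- XtXinv %*% crossprod(X, Y)              # p x genes
  res <- Y - X %*% B
  df <- n - p
  sigma2 <- colSums(res^2) / df
  beta <- B[coef, ]
  se <- sqrt(sigma2 * XtXinv[coef, coef])
  t_stat <- beta / se
  p_value <- 2 * pt(-abs(t_stat), df)
  list(beta = beta, se = se, t_stat = t_stat, p_value = p_value, df = df)
}

## ---- user-facing operations ---------------------------------------------

#' Per-gene linear-model association
#'
#' Fits, for each gene, ordinary least squares of log2 expression on an
#' intercept, the variable of interest (sex or age), and any configured
#' covariates. The t statistic is beta/se at the residual degrees of
#' freedom, the p-value is two-sided, and the FDR column is the
#' Benjamini-Hochberg adjustment across all tested genes. For sex, the
#' coefficient is the male-minus-female log2 difference and a signed fold
#' change is reported (values > 1 mean higher in males, -r means r-fold
#' higher in females); for age it is the log2 change per year.
#'
#' @param gm A `gene_matrix`.
#' @param cfg An [association_config()].
#' @return A data.frame of class `association_table` with columns `gene`,
#'   `beta`, `se`, `t_stat`, `p_value`, `fdr`, `signed_fc` (NA for age),
#'   `direction` (sign of beta); attribute `variable` records the tested
#'   variable.
#' @export
#' @examples
#' spec <- cohort_spec("toy", 60, 30, c(40, 80), c(40, 80))
#' truth <- effect_truth(paste0("G", 1:50), "1",
#'                       sex_log2fc = c(1.5, rep(0, 49)))
#' gm <- collapse_probes(generate_study(spec, truth, seed = 1))
#' head(fit_associations(gm, association_config("sex")))
fit_associations <- function(gm, cfg) {
  stopifnot(inherits(gm, "gene_matrix"), inherits(cfg, "association_config"))
  d <- .build_design(gm$samples, cfg)
  Y <- gm$expr[d$keep, , drop = FALSE]
  fit <- .ols_matrix(d$X, Y, d$var_col)
  fdr <- bh_adjust(fit$p_value)
  out <- data.frame(
    gene = colnames(Y),
    beta = unname(fit$beta),
    se = unname(fit$se),
    t_stat = unname(fit$t_stat),
    p_value = unname(fit$p_value),
    fdr = unname(fdr),
    signed_fc = if (cfg$variable == "sex") signed_fold_change(unname(fit$beta))
                else NA_real_,
    direction = sign(unname(fit$beta)),
    stringsAsFactors = FALSE)
  attr(out, "variable") <- cfg$variable
  attr(out, "n_samples") <- nrow(Y)
  class(out) <- c("association_table", "data.frame")
  out
}

#' Signed fold change from a log2 difference
#'
#' Maps a log2 difference to the signed-fold convention: `2^beta` when
#' `beta >= 0`, `-2^(-beta)` otherwise, so values > 1 mean higher
#' expression in the first group and -r means r-fold higher in the second.
#' [log2_from_signed_fc()] is the exact inverse.
#'
#' @param beta_log2 Numeric vector of log2 differences.
#' @return Numeric vector in (-Inf, -1] U [1, Inf).
#' @export
#' @examples
#' signed_fold_change(c(0, 1, -1))   # 1, 2, -2
signed_fold_change <- function(beta_log2) {
  ifelse(beta_log2 >= 0, 2^beta_log2, -2^(-beta_log2))
}

#' @rdname signed_fold_change
#' @param fc Signed fold changes as produced by [signed_fold_change()].
#' @export
log2_from_signed_fc <- function(fc) {
  sign(fc) * log2(abs(fc))
}

#' Benjamini-Hochberg adjustment
#'
#' Classic step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and returned in the
#' original order. Calls [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (q-values), same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}
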