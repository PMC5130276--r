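# Shared fixtures and independent oracles. The oracles re-derive each
# statistic from its definition and stay ignorant of the package internals.

# gene-level matrix with given per-gene male-minus-female log2 differences
# and/or per-year age slopes; residual noise sd constant across genes
make_gene_matrix <- function(n_male, n_female, effects_sex = NULL,
                             effects_age = NULL, n_null = 50, sd = 0.3,
                             age_range = c(36, 85), cohort = "toy",
                             seed = 1, smoking_levels = c(current = 1)) {
  set.seed(seed)
  genes <- c(names(effects_sex), names(effects_age),
             if (n_null > 0) sprintf("NULL%04d", seq_len(n_null)))
  fc <- c(unname(effects_sex), rep(0, length(effects_age)), rep(0, n_null))
  sl <- c(rep(0, length(effects_sex)), unname(effects_age), rep(0, n_null))
  n <- n_male + n_female
  sex <- rep(c("M", "F"), c(n_male, n_female))
  age <- runif(n, age_range[1], age_range[2])
  smoking <- sample(names(smoking_levels), n, TRUE, prob = smoking_levels)
  male <- as.numeric(sex == "M")
  mu <- matrix(8, n, length(genes)) + outer(male, fc) + outer(age, sl)
  expr <- mu + matrix(rnorm(n * length(genes), 0, sd), n)
  dimnames(expr) <- list(sprintf("%s_S%03d", cohort, 1:n), genes)
  structure(list(
    expr = expr,
    samples = data.frame(sample_id = rownames(expr), sex = sex,
                         age_years = age, smoking = smoking, batch = "b1",
                         cohort = cohort, stringsAsFactors = FALSE),
    genes = data.frame(gene = genes, chromosome = "1",
                       probe_id = paste0(genes, "_p1"), detection_rate = 1,
                       stringsAsFactors = FALSE)),
    class = "gene_matrix")
}

# hand-buildable probe-level study
make_study <- function(expr, detection_p, sex, gene_symbol,
                       chromosome = "1", age = NULL, batch = "b1") {
  n <- nrow(expr)
  probe_id <- colnames(expr)
  structure(list(
    expr = expr, detection_p = detection_p,
    samples = data.frame(sample_id = rownames(expr) %||% paste0("S", 1:n),
                         sex = sex,
                         age_years = age %||% runif(n, 40, 80),
                         smoking = "current",
                         batch = rep_len(batch, n), cohort = "manual",
                         stringsAsFactors = FALSE),
    probe_map = data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
                           chromosome = rep_len(chromosome, length(probe_id)),
                           stringsAsFactors = FALSE)),
    class = "expression_study")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- oracles ---------------------------------------------------------------

# Benjamini-Hochberg by direct enumeration of the step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[ord[i]] <- min(1, min(p[ord[js]] * m / js))
  }
  q
}

# pooled-variance two-sample t statistic
two_sample_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# enrichment score by literal position-by-position walk of the ranking
es_oracle <- function(scores, hit, weight = 0) {
  N <- length(scores)
  k <- sum(hit)
  w <- if (weight == 0) rep(1, N) else abs(scores)^weight
  tot <- sum(w[hit])
  rs <- numeric(N)
  s <- 0
  for (i in seq_len(N)) {
    s <- if (hit[i]) s + w[i] / tot else s - 1 / (N - k)
    rs[i] <- s
  }
  extreme <- if (abs(max(rs)) >= abs(min(rs))) max(rs) else min(rs)
  extreme
}
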