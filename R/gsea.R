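#' Rank genes by association t statistic
#'
#' Sorts genes in descending order of the t statistic, breaking ties by
#' gene symbol so the ranking is deterministic.
#'
#' @param assoc An `association_table`.
#' @return A data.frame with columns `gene` and `score` (the t statistic),
#'   ordered from most male-/age-up-regulated to most down-regulated.
#' @export
rank_genes <- function(assoc) {
  stopifnot(inherits(assoc, "association_table"))
  if (any(!is.finite(assoc$t_stat))) stop("t statistics must be finite")
  ord <- order(-assoc$t_stat, assoc$gene)
  data.frame(gene = assoc$gene[ord], score = assoc$t_stat[ord],
             stringsAsFactors = FALSE)
}

#' Restrict a gene-set collection to a universe and size window
#'
#' Set membership is intersected with the analysis universe first; a set is
#' retained iff its post-intersection size lies in
#' `[min_size, max_size]` (inclusive).
#'
#' @param collection A `gene_set_collection` from [read_gmt()] or
#'   [gene_set_collection()].
#' @param universe Character vector of analyzable genes.
#' @param min_size,max_size Inclusive size bounds (defaults 15 and 500).
#' @return The filtered `gene_set_collection`.
#' @export
filter_sets <- function(collection, universe, min_size = 15, max_size = 500) {
  stopifnot(inherits(collection, "gene_set_collection"),
            min_size <= max_size)
  sets <- lapply(collection$sets, intersect, y = universe)
  size <- lengths(sets)
  keep <- size >= min_size & size <= max_size
  gene_set_collection(sets[keep], source = collection$source)
}

#' Kolmogorov-Smirnov running-sum enrichment score
#'
#' Walks down the ranking, incrementing the running sum by
#' `|score|^weight / sum(|scores in set|^weight)` at set members and
#' decrementing by `1/(N - N_set)` elsewhere; the enrichment score is the
#' running-sum extremum (signed). `weight = 0` gives the classic
#' Kolmogorov-Smirnov form (equal increments `1/N_set`). The leading edge
#' is the set members at or before the extremum for positive scores, and
#' at or after it for negative scores.
#'
#' @param ranked A ranking from [rank_genes()] (or any data.frame with
#'   `gene` and `score` ordered by decreasing score).
#' @param set_members Character vector of member genes (non-empty, proper
#'   subset of the ranking).
#' @param weight Non-negative exponent on the scores (default 0).
#' @return A list with `es`, `running_sum` (length N), `leading_edge`.
#' @export
enrichment_score <- function(ranked, set_members, weight = 0) {
  genes <- ranked$gene
  N <- length(genes)
  hit <- genes %in% set_members
  k <- sum(hit)
  if (k == 0) stop("empty gene set (no members in the ranking)")
  if (k == N) stop("gene set equals the whole universe")
  inc <- if (weight == 0) rep(1 / k, N) else abs(ranked$score)^weight
  inc[!hit] <- 0
  inc <- inc / sum(inc)
  dec <- rep(1 / (N - k), N)
  dec[hit] <- 0
  rs <- cumsum(inc - dec)
  i_max <- which.max(rs); i_min <- which.min(rs)
  es <- if (abs(rs[i_max]) >= abs(rs[i_min])) rs[i_max] else rs[i_min]
  leading <- if (es >= 0) genes[hit & seq_len(N) <= i_max]
             else genes[hit & seq_len(N) >= i_min]
  list(es = es, running_sum = rs, leading_edge = leading)
}

## Fast ES from sorted hit positions; algebraically identical to the
## cumsum walk in enrichment_score() but O(k) per set, for permutations.
## pos: sorted rank positions of the set's members; w: matching |score|^weight
## (ignored when weight == 0); N: universe size.
.es_from_positions <- function(pos, N, w = NULL) {
  k <- length(pos)
  i <- seq_len(k)
  cw <- if (is.null(w)) i / k else cumsum(w) / sum(w)
  miss_before <- (pos - i) / (N - k)
  after <- cw - miss_before                    # running sum just after hit i
  before <- c(0, cw[-k]) - miss_before         # just before hit i
  hi <- max(after)
  lo <- min(before)
  if (abs(hi) >= abs(lo)) hi else lo
}

#' Gene set enrichment with phenotype-permutation significance
#'
#' Computes the observed enrichment score of every set on the ranking
#' induced by the per-gene association t statistics, then builds a null by
#' shuffling the variable of interest across samples, refitting the
#' per-gene models, re-ranking, and recomputing every set's score. The
#' permutation p-value is the add-one-corrected fraction of null scores at
#' least as extreme in absolute value; the normalized score divides the
#' observed score by the mean |null score| of matching sign; FDR is the
#' Benjamini-Hochberg adjustment across all tested sets.
#'
#' @param gm A `gene_matrix`.
#' @param cfg An [association_config()].
#' @param collection A `gene_set_collection`, typically already passed
#'   through [filter_sets()] against the matrix genes.
#' @param n_permutations Number of phenotype shuffles (>= 1; >= 100
#'   recommended).
#' @param seed Integer seed.
#' @param weight Score exponent passed to the running sum (default 0, the
#'   classic Kolmogorov-Smirnov statistic).
#' @return An object of class `enrichment_result`: data.frame with columns
#'   `set`, `es`, `nes`, `p_value`, `fdr`, `size_after_filter`; attribute
#'   `leading_edge` is a named list of gene vectors.
#' @export
enrichment_significance <- function(gm, cfg, collection, n_permutations,
                                    seed, weight = 0) {
  stopifnot(inherits(gm, "gene_matrix"),
            inherits(collection, "gene_set_collection"))
  if (n_permutations < 1)
    stop("n_permutations must be >= 1 (>= 100 recommended)")
  sets <- lapply(collection$sets, intersect, y = colnames(gm$expr))
  if (any(lengths(sets) == 0)) stop("set(s) with no genes in the matrix")

  d <- .build_design(gm$samples, cfg)
  Y <- gm$expr[d$keep, , drop = FALSE]
  X <- d$X
  genes <- colnames(Y)
  N <- length(genes)
  set_idx <- lapply(sets, match, table = genes)

  score_all_sets <- function(t_stat) {
    ord <- order(-t_stat, genes)
    rank_of <- integer(N); rank_of[ord] <- seq_len(N)
    abs_sorted <- abs(t_stat)[ord]
    vapply(set_idx, function(ix) {
      pos <- sort(rank_of[ix])
      w <- if (weight == 0) NULL else abs_sorted[pos]^weight
      .es_from_positions(pos, N, w)
    }, numeric(1))
  }

  obs_fit <- .ols_matrix(X, Y, d$var_col)
  es_obs <- score_all_sets(obs_fit$t_stat)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  null_es <- matrix(NA_real_, n_permutations, length(sets))
  n <- nrow(X)
  for (b in seq_len(n_permutations)) {
    idx <- sample.int(n)
    Xp <- X
    Xp[, d$var_col] <- X[idx, d$var_col]
    null_es[b, ] <- score_all_sets(.ols_matrix(Xp, Y, d$var_col)$t_stat)
  }

  p_value <- vapply(seq_along(sets), function(j)
    (1 + sum(abs(null_es[, j]) >= abs(es_obs[j]))) / (n_permutations + 1),
    numeric(1))
  nes <- vapply(seq_along(sets), function(j) {
    same <- null_es[, j] * sign(es_obs[j]) > 0
    if (!any(same)) return(NA_real_)
    es_obs[j] / mean(abs(null_es[same, j]))
  }, numeric(1))

  ## leading edges from the observed ranking
  obs_rank <- data.frame(gene = genes, score = obs_fit$t_stat)[
    order(-obs_fit$t_stat, genes), ]
  leading <- lapply(sets, function(s)
    enrichment_score(obs_rank, s, weight)$leading_edge)

  out <- data.frame(set = names(sets), es = unname(es_obs),
                    nes = unname(nes), p_value = unname(p_value),
                    fdr = bh_adjust(p_value),
                    size_after_filter = unname(lengths(sets)),
                    stringsAsFactors = FALSE)
  attr(out, "leading_edge") <- leading
  attr(out, "n_permutations") <- n_permutations
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Overlap coefficient between two sets
#'
#' `|A intersect B| / min(|A|, |B|)`; 0 when either set is empty.
#' @param a,b Character vectors.
#' @return A number in \[0, 1\].
#' @export
overlap_coefficient <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(0)
  length(intersect(a, b)) / min(length(unique(a)), length(unique(b)))
}

#' Build an enrichment-map graph of significant gene sets
#'
#' Nodes are sets with FDR below `fdr_cutoff` (node attribute `size` =
#' set size); an edge connects two sets when their overlap coefficient
#' `|A intersect B| / min(|A|, |B|)` is at least `overlap_cutoff`
#' (inclusive), with edge attributes `weight` (shared-gene count) and
#' `overlap` (the coefficient). Connected components of the graph surface
#' clusters of functionally related sets.
#'
#' @param result An `enrichment_result`.
#' @param collection The matching `gene_set_collection`.
#' @param fdr_cutoff FDR threshold for inclusion (default 0.05).
#' @param overlap_cutoff Minimum overlap coefficient (default 0.5).
#' @return An [igraph::graph] with no self-edges.
#' @export
build_enrichment_map <- function(result, collection, fdr_cutoff = 0.05,
                                 overlap_cutoff = 0.5) {
  stopifnot(inherits(result, "enrichment_result"))
  sig <- result$set[result$fdr < fdr_cutoff]
  if (!all(sig %in% names(collection$sets)))
    stop("result and collection set names disagree")
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(sig), name = sig,
                            size = lengths(collection$sets[sig]))
  if (length(sig) >= 2) {
    pairs <- utils::combn(sig, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- collection$sets[[pairs[1, j]]]
      b <- collection$sets[[pairs[2, j]]]
      oc <- overlap_coefficient(a, b)
      if (oc >= overlap_cutoff)
        g <- igraph::add_edges(g, pairs[, j],
                               weight = length(intersect(a, b)),
                               overlap = oc)
    }
  }
  g
}
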