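fake_assoc <- function(genes, t) {
  out <- data.frame(gene = genes, beta = t, se = 1, t_stat = t,
                    p_value = 2 * pt(-abs(t), 50), stringsAsFactors = FALSE)
  out$fdr <- out$p_value  # single-purpose fixture; adjustment irrelevant here
  out$signed_fc <- NA_real_
  out$direction <- sign(t)
  class(out) <- c("association_table", "data.frame")
  out
}

test_that("genes rank by descending t with alphabetical tie-break", {
  a <- fake_assoc(c("A", "B", "C"), c(2, -1, 0.5))
  expect_identical(rank_genes(a)$gene, c("A", "C", "B"))
  b <- fake_assoc(c("Z", "Q"), c(1, 1))
  expect_identical(rank_genes(b)$gene, c("Q", "Z"))
  # reversing all signs reverses a tie-free ranking exactly
  set.seed(51)
  cc <- fake_assoc(sprintf("G%02d", 1:20), rnorm(20))
  expect_identical(rank_genes(fake_assoc(cc$gene, -cc$t_stat))$gene,
                   rev(rank_genes(cc)$gene))
  expect_error(rank_genes(fake_assoc("A", NaN)), "finite")
})

test_that("set filtering intersects with the universe before sizing", {
  coll <- gene_set_collection(list(
    big = sprintf("U%03d", 1:600),    # 400 in universe -> kept
    small = sprintf("U%03d", 1:14),   # 14 in universe -> removed
    edge15 = sprintf("U%03d", 1:15),  # boundary inclusive
    out = sprintf("V%03d", 1:100)))   # 0 in universe
  universe <- sprintf("U%03d", 1:400)
  kept <- filter_sets(coll, universe, 15, 500)
  expect_setequal(names(kept$sets), c("big", "edge15"))
  expect_equal(length(kept$sets$big), 400)
  expect_length(filter_sets(coll, character(), 15, 500)$sets, 0)
})

test_that("running-sum score matches the literal enumeration oracle", {
  set.seed(52)
  for (i in 1:60) {
    N <- sample(5:15, 1)
    k <- sample(1:min(5, N - 1), 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    genes <- sprintf("g%02d", 1:N)
    members <- sample(genes, k)
    ranked <- data.frame(gene = genes, score = scores)
    for (w in c(0, 1)) {
      got <- enrichment_score(ranked, members, weight = w)
      want <- es_oracle(scores, genes %in% members, weight = w)
      expect_equal(got$es, want, tolerance = 1e-12)
      expect_length(got$running_sum, N)
    }
  }
})

test_that("a set concentrated at the top scores near its maximum", {
  N <- 20; k <- 5
  genes <- sprintf("g%02d", 1:N)
  ranked <- data.frame(gene = genes, score = seq(3, -3, length.out = N))
  got <- enrichment_score(ranked, genes[1:k], weight = 0)
  expect_equal(got$es, es_oracle(ranked$score, seq_len(N) <= k))
  expect_equal(got$es, 1 - 0 / (N - k))  # all hits before any miss
  expect_setequal(got$leading_edge, genes[1:k])
})

test_that("complement symmetry holds for the unweighted statistic", {
  set.seed(53)
  N <- 12
  genes <- sprintf("g%02d", 1:N)
  ranked <- data.frame(gene = genes, score = sort(rnorm(N), decreasing = TRUE))
  members <- sample(genes, 4)
  es_a <- enrichment_score(ranked, members, weight = 0)$es
  es_b <- enrichment_score(ranked, setdiff(genes, members), weight = 0)$es
  expect_equal(abs(es_a), abs(es_b), tolerance = 1e-12)
})

test_that("degenerate sets are refused", {
  ranked <- data.frame(gene = c("a", "b"), score = c(1, 0))
  expect_error(enrichment_score(ranked, character()), "empty")
  expect_error(enrichment_score(ranked, c("a", "b")), "universe")
})

test_that("scores agree with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(54)
  N <- 80
  genes <- sprintf("g%02d", 1:N)
  scores <- sort(rnorm(N), decreasing = TRUE)
  ranked <- data.frame(gene = genes, score = scores)
  for (w in c(0, 1)) {
    for (i in 1:10) {
      pos <- sort(sample(N, sample(3:20, 1)))
      ours <- enrichment_score(ranked, genes[pos], weight = w)$es
      ref <- fgsea::calcGseaStat(setNames(scores, genes),
                                 selectedStats = pos, gseaParam = w)
      expect_equal(ours, ref, tolerance = 1e-12)
    }
  }
})

test_that("phenotype permutation finds a planted age-driven set", {
  hits <- vapply(1:5, function(i) {
    gm <- make_gene_matrix(30, 30,
                           effects_age = setNames(rep(0.04, 20),
                                                  sprintf("SET%02d", 1:20)),
                           n_null = 400, sd = 0.4, seed = 60 + i)
    coll <- gene_set_collection(list(
      planted = sprintf("SET%02d", 1:20),
      decoy = sprintf("NULL%04d", 1:30)))
    res <- enrichment_significance(gm, association_config("age"), coll,
                                   n_permutations = 200, seed = 70 + i)
    res$fdr[res$set == "planted"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("on null data the permutation p-values are well calibrated", {
  gm <- make_gene_matrix(25, 25, n_null = 300, sd = 0.3, seed = 81)
  sets <- lapply(1:40, function(i)
    sample(colnames(gm$expr), 25))
  names(sets) <- sprintf("S%02d", 1:40)
  res <- enrichment_significance(gm, association_config("sex"),
                                 gene_set_collection(sets),
                                 n_permutations = 200, seed = 82)
  frac <- mean(res$p_value < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
  expect_true(all(abs(res$es) <= 1))
  expect_error(enrichment_significance(gm, association_config("sex"),
                                       gene_set_collection(sets),
                                       n_permutations = 0, seed = 1),
               "n_permutations")
})

test_that("permutation p-values are distributionally stable across seeds", {
  gm <- make_gene_matrix(20, 20, n_null = 200, sd = 0.3, seed = 83)
  sets <- lapply(1:25, function(i) sample(colnames(gm$expr), 20))
  names(sets) <- sprintf("S%02d", 1:25)
  coll <- gene_set_collection(sets)
  p1 <- enrichment_significance(gm, association_config("sex"), coll,
                                n_permutations = 150, seed = 84)$p_value
  p2 <- enrichment_significance(gm, association_config("sex"), coll,
                                n_permutations = 150, seed = 985)$p_value
  expect_gt(suppressWarnings(ks.test(p1, p2))$p.value, 0.001)
})

test_that("the enrichment map connects sets by overlap coefficient", {
  res <- data.frame(set = c("A", "B", "C", "D"),
                    es = c(0.8, 0.7, 0.6, 0.5), nes = 1,
                    p_value = c(0.001, 0.001, 0.001, 0.9),
                    fdr = c(0.01, 0.01, 0.01, 0.9),
                    size_after_filter = c(10, 20, 10, 5))
  class(res) <- c("enrichment_result", "data.frame")
  coll <- gene_set_collection(list(
    A = sprintf("x%02d", 1:10),          # subset of B
    B = sprintf("x%02d", 1:20),
    C = c(sprintf("x%02d", 16:20), sprintf("y%02d", 1:5)),  # 5/min(10,20)=0.5
    D = sprintf("z%02d", 1:5)))          # not significant
  g <- build_enrichment_map(res, coll, fdr_cutoff = 0.05,
                            overlap_cutoff = 0.5)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))   # D excluded
  edges <- igraph::as_data_frame(g)
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  expect_true("A B" %in% key)            # containment -> coefficient 1
  expect_true("B C" %in% key)            # exactly at the 0.5 cutoff
  expect_false("A C" %in% key)           # disjoint
  expect_false(any(edges$from == edges$to))
  expect_equal(edges$weight[key == "B C"], 5)
  # connected components partition the nodes
  comp <- igraph::components(g)
  expect_equal(sum(comp$csize), igraph::vcount(g))
})
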