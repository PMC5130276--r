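make_detection_study <- function(det_counts, gene_symbol,
                                 probe_id = NULL, n = 100) {
  # det_counts: per-probe number of samples with detection p < 0.01
  P <- length(det_counts)
  probe_id <- probe_id %||% sprintf("P%03d", seq_len(P))
  detp <- sapply(det_counts, function(k) c(rep(0.001, k), rep(0.5, n - k)))
  expr <- matrix(rnorm(n * P, 8), n, P)
  dimnames(expr) <- list(paste0("S", 1:n), probe_id)
  dimnames(detp) <- dimnames(expr)
  make_study(expr, detp, sex = rep(c("M", "F"), length.out = n),
             gene_symbol = gene_symbol)
}

test_that("detection filter keeps the 10% boundary and drops below it", {
  st <- make_detection_study(c(10, 9, 100), c("A", "B", "C"))
  out <- filter_probes(st)
  expect_identical(out$probe_map$gene_symbol, c("A", "C"))  # 9/100 removed
  expect_identical(dim(out$expr), dim(out$detection_p))
})

test_that("unannotated probes are removed even when always detected", {
  st <- make_detection_study(c(100, 100, 100), c("A", NA, ""))
  out <- filter_probes(st)
  expect_identical(out$probe_map$probe_id, "P001")
})

test_that("filtering everything warns rather than errors", {
  st <- make_detection_study(c(2, 3), c("A", "B"))
  expect_warning(out <- filter_probes(st), "all probes removed")
  expect_equal(ncol(out$expr), 0)
})

test_that("collapse keeps the highest-detection probe, ties by probe id", {
  st <- make_detection_study(c(95, 80, 90, 90, 70),
                             c("G1", "G1", "G2", "G2", "G3"),
                             probe_id = c("P010", "P011", "P002", "P001",
                                          "P020"))
  gm <- collapse_probes(st)
  expect_identical(gm$genes$gene, c("G1", "G2", "G3"))
  expect_identical(gm$genes$probe_id, c("P010", "P001", "P020"))
  expect_equal(gm$genes$detection_rate, c(0.95, 0.90, 0.70))
  # single-probe gene: column equals the probe values
  expect_identical(unname(gm$expr[, "G3"]), unname(st$expr[, "P020"]))
})

test_that("filter then collapse is idempotent on its own output", {
  st <- make_detection_study(c(95, 80, 90, 50), c("G1", "G1", "G2", "G2"))
  once <- collapse_probes(filter_probes(st))
  st2 <- st
  keep <- match(once$genes$probe_id, st$probe_map$probe_id)
  st2$expr <- st$expr[, keep, drop = FALSE]
  st2$detection_p <- st$detection_p[, keep, drop = FALSE]
  st2$probe_map <- st$probe_map[keep, ]
  twice <- collapse_probes(filter_probes(st2))
  expect_equal(once$expr, twice$expr)
  expect_equal(once$genes, twice$genes, ignore_attr = TRUE)
})

test_that("quantile normalization matches the order-statistic means", {
  gm <- make_gene_matrix(1, 1, n_null = 3, seed = 4)
  gm$expr <- matrix(c(1, 4, 2, 5, 3, 6), 2, 3,
                    dimnames = list(c("a", "b"), c("G1", "G2", "G3")))
  gm$samples <- gm$samples[1:2, ]
  out <- quantile_normalize(gm)
  expect_equal(unname(out$expr), rbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
})

test_that("quantile normalization is idempotent and equalizes distributions", {
  gm <- make_gene_matrix(10, 10, n_null = 200, seed = 5)
  gm$expr <- gm$expr + runif(nrow(gm$expr))  # sample-specific shifts
  once <- quantile_normalize(gm)
  twice <- quantile_normalize(once)
  expect_equal(once$expr, twice$expr, tolerance = 1e-12)
  sorted <- apply(once$expr, 1, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
})

test_that("single-sample input is returned unchanged", {
  gm <- make_gene_matrix(1, 1, n_null = 10, seed = 6)
  gm$expr <- gm$expr[1, , drop = FALSE]
  gm$samples <- gm$samples[1, ]
  expect_identical(quantile_normalize(gm)$expr, gm$expr)
})

make_batched_matrix <- function(n1, n2, n_genes, loc = 0, scale = 1,
                                sex_fc = 0, seed = 1) {
  spec <- cohort_spec("b", n1 + n2, floor((n1 + n2) / 2), c(40, 80),
                      c(40, 80), batch_sizes = c(n1, n2))
  truth <- effect_truth(sprintf("G%04d", seq_len(n_genes)), "1",
                        sex_log2fc = sex_fc, residual_sd = 0.3)
  bat <- batch_effects(2, n_genes, location = c(0, loc), scale = c(1, scale))
  collapse_probes(generate_study(spec, truth, bat, seed = seed))
}

test_that("near-null data pass through batch adjustment nearly unchanged", {
  gm <- make_batched_matrix(100, 50, 200, loc = 0, scale = 1, seed = 31)
  adj <- combat_adjust(gm)
  rms <- sqrt(mean((adj$expr - gm$expr)^2))
  expect_lt(rms, 0.05)
})

test_that("a planted location shift is removed by batch adjustment", {
  gm <- make_batched_matrix(100, 50, 200, loc = 1.0, seed = 32)
  adj <- combat_adjust(gm)
  b <- adj$samples$batch
  delta <- colMeans(adj$expr[b == "b2", ]) - colMeans(adj$expr[b == "b1", ])
  expect_lt(mean(abs(delta)), 0.05)
  # and the shift was really there beforehand
  raw <- colMeans(gm$expr[b == "b2", ]) - colMeans(gm$expr[b == "b1", ])
  expect_gt(mean(raw), 0.9)
})

test_that("identical batches are left essentially untouched", {
  gm <- make_batched_matrix(60, 60, 100, seed = 33)
  gm$expr[gm$samples$batch == "b2", ] <- gm$expr[gm$samples$batch == "b1", ]
  adj <- combat_adjust(gm)
  expect_lt(sqrt(mean((adj$expr - gm$expr)^2)), 0.05)
})

test_that("batch adjustment preconditions are enforced", {
  gm <- make_batched_matrix(60, 60, 50, seed = 34)
  expect_error(combat_adjust(gm, batch = rep("b1", 120)), "2 batches")
  expect_error(combat_adjust(gm, batch = c("b2", rep("b1", 119))),
               "at least 2 samples")
  expect_error(combat_adjust(gm, covariates =
                               as.numeric(gm$samples$batch == "b2")),
               "confounded")
})

test_that("batch adjustment preserves planted sex effects", {
  # paired comparison: recovery error with batch effects + adjustment vs
  # the same draws with no batch effect at all
  err_adj <- err_prot <- err_clean <- numeric(20)
  for (i in 1:20) {
    gm <- make_batched_matrix(60, 40, 60, loc = 1.5, scale = 1.5,
                              sex_fc = c(0.8, rep(0, 59)), seed = 400 + i)
    clean <- make_batched_matrix(60, 40, 60, loc = 0, scale = 1,
                                 sex_fc = c(0.8, rep(0, 59)), seed = 400 + i)
    est <- function(g) {
      male <- g$samples$sex == "M"
      mean(g$expr[male, 1]) - mean(g$expr[!male, 1])
    }
    err_adj[i] <- est(combat_adjust(gm)) - 0.8
    err_prot[i] <- est(combat_adjust(gm, covariates =
                         as.numeric(gm$samples$sex == "M"))) - 0.8
    err_clean[i] <- est(clean) - 0.8
  }
  # protecting the biological covariate gives near-oracle recovery
  expect_lt(mean(abs(err_prot)), 1.3 * mean(abs(err_clean)))
  # the no-covariate default absorbs a little of the effect into the
  # batch means when sex is chance-imbalanced across batches, but the
  # attenuation stays a small fraction of the sampling error
  expect_lt(mean(abs(err_adj)), 1.6 * mean(abs(err_clean)))
  expect_lt(abs(mean(err_adj)), 3 * sd(err_adj) / sqrt(20))  # no gross bias
})

test_that("preprocess_study chains the stages", {
  spec <- cohort_spec("d", 60, 30, c(40, 80), c(40, 80),
                      batch_sizes = c(30, 30))
  truth <- effect_truth(sprintf("G%03d", 1:80), "1",
                        expressed_fraction = c(rep(1, 70), rep(0.02, 10)))
  st <- generate_study(spec, truth, batch_effects(2, 80, location = c(0, 1)),
                       seed = 41)
  gm <- preprocess_study(st)
  expect_lte(ncol(gm$expr), 70)      # barely-detected genes filtered
  b <- gm$samples$batch
  delta <- colMeans(gm$expr[b == "b2", ]) - colMeans(gm$expr[b == "b1", ])
  expect_lt(mean(abs(delta)), 0.1)   # batch shift removed
})
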