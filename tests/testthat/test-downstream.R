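# Clustering, feature ranking, prevalence, association, survival, BH,
# segmentation QC.

test_that("Leiden clustering separates blobs and is deterministic", {
  set.seed(14)
  blob <- rbind(matrix(stats::rnorm(60 * 2, 0), 60, 2),
                matrix(stats::rnorm(60 * 2, 12), 60, 2))
  cl <- cluster_cells(blob, n_neighbours = 40, resolution = 1.0, seed = 0)
  expect_identical(length(unique(cl)), 2L)
  expect_identical(sort(unique(cl)), 0:1)       # contiguous from 0
  # the two blobs are pure
  expect_identical(length(unique(cl[1:60])), 1L)
  expect_identical(length(unique(cl[61:120])), 1L)
  # duplicate rows always co-cluster
  dup <- rbind(blob, blob[1, , drop = FALSE])
  cl_d <- cluster_cells(dup, n_neighbours = 40, resolution = 1.0, seed = 0)
  expect_identical(cl_d[121], cl_d[1])
  # determinism
  expect_identical(cl, cluster_cells(blob, 40, 1.0, seed = 0))
  expect_error(cluster_cells(blob[1:10, ], n_neighbours = 10), "smaller")
})

test_that("rank_features surfaces planted markers and skips degenerates", {
  set.seed(15)
  n <- 90
  clusters <- rep(0:2, each = n / 3)
  f <- matrix(stats::rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("up_in_A", "noise1", "noise2", "flat")))
  f[clusters == 0, "up_in_A"] <- f[clusters == 0, "up_in_A"] + 5
  f[, "flat"] <- 1.0                              # constant feature
  rk <- rank_features(f, clusters)
  tabA <- rk$full[rk$full$cluster_id == 0, ]
  best <- tabA$feature[which.max(tabA$t)]
  expect_identical(best, "up_in_A")
  expect_true(tabA$t[tabA$feature == "up_in_A"] > 0)
  expect_true(tabA$selected[tabA$feature == "up_in_A"])
  expect_false(any(rk$full$selected[rk$full$feature == "flat"]))
  expect_true(all(rk$full$p_adj >= rk$full$p, na.rm = TRUE))
  # top-3 cap
  expect_lte(max(tapply(rk$full$selected, rk$full$cluster_id, sum)), 3)
  # single-cell cluster skipped with a warning
  cl2 <- c(clusters[-1], 99L)
  expect_warning(rank_features(f, cl2), "cluster 99")
  expect_error(rank_features(f, rep(0L, n)), ">= 2 clusters")
})

test_that("prevalence proportions and per-mm2 scaling are exact", {
  clusters <- c(rep(0L, 4), rep(1L, 6))
  sids <- rep("s1", 10)
  pv <- prevalence(clusters, sids, list(s1 = c(1000L, 1000L)))
  expect_equal(pv$proportion[pv$cluster_id == 0], 0.4)
  expect_equal(sum(pv$proportion), 1)
  # 50 cells of one cluster on a 1000x1000 image -> 50 per mm^2
  pv2 <- prevalence(rep(0L, 50), rep("s1", 50), list(s1 = c(1000L, 1000L)))
  expect_equal(pv2$per_mm2, 50)
  # linear in count, inverse in area
  pv3 <- prevalence(rep(0L, 100), rep("s1", 100), list(s1 = c(1000L, 1000L)))
  expect_equal(pv3$per_mm2, 100)
  pv4 <- prevalence(rep(0L, 50), rep("s1", 50), list(s1 = c(2000L, 1000L)))
  expect_equal(pv4$per_mm2, 25)
  # multi-sample: per-sample proportions each sum to 1, zeros included
  pv5 <- prevalence(c(0L, 0L, 1L, 1L, 1L), c("a", "a", "a", "b", "b"),
                    list(a = c(10L, 10L), b = c(10L, 10L)))
  expect_equal(as.numeric(tapply(pv5$proportion, pv5$sample_id, sum)), c(1, 1))
  expect_equal(pv5$n_cells[pv5$sample_id == "b" & pv5$cluster_id == 0], 0L)
})

test_that("associate_latent finds a separating dimension and honours NA rules", {
  set.seed(16)
  ns <- 24
  sids <- sprintf("s%02d", 1:ns)
  grade <- rep(c("high", "low"), each = ns / 2)
  # latent dim 1 tracks grade imperfectly (4 planted mismatches avoid
  # complete separation, which would null the Wald statistic); dim 2 noise
  z1_sample <- ifelse(grade == "high", 1, -1)
  z1_sample[c(1, 2, 13, 14)] <- -z1_sample[c(1, 2, 13, 14)]
  # 3 cells per sample
  z <- cbind(rep(z1_sample, each = 3) + stats::rnorm(3 * ns, 0, 0.1),
             stats::rnorm(3 * ns))
  clinical <- data.frame(sample_id = sids, grade = grade)
  res <- associate_latent(z, rep(sids, each = 3), clinical)
  hi1 <- res[res$category == "high" & res$predictor == "z1", ]
  expect_gt(abs(hi1$t_value), 1)
  expect_lt(hi1$p, 0.05)
  expect_gt(abs(hi1$t_value),
            abs(res$t_value[res$category == "high" & res$predictor == "z2"]))
  # a category with a single sample gets NA rows
  clinical2 <- clinical
  clinical2$grade[1] <- "rare"
  res2 <- associate_latent(z, rep(sids, each = 3), clinical2)
  expect_true(all(is.na(res2$t_value[res2$category == "rare"])))
})

test_that("associate_latent drops aliased dimensions and refits", {
  set.seed(17)
  ns <- 20
  sids <- sprintf("s%02d", 1:ns)
  grade <- rep(c("a", "b"), each = ns / 2)
  base <- stats::rnorm(ns)
  z <- cbind(base, base, stats::rnorm(ns))[rep(1:ns, each = 2), ]
  res <- associate_latent(z, rep(sids, each = 2),
                          data.frame(sample_id = sids, grade = grade))
  # the duplicated dimension is aliased: one of z1/z2 is NA, not both
  sub <- res[res$category == "a", ]
  expect_true(xor(is.na(sub$t_value[sub$predictor == "z1"]),
                  is.na(sub$t_value[sub$predictor == "z2"])))
  expect_false(is.na(sub$t_value[sub$predictor == "z3"]))
})

test_that("associate_proportion signs follow planted enrichment", {
  set.seed(18)
  ns <- 40
  sids <- sprintf("s%02d", 1:ns)
  grade <- rep(c("g3", "g1"), each = ns / 2)
  p0 <- ifelse(grade == "g3", 0.6, 0.2) + stats::runif(ns, -0.05, 0.05)
  dens <- stats::runif(ns, 80, 120)   # per-sample total cell density
  prev <- data.frame(sample_id = rep(sids, each = 2),
                     cluster_id = rep(0:1, ns),
                     proportion = as.vector(rbind(p0, 1 - p0)),
                     per_mm2 = as.vector(rbind(p0 * dens, (1 - p0) * dens)))
  clinical <- data.frame(sample_id = sids, grade = grade)
  res <- associate_proportion(prev, clinical, "proportion")
  expect_gt(res$t_value[res$category == "g3" & res$predictor == "cl0"], 0)
  expect_lt(res$t_value[res$category == "g1" & res$predictor == "cl0"], 0)
  # joint per-mm2 variant fits all clusters together
  res2 <- associate_proportion(prev, clinical, "per_mm2")
  expect_identical(nrow(res2), 4L)
  expect_true(all(is.finite(res2$t_value)))
  # identical proportions across samples -> NA t
  prev_const <- prev
  prev_const$proportion <- rep(c(0.5, 0.5), ns)
  res3 <- associate_proportion(prev_const, clinical, "proportion")
  expect_true(all(is.na(res3$t_value)))
})

test_that("survival analysis recovers signal and validates inputs", {
  set.seed(19)
  ns <- 120
  x <- stats::rnorm(ns)
  sv <- generate_survival(x, log_hr = 1.0, seed = 20, censor_rate = 0.1)
  prev <- data.frame(sample_id = sv$sample_id, cluster_id = 0L,
                     proportion = x, per_mm2 = x * 100)
  clinical <- sv[, c("sample_id", "survival_time", "event_indicator")]
  res <- survival_analysis(prev, clinical, "proportion")
  expect_gt(res$hazard_ratio, 1)
  expect_lt(res$p_adj, 0.01)
  expect_gt(res$concordance, 0.6)
  # concordance of a perfectly rank-predictive covariate ~ 1: with no
  # censoring and a dominant effect, risk ordering matches event times
  sv2 <- generate_survival(seq(-3, 3, length.out = 60), log_hr = 6,
                           seed = 21, censor_rate = 0)
  prev2 <- data.frame(sample_id = sv2$sample_id, cluster_id = 0L,
                      proportion = sv2$x, per_mm2 = sv2$x)
  clin2 <- sv2[, c("sample_id", "survival_time", "event_indicator")]
  res2 <- survival_analysis(prev2, clin2, "proportion")
  expect_gt(res2$concordance, 0.9)
  # error paths
  clin_noev <- clinical; clin_noev$event_indicator <- 0
  expect_error(survival_analysis(prev, clin_noev), "no events")
  clin_bad <- clinical; clin_bad$survival_time[1] <- 0
  expect_error(survival_analysis(prev, clin_bad), "non-positive")
})

test_that("bh_adjust reproduces the step-up reference exactly", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(22)
  for (i in 1:20) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  }
  # NA handling mirrors the reference
  p <- c(0.001, NA, 0.04, 0.9, NA, 0.2)
  expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  # monotone in input ranks
  p <- sort(stats::runif(15))
  expect_true(all(diff(bh_adjust(p)) >= 0))
})

test_that("segmentation QC percentage behaves at its limits", {
  # perfectly anti-correlated pair: nobody is above both medians
  n <- 100
  a <- seq_len(n); b <- rev(a)
  Y <- cbind(A = a, B = b)
  expect_equal(segmentation_qc(Y, list(c("A", "B")))$pct_double_positive, 0)
  # independent continuous proteins: ~25% double positive
  set.seed(23)
  Y2 <- cbind(A = stats::rnorm(4000), B = stats::rnorm(4000))
  pct <- segmentation_qc(Y2, list(c("A", "B")))$pct_double_positive
  expect_gt(pct, 20); expect_lt(pct, 30)
  # all-identical values: strict inequality forces 0%
  Y3 <- cbind(A = rep(1, 50), B = rep(2, 50))
  expect_equal(segmentation_qc(Y3, list(c("A", "B")))$pct_double_positive, 0)
  # default pairs resolve against the synthetic panel
  qc <- segmentation_qc(default_cv()$Y)
  expect_gte(nrow(qc), 3L)
  expect_true(all(qc$pct_double_positive >= 0 & qc$pct_double_positive <= 100))
  expect_error(segmentation_qc(Y2, list(c("A", "missing"))), "not in panel")
})

test_that("planted outcome-linked phenotype attains the largest |t| end-to-end", {
  # small many-sample synthetic world so sample-level association has power
  gen <- cache_get("gen_assoc", function()
    generate_synthetic(synthetic_spec(
      n_samples = 24L, grid = c(64L, 64L), cells_per_sample = 30L,
      clinical_effect = 30, seed = 42L)))
  tp <- truth_prevalence(gen$truth)
  prev <- data.frame(sample_id = tp$sample_id, cluster_id = tp$type - 1L,
                     proportion = tp$proportion, per_mm2 = tp$proportion * 100)
  clinical <- gen$clinical[, c("sample_id", "grade")]
  res <- associate_proportion(prev, clinical, "proportion", min_samples = 5L)
  hi <- res[res$category == "high", ]
  expect_identical(hi$predictor[which.max(abs(hi$t_value))], "cl0")
})
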