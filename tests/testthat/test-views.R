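# Feature derivation: mean expression, nuclear co-localization,
# morphology, spatial neighbours/context, covariates.

test_that("mean_expression matches hand values and the loop oracle", {
  # one 2-pixel cell, protein values 2 and 4 -> mean 3
  ch <- list(matrix(5, 2, 2), matrix(5, 2, 2), matrix(c(2, 4, 0, 0), 2, 2))
  fx <- toy_sample(2, 2, ch, cells = list(list(label = 7L, rows = 1:2, cols = 1)))
  Y <- mean_expression(fx$stack, fx$mask, fx$channels)
  expect_identical(dim(Y), c(1L, 1L))
  expect_equal(Y[1, 1], 3.0)
  expect_identical(rownames(Y), "7")

  # uniform image: every cell's mean equals the constant, all proteins
  fx2 <- random_fixture(seed = 11)
  fx2$stack$pixels[] <- 4.25
  Y2 <- mean_expression(fx2$stack, fx2$mask, fx2$channels)
  expect_true(all(Y2 == 4.25))

  # random 20x20 fixture vs brute-force loop oracle
  fx3 <- random_fixture(ny = 20, nx = 20, n_prot = 3, n_cells = 9, seed = 12)
  expect_equal(unname(mean_expression(fx3$stack, fx3$mask, fx3$channels)),
               oracle_mean_expression(fx3$stack, fx3$mask, fx3$channels),
               tolerance = 1e-12)
})

test_that("nuclear_localization hits the exact correlation limits", {
  nuc1 <- matrix(stats::runif(16, 1, 5), 4, 4)
  # protein1 identical to the mean nuclear stain; protein2 its negation
  # about the mean
  prot1 <- nuc1
  prot2 <- 2 * mean(nuc1) - nuc1
  fx <- toy_sample(4, 4, list(nuc1, nuc1, prot1, prot2),
                   cells = list(list(label = 1L, rows = 1:4, cols = 1:4)))
  S <- nuclear_localization(fx$stack, fx$mask, fx$channels)
  expect_equal(S[1, 1], 1.0, tolerance = 1e-12)
  expect_equal(S[1, 2], -1.0, tolerance = 1e-12)
})

test_that("nuclear_localization matches the textbook Pearson oracle", {
  fx <- random_fixture(ny = 20, nx = 20, n_prot = 3, n_cells = 9, seed = 13)
  S <- nuclear_localization(fx$stack, fx$mask, fx$channels)
  expect_equal(unname(S),
               oracle_nuclear_localization(fx$stack, fx$mask, fx$channels),
               tolerance = 1e-10)
  expect_true(all(S >= -1 & S <= 1))

  # swapping the two DNA channels leaves S unchanged (mean is symmetric)
  fx_sw <- fx
  fx_sw$stack$pixels[, , 1:2] <- fx$stack$pixels[, , 2:1]
  expect_equal(S, nuclear_localization(fx_sw$stack, fx_sw$mask, fx_sw$channels))

  # degenerate: constant protein within a cell -> 0
  fx$stack$pixels[, , 3] <- 1
  S0 <- nuclear_localization(fx$stack, fx$mask, fx$channels)
  expect_true(all(S0[, 1] == 0))

  bad <- fx$channels
  bad$is_dna_intercalator[2] <- FALSE
  expect_error(channel_map(as.data.frame(bad)), "DNA")
})

test_that("morphology emits the 5 documented features with known values", {
  fx <- toy_sample(8, 8, list(matrix(1, 8, 8), matrix(1, 8, 8), matrix(1, 8, 8)),
                   cells = list(list(label = 2L, rows = 2:5, cols = 2:5),
                                list(label = 9L, rows = 7:8, cols = 1:6)))
  Mm <- morphology(fx$mask)
  expect_identical(ncol(Mm), 5L)
  expect_identical(colnames(Mm), c("area", "perimeter", "eccentricity",
                                   "concavity", "asymmetry"))
  sq <- Mm["2", ]
  expect_equal(sq[["area"]], 16)          # 4x4 filled square
  expect_equal(sq[["perimeter"]], 16)     # 4 sides x 4 boundary faces
  expect_equal(sq[["eccentricity"]], 0)
  expect_equal(sq[["concavity"]], 0)      # convex: area == convex area
  expect_equal(sq[["asymmetry"]], 0)
  rect <- Mm["9", ]
  expect_equal(rect[["area"]], 12)        # 2x6 rectangle
  expect_equal(rect[["concavity"]], 0)
  expect_gt(rect[["eccentricity"]], 0.8)
  expect_gt(rect[["asymmetry"]], 0)
})

test_that("morphology is translation invariant", {
  base <- list(list(label = 1L, rows = 2:4, cols = 2:3),
               list(label = 2L, rows = c(6, 6, 7), cols = c(2, 3, 2)))
  shift <- list(list(label = 1L, rows = 5:7, cols = 6:7),
                list(label = 2L, rows = c(9, 9, 10), cols = c(7, 8, 7)))
  mk <- function(cells) toy_sample(12, 12, list(matrix(0, 12, 12),
                                                matrix(0, 12, 12),
                                                matrix(0, 12, 12)),
                                   cells = cells)$mask
  expect_equal(morphology(mk(base)), morphology(mk(shift)))
})

test_that("toy L-shaped cell has positive concavity", {
  m <- matrix(0L, 6, 6)
  m[1:4, 1] <- 1L; m[4, 1:4] <- 1L
  conc <- morphology(segmentation_mask(m, "s"))[1, "concavity"]
  expect_gt(conc, 0.2)
})

test_that("spatial_neighbours matches brute force and its invariants", {
  # 3 collinear cells, k = 1: middle cell picks the nearer endpoint
  cent <- rbind(c(0, 0), c(0, 4), c(0, 10))
  D <- spatial_neighbours(cent, rep("s", 3), k = 1)
  expect_equal(which(D[2, ] == 1), 1L)

  set.seed(21)
  n <- 40
  cent <- cbind(stats::runif(n, 0, 100), stats::runif(n, 0, 100))
  sids <- rep(c("a", "b"), each = n / 2)
  D <- spatial_neighbours(cent, sids, k = 10)
  expect_true(all(Matrix::rowSums(D) == 10))      # k rows exactly
  expect_true(all(Matrix::diag(D) == 0))          # no self-neighbours
  # never crosses samples
  expect_equal(sum(D[sids == "a", sids == "b"]), 0)
  expect_equal(sum(D[sids == "b", sids == "a"]), 0)
  # exhaustive pairwise-distance oracle
  for (i in seq_len(n)) {
    same <- which(sids == sids[i] & seq_len(n) != i)
    d <- sqrt(colSums((t(cent[same, ]) - cent[i, ])^2))
    expect_setequal(which(D[i, ] == 1), same[order(d)][1:10])
  }

  # k shortfall: a 3-cell sample with k = 10 uses all available cells
  D3 <- spatial_neighbours(cent[1:3, ], rep("s", 3), k = 10)
  expect_true(all(Matrix::rowSums(D3) == 2))
  expect_warning(spatial_neighbours(rbind(c(0, 0)), "s", k = 10), "single cell")
})

test_that("spatial_context equals the neighbour-averaging oracle", {
  cv <- default_cv()
  n <- 45
  Y <- cv$Y[1:n, ]; S <- cv$S[1:n, ]; M <- cv$M[1:n, ]
  D <- spatial_neighbours(cv$centroids[1:n, ], cv$sample_ids[1:n], k = 5)
  C <- spatial_context(Y, S, M, D)
  expect_identical(ncol(C), 2L * ncol(Y) + 5L)
  expect_equal(unname(C), oracle_spatial_context(Y, S, M, D),
               tolerance = 1e-12)

  # one neighbour -> exactly that neighbour's scaled row
  D1 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(n, n))
  expect_warning(C1 <- spatial_context(Y, S, M, D1), "no neighbours")
  scaled <- scale(cbind(Y, S, M))
  expect_equal(unname(C1[1, ]), unname(scaled[2, ]), tolerance = 1e-12)
  expect_true(all(C1[3, ] == 0))  # zero-neighbour row

  # all-identical features -> all-zero context
  Yc <- matrix(2, n, 3); Sc <- matrix(0.5, n, 3); Mc <- matrix(1, n, 5)
  expect_true(all(spatial_context(Yc, Sc, Mc, D) == 0))

  # location invariance: adding a constant to one protein changes nothing
  Y2 <- Y; Y2[, 2] <- Y2[, 2] + 57.3
  expect_equal(spatial_context(Y2, S, M, D), C, tolerance = 1e-9)
})

test_that("background covariates cover both channel regimes", {
  # uniform image of constant c: mean sample intensity = c
  fx <- random_fixture(ny = 12, nx = 12, n_prot = 2, n_cells = 4, seed = 31)
  fx$stack$pixels[] <- 3.5
  b <- background_covariates(fx$stack, fx$mask, fx$channels)
  expect_equal(unname(b[1, "sample_intensity"]), 3.5)

  # no background channels, all background pixels 0 -> per-protein
  # background means all 0
  fx2 <- random_fixture(ny = 12, nx = 12, n_prot = 2, n_cells = 4, seed = 32)
  bgpix <- fx2$mask$labels == 0
  for (k in seq_len(dim(fx2$stack$pixels)[3])) {
    pl <- fx2$stack$pixels[, , k]; pl[bgpix] <- 0
    fx2$stack$pixels[, , k] <- pl
  }
  b2 <- background_covariates(fx2$stack, fx2$mask, fx2$channels)
  expect_true(all(b2[1, paste0("bgmean_prot", 1:2)] == 0))
  # loop oracle for the intensity covariate
  expect_equal(unname(b2[1, "sample_intensity"]), mean(fx2$stack$pixels))

  # with a flagged background channel: correlation + intensity covariates
  fx3 <- random_fixture(ny = 20, nx = 20, n_prot = 2, n_cells = 9, seed = 33,
                        background = TRUE)
  b3 <- background_covariates(fx3$stack, fx3$mask, fx3$channels)
  expect_setequal(colnames(b3), c("bgcor_prot1", "bgcor_prot2",
                                  "sample_intensity", "bg_intensity"))
  bgch <- which(fx3$channels$is_background)
  expect_equal(unname(b3[1, "bg_intensity"]), mean(fx3$stack$pixels[, , bgch]))
  # oracle for the background correlation of protein 1
  Y <- mean_expression(fx3$stack, fx3$mask, fx3$channels)
  labs <- sort(unique(fx3$mask$labels[fx3$mask$labels > 0]))
  bg_cell <- vapply(labs, function(l)
    mean(fx3$stack$pixels[, , bgch][fx3$mask$labels == l]), numeric(1))
  expect_equal(unname(b3[1, "bgcor_prot1"]), oracle_pearson(bg_cell, Y[, 1]),
               tolerance = 1e-12)
})

test_that("one_hot layout and permutation behaviour", {
  expect_true(all(one_hot(rep("only", 4)) == 1))
  oh <- one_hot(rep(c("c", "a", "b"), each = 2))
  expect_identical(dim(oh), c(6L, 3L))
  expect_identical(colnames(oh), c("onehot_a", "onehot_b", "onehot_c"))
  expect_equal(unname(colSums(oh)), c(2, 2, 2))
  expect_true(all(rowSums(oh) == 1))
  ids <- rep(c("a", "b", "c"), times = c(3, 2, 4))
  perm <- sample(length(ids))
  expect_equal(one_hot(ids)[perm, ], one_hot(ids[perm]))
})

test_that("derive_cell_views assembles consistent dimensions", {
  cv <- default_cv()
  P <- length(cv$proteins)
  expect_identical(ncol(cv$Y), P)
  expect_identical(ncol(cv$S), P)
  expect_identical(ncol(cv$M), 5L)
  expect_identical(ncol(cv$C), 2L * P + 5L)
  expect_identical(ncol(cv$b), P + 1L + length(cv$sample_levels))
  expect_false(anyNA(cv$Y) || anyNA(cv$S) || anyNA(cv$M) || anyNA(cv$C))
  expect_true(all(rowSums(cv$b[, paste0("onehot_", cv$sample_levels)]) == 1))
})
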