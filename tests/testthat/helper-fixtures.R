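# Shared fixtures and independent oracles. Expensive artifacts (the
# default synthetic dataset and a trained model on it) are computed once
# per test run and cached.

.hv_cache <- new.env(parent = emptyenv())

cache_get <- function(key, fn) {
  if (!exists(key, envir = .hv_cache, inherits = FALSE))
    assign(key, fn(), envir = .hv_cache)
  get(key, envir = .hv_cache, inherits = FALSE)
}

# The default stated-world fixture: 3 samples, ~600 cells, 4 phenotypes,
# seed 0.
default_gen <- function() cache_get("gen", function()
  generate_synthetic(synthetic_spec(seed = 0L)))

default_cv <- function() cache_get("cv", function()
  derive_cell_views(default_gen()$samples))

default_model_cfg <- function() model_config(seed = 0L, epochs = 60L,
                                             patience = 15L)

default_model <- function() cache_get("model", function()
  train_hmivae(default_cv(), default_model_cfg()))

default_latent <- function() cache_get("latent", function()
  embed_all(default_model(), default_cv()))

# A small handmade sample: rectangular cells on a grid, arbitrary
# channel values. cells = list of list(label, rows, cols) in 1-based
# matrix indices.
toy_sample <- function(ny, nx, channel_values, cells,
                       dna = c(1L, 2L), background = integer(0),
                       sample_id = "toy") {
  n_ch <- length(channel_values)
  arr <- array(0, dim = c(ny, nx, n_ch))
  for (k in seq_len(n_ch)) arr[, , k] <- channel_values[[k]]
  mask <- matrix(0L, ny, nx)
  for (cl in cells) mask[cl$rows, cl$cols] <- cl$label
  nms <- character(n_ch)
  nms[dna] <- paste0("DNA", seq_along(dna))
  nms[background] <- paste0("BG", seq_along(background))
  rest <- setdiff(seq_len(n_ch), c(dna, background))
  nms[rest] <- paste0("prot", seq_along(rest))
  chmap <- channel_map(data.frame(
    channel_index = seq_len(n_ch) - 1L,
    protein_name = nms,
    is_dna_intercalator = seq_len(n_ch) %in% dna,
    is_background = seq_len(n_ch) %in% background))
  list(stack = pixel_stack(arr, sample_id),
       mask = segmentation_mask(mask, sample_id),
       channels = chmap)
}

# Random fixture with block cells; returns a load_sample()-style triplet.
random_fixture <- function(ny = 20, nx = 20, n_prot = 3, n_cells = 9,
                           seed = 1, sample_id = "rf", background = FALSE) {
  set.seed(seed)
  n_ch <- n_prot + 2L + as.integer(background)
  arr <- array(stats::runif(ny * nx * n_ch, 0, 10), dim = c(ny, nx, n_ch))
  mask <- matrix(0L, ny, nx)
  side <- 4L
  per_row <- (nx - 1L) %/% (side + 1L)
  for (i in seq_len(n_cells)) {
    r0 <- 1L + ((i - 1L) %/% per_row) * (side + 1L)
    c0 <- 1L + ((i - 1L) %% per_row) * (side + 1L)
    mask[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- i * 3L  # non-sequential
  }
  chmap <- channel_map(data.frame(
    channel_index = seq_len(n_ch) - 1L,
    protein_name = c("DNA1", "DNA2", paste0("prot", seq_len(n_prot)),
                     if (background) "ArAr80"),
    is_dna_intercalator = c(TRUE, TRUE, rep(FALSE, n_ch - 2L)),
    is_background = c(rep(FALSE, n_prot + 2L), if (background) TRUE)))
  list(stack = pixel_stack(arr, sample_id),
       mask = segmentation_mask(mask, sample_id),
       channels = chmap)
}

# ---- independent oracles (brute-force loops, no shared code paths) ----

oracle_mean_expression <- function(stack, mask, chmap) {
  labs <- sort(unique(mask$labels[mask$labels > 0]))
  keep <- which(!chmap$is_dna_intercalator & !chmap$is_background)
  out <- matrix(NA_real_, length(labs), length(keep))
  for (a in seq_along(labs)) {
    sel <- mask$labels == labs[a]
    for (j in seq_along(keep)) {
      vals <- c()
      for (y in seq_len(nrow(sel))) for (x in seq_len(ncol(sel)))
        if (sel[y, x]) vals <- c(vals, stack$pixels[y, x, keep[j]])
      out[a, j] <- sum(vals) / length(vals)
    }
  }
  out
}

oracle_pearson <- function(a, b) {
  n <- length(a)
  am <- sum(a) / n; bm <- sum(b) / n
  num <- sum((a - am) * (b - bm))
  den <- sqrt(sum((a - am)^2) * sum((b - bm)^2))
  num / den
}

oracle_nuclear_localization <- function(stack, mask, chmap) {
  labs <- sort(unique(mask$labels[mask$labels > 0]))
  dna <- which(chmap$is_dna_intercalator)
  keep <- which(!chmap$is_dna_intercalator & !chmap$is_background)
  out <- matrix(0, length(labs), length(keep))
  for (a in seq_along(labs)) {
    sel <- which(mask$labels == labs[a])
    nucv <- (stack$pixels[, , dna[1]][sel] + stack$pixels[, , dna[2]][sel]) / 2
    for (j in seq_along(keep)) {
      pv <- stack$pixels[, , keep[j]][sel]
      r <- if (length(sel) < 3 || stats::sd(pv) == 0 || stats::sd(nucv) == 0) 0
           else oracle_pearson(pv, nucv)
      out[a, j] <- r
    }
  }
  out
}

oracle_spatial_context <- function(Y, S, M, D) {
  feats <- cbind(Y, S, M)
  scaled <- feats
  for (j in seq_len(ncol(feats))) {
    s <- stats::sd(feats[, j])
    scaled[, j] <- if (s > 1e-12) (feats[, j] - mean(feats[, j])) / s else 0
  }
  Dd <- as.matrix(D)
  out <- matrix(0, nrow(feats), ncol(feats))
  for (i in seq_len(nrow(feats))) {
    nb <- which(Dd[i, ] == 1)
    if (length(nb))
      out[i, ] <- colMeans(scaled[nb, , drop = FALSE])
  }
  out
}

oracle_knn_labels <- function(ref, labels, query, k, metric) {
  out <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    d <- numeric(nrow(ref))
    for (j in seq_len(nrow(ref))) {
      if (metric == "euclidean") {
        d[j] <- sqrt(sum((query[i, ] - ref[j, ])^2))
      } else {
        d[j] <- 1 - sum(query[i, ] * ref[j, ]) /
          (sqrt(sum(query[i, ]^2)) * sqrt(sum(ref[j, ]^2)))
      }
    }
    nb <- order(d, seq_along(d))[seq_len(k)]
    votes <- table(labels[nb])
    out[i] <- sort(names(votes)[votes == max(votes)])[1]
  }
  out
}

# Pair-counting ARI over all element pairs, straight from the
# definition.
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  tot <- n11 + n10 + n01 + n00
  expected <- (n11 + n10) * (n11 + n01) / tot
  mx <- ((n11 + n10) + (n11 + n01)) / 2
  if (mx == expected) return(1)
  (n11 - expected) / (mx - expected)
}

# Fraction of variance in each latent dimension explained by sample
# identity (one-way ANOVA R^2), averaged over dimensions.
sample_var_explained <- function(z, sample_ids) {
  f <- factor(sample_ids)
  mean(apply(z, 2, function(col) {
    fit <- stats::lm(col ~ f)
    1 - sum(stats::resid(fit)^2) / sum((col - mean(col))^2)
  }))
}

permute_cellviews <- function(cv, perm) {
  out <- cv
  for (nm in c("Y", "S", "M", "C", "b", "centroids"))
    out[[nm]] <- cv[[nm]][perm, , drop = FALSE]
  out$cell_ids <- cv$cell_ids[perm]
  out$sample_ids <- cv$sample_ids[perm]
  out
}
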