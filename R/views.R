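# Derivation of the four per-cell views from image-space inputs:
#   Y  mean protein expression            (N x P, raw counts)
#   S  protein nuclear co-localization    (N x P, Pearson r in [-1, 1])
#   M  morphology                         (N x 5)
#   C  spatial context                    (N x L, L = 2P + 5, z-score units)
# plus technical covariates b (background features + sample one-hot).
#
# Cells are keyed by (sample_id, original mask label); labels need not be
# sequential. Within a sample, rows are ordered by increasing mask label.

MORPH_FEATURES <- c("area", "perimeter", "eccentricity", "concavity", "asymmetry")

# Pixel index lists per cell, in increasing label order. Returns a named
# list label -> integer vector of linear indices into the mask matrix.
cell_pixel_index <- function(mask) {
  lab <- mask$labels
  pos <- which(lab > 0L)
  if (!length(pos)) hv_stop("mask for sample '%s' is all background", mask$sample_id)
  idx <- split(pos, lab[pos])
  idx[order(as.integer(names(idx)))]
}

protein_channels <- function(chmap) {
  keep <- !chmap$is_dna_intercalator & !chmap$is_background
  list(idx = which(keep), names = chmap$protein_name[keep])
}

#' Per-cell mean protein expression (view Y)
#'
#' For each cell, the arithmetic mean of each protein's pixel counts over
#' the pixels assigned to that cell. DNA-intercalator and background
#' channels are excluded from the protein columns.
#'
#' @param stack an `hv_stack`
#' @param mask the paired `hv_mask`
#' @param chmap the `hv_channels` table
#' @return numeric matrix, one row per cell (increasing mask label),
#'   one column per protein
#' @export
mean_expression <- function(stack, mask, chmap) {
  idx <- cell_pixel_index(mask)
  pc <- protein_channels(chmap)
  out <- matrix(0, nrow = length(idx), ncol = length(pc$idx),
                dimnames = list(names(idx), pc$names))
  for (j in seq_along(pc$idx)) {
    plane <- stack$pixels[, , pc$idx[j]]
    out[, j] <- vapply(idx, function(i) mean(plane[i]), numeric(1))
  }
  out
}

#' Per-cell nuclear co-localization scores (view S)
#'
#' The mean nuclear stain is the per-pixel average of the two
#' DNA-intercalator channels. For each cell and protein, the score is
#' the Pearson correlation over the cell's pixels between the protein's
#' counts and the mean nuclear stain. Degenerate cases (constant vectors,
#' cells with fewer than 3 pixels) give 0.
#'
#' @inheritParams mean_expression
#' @return numeric matrix in `[-1, 1]`, one row per cell, one column per
#'   protein (named `nc_<protein>`)
#' @export
nuclear_localization <- function(stack, mask, chmap) {
  dna <- which(chmap$is_dna_intercalator)
  if (length(dna) != 2L)
    hv_stop("expected exactly 2 DNA-intercalator channels, found %d", length(dna))
  nuc <- (stack$pixels[, , dna[1]] + stack$pixels[, , dna[2]]) / 2
  idx <- cell_pixel_index(mask)
  pc <- protein_channels(chmap)
  out <- matrix(0, nrow = length(idx), ncol = length(pc$idx),
                dimnames = list(names(idx), paste0("nc_", pc$names)))
  for (j in seq_along(pc$idx)) {
    plane <- stack$pixels[, , pc$idx[j]]
    out[, j] <- vapply(idx, function(i) hv_safe_cor(plane[i], nuc[i]), numeric(1))
  }
  out
}

# Second central moments of a cell's pixel-center coordinates; returns
# eigenvalues (l1 >= l2) of the 2x2 inertia tensor.
pixel_moment_eigen <- function(ys, xs) {
  mu20 <- mean((xs - mean(xs))^2)
  mu02 <- mean((ys - mean(ys))^2)
  mu11 <- mean((xs - mean(xs)) * (ys - mean(ys)))
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  c(tr / 2 + disc, max(tr / 2 - disc, 0))
}

# Convex hull area of the pixel squares (corner points), via shoelace.
convex_area_px <- function(ys, xs) {
  cx <- c(xs - 0.5, xs + 0.5, xs + 0.5, xs - 0.5)
  cy <- c(ys - 0.5, ys - 0.5, ys + 0.5, ys + 0.5)
  h <- grDevices::chull(cx, cy)
  hx <- cx[h]; hy <- cy[h]
  n <- length(h)
  abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) / 2
}

# Boundary length: count of 4-connectivity pixel faces adjacent to a
# pixel outside the cell (including image border).
perimeter_px <- function(ys, xs) {
  key <- paste(ys, xs)
  inside <- new.env(hash = TRUE, size = length(key))
  for (k in key) assign(k, TRUE, envir = inside)
  per <- 0L
  for (i in seq_along(ys)) {
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      if (!exists(paste(ys[i] + d[1], xs[i] + d[2]), envir = inside,
                  inherits = FALSE))
        per <- per + 1L
    }
  }
  per
}

#' Per-cell morphology features (view M)
#'
#' Five features per cell: `area` (pixel count), `perimeter`
#' (4-connectivity boundary edge count), `eccentricity` of the
#' moment-fitted ellipse, `concavity` = 1 - area / convex hull area, and
#' `asymmetry` = (major - minor) / (major + minor) axis contrast. All
#' are invariant to translation of the cell's pixels.
#'
#' @param mask an `hv_mask`
#' @return numeric matrix, one row per cell, 5 columns
#' @export
morphology <- function(mask) {
  idx <- cell_pixel_index(mask)
  ny <- nrow(mask$labels)
  out <- matrix(0, nrow = length(idx), ncol = 5L,
                dimnames = list(names(idx), MORPH_FEATURES))
  for (i in seq_along(idx)) {
    lin <- idx[[i]]
    ys <- (lin - 1L) %% ny          # 0-based row (y)
    xs <- (lin - 1L) %/% ny         # 0-based column (x)
    ev <- pixel_moment_eigen(ys, xs)
    ecc <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
    conc <- 1 - length(lin) / convex_area_px(ys, xs)
    asym <- if (sum(sqrt(ev)) > 0) diff(rev(sqrt(ev))) / sum(sqrt(ev)) else 0
    out[i, ] <- c(length(lin), perimeter_px(ys, xs), ecc, max(conc, 0), asym)
  }
  out
}

#' Per-cell centroids in pixel units
#'
#' Centroid = mean (y, x) coordinate of the cell's mask pixels, 0-based.
#'
#' @param mask an `hv_mask`
#' @return numeric matrix, columns `y`, `x`
#' @export
cell_centroids <- function(mask) {
  idx <- cell_pixel_index(mask)
  ny <- nrow(mask$labels)
  t(vapply(idx, function(lin) {
    c(y = mean((lin - 1L) %% ny), x = mean((lin - 1L) %/% ny))
  }, numeric(2)))
}

#' Spatial k-nearest-neighbour graph
#'
#' For each cell, the k nearest other cells of the same sample by
#' Euclidean distance between centroids. Neighbour relations never cross
#' sample boundaries and a cell is never its own neighbour. Distance
#' ties are broken in favour of the cell appearing earlier (lower mask
#' label within a sample). Samples with fewer than k + 1 cells use all
#' available cells; a single-cell sample yields an all-zero row with a
#' warning.
#'
#' @param centroids N x 2 matrix of (y, x) centroids
#' @param sample_ids character vector of length N
#' @param k neighbour count (default 10)
#' @return sparse binary N x N `Matrix`; row i flags the neighbours of
#'   cell i
#' @export
spatial_neighbours <- function(centroids, sample_ids, k = 10L) {
  n <- nrow(centroids)
  ii <- integer(0); jj <- integer(0)
  for (s in unique(sample_ids)) {
    rows <- which(sample_ids == s)
    if (length(rows) < 2L) {
      hv_warn("sample '%s' has a single cell; its neighbour row is all zero", s)
      next
    }
    dm <- as.matrix(stats::dist(centroids[rows, , drop = FALSE]))
    kk <- min(k, length(rows) - 1L)
    for (a in seq_along(rows)) {
      d <- dm[a, ]
      d[a] <- Inf
      nb <- order(d, seq_along(d))[seq_len(kk)]
      ii <- c(ii, rep(rows[a], kk)); jj <- c(jj, rows[nb])
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
}

#' Spatial context features (view C)
#'
#' Columns of `[Y | S | M]` are z-scored over all N cells (zero-variance
#' columns become zeros), then each cell's context row is the mean of
#' its spatial neighbours' scaled feature rows (row-normalized `D`
#' times the scaled concatenation). Width is `L = 2P + 5`.
#'
#' @param Y,S,M the three feature matrices on the same cells
#' @param D sparse neighbour matrix from [spatial_neighbours()]
#' @return numeric N x L matrix
#' @export
spatial_context <- function(Y, S, M, D) {
  feats <- cbind(Y, S, M)
  if (is.null(colnames(feats)))
    colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  scaled <- hv_zscore(feats)$x
  deg <- Matrix::rowSums(D)
  if (any(deg == 0)) hv_warn("%d cell(s) have no neighbours; context rows set to zero",
                             sum(deg == 0))
  w <- ifelse(deg > 0, 1 / deg, 0)
  out <- as.matrix(Matrix::Diagonal(x = w) %*% D %*% scaled)
  dimnames(out) <- list(rownames(feats), paste0("sc_", colnames(feats)))
  out
}

#' Technical background covariates for one sample
#'
#' With background channels flagged in the channel map: (i) per-protein
#' correlation, across the sample's cells, between mean
#' background-channel staining per cell and mean protein expression per
#' cell; (ii) mean sample intensity (average pixel value over all
#' channels); (iii) mean background-channel intensity. Without
#' background channels: (a) mean sample intensity and (b) the
#' per-protein mean over background (0-labelled) pixels. Covariates are
#' constant within a sample and broadcast to every cell.
#'
#' @inheritParams mean_expression
#' @return one-row numeric matrix of named covariates (same names across
#'   samples of a dataset)
#' @export
background_covariates <- function(stack, mask, chmap) {
  pc <- protein_channels(chmap)
  bg <- which(chmap$is_background)
  sample_intensity <- mean(stack$pixels)
  if (length(bg)) {
    idx <- cell_pixel_index(mask)
    bgplane <- apply(stack$pixels[, , bg, drop = FALSE], c(1, 2), mean)
    bg_per_cell <- vapply(idx, function(i) mean(bgplane[i]), numeric(1))
    Y <- mean_expression(stack, mask, chmap)
    if (length(idx) < 3L) {
      hv_warn("sample '%s' has <3 cells; background correlations set to 0",
              stack$sample_id)
      cors <- rep(0, length(pc$names))
    } else {
      cors <- vapply(seq_along(pc$names),
                     function(j) hv_safe_cor(bg_per_cell, Y[, j]), numeric(1))
    }
    out <- c(cors, sample_intensity, mean(stack$pixels[, , bg]))
    names(out) <- c(paste0("bgcor_", pc$names), "sample_intensity", "bg_intensity")
  } else {
    bgpix <- which(mask$labels == 0L)
    bgmeans <- vapply(pc$idx, function(ch) {
      plane <- stack$pixels[, , ch]
      if (length(bgpix)) mean(plane[bgpix]) else 0
    }, numeric(1))
    out <- c(sample_intensity, bgmeans)
    names(out) <- c("sample_intensity", paste0("bgmean_", pc$names))
  }
  matrix(out, nrow = 1, dimnames = list(NULL, names(out)))
}

#' One-hot sample encoding
#'
#' @param sample_ids character vector, one entry per cell
#' @param levels sample levels defining the column order; defaults to
#'   the lexicographically sorted unique sample ids
#' @return N x R binary matrix; each row sums to 1
#' @export
one_hot <- function(sample_ids, levels = sort(unique(sample_ids))) {
  f <- factor(sample_ids, levels = levels)
  if (anyNA(f)) hv_stop("sample_ids outside the declared levels")
  out <- matrix(0, nrow = length(f), ncol = length(levels),
                dimnames = list(NULL, paste0("onehot_", levels)))
  out[cbind(seq_along(f), as.integer(f))] <- 1
  out
}

#' Derive all per-cell views and covariates for a dataset
#'
#' Runs the full feature-derivation stage over a list of samples and
#' assembles the `hv_cellviews` container used by the model and all
#' downstream analyses.
#'
#' @param samples list of sample triplets as returned by [load_sample()]
#'   (elements `stack`, `mask`, `channels`); all samples must share the
#'   same channel map
#' @param k spatial neighbour count (default 10)
#' @return an object of class `hv_cellviews` with matrices `Y`, `S`,
#'   `M`, `C`, `b`, centroids, cell/sample identifiers, protein names,
#'   and per-sample image dimensions
#' @export
derive_cell_views <- function(samples, k = 10L) {
  stopifnot(length(samples) >= 1L)
  chmap <- samples[[1]]$channels
  for (s in samples)
    if (!identical(s$channels$protein_name, chmap$protein_name))
      hv_stop("samples disagree on the channel map")
  per <- lapply(samples, function(s) {
    list(Y = mean_expression(s$stack, s$mask, chmap),
         S = nuclear_localization(s$stack, s$mask, chmap),
         M = morphology(s$mask),
         b = background_covariates(s$stack, s$mask, chmap),
         cent = cell_centroids(s$mask),
         sample_id = s$stack$sample_id,
         dims = dim(s$mask$labels))
  })
  Y <- do.call(rbind, lapply(per, `[[`, "Y"))
  S <- do.call(rbind, lapply(per, `[[`, "S"))
  M <- do.call(rbind, lapply(per, `[[`, "M"))
  cent <- do.call(rbind, lapply(per, `[[`, "cent"))
  ncells <- vapply(per, function(p) nrow(p$Y), integer(1))
  sample_ids <- rep(vapply(per, `[[`, character(1), "sample_id"), ncells)
  cell_ids <- as.integer(unlist(lapply(per, function(p) rownames(p$Y))))
  D <- spatial_neighbours(cent, sample_ids, k = k)
  C <- spatial_context(Y, S, M, D)
  bg <- do.call(rbind, lapply(seq_along(per), function(i)
    per[[i]]$b[rep(1, ncells[i]), , drop = FALSE]))
  levels <- sort(unique(sample_ids))
  b <- cbind(bg, one_hot(sample_ids, levels))
  dims <- lapply(per, `[[`, "dims")
  names(dims) <- vapply(per, `[[`, character(1), "sample_id")
  rownames(Y) <- rownames(S) <- rownames(M) <- rownames(C) <- rownames(b) <- NULL
  rownames(cent) <- NULL
  structure(list(Y = Y, S = S, M = M, C = C, b = b, centroids = cent,
                 cell_ids = cell_ids, sample_ids = sample_ids,
                 proteins = protein_channels(chmap)$names,
                 sample_levels = levels, k_spatial = as.integer(k),
                 image_dims = dims),
            class = "hv_cellviews")
}

#' @method print hv_cellviews
#' @export
print.hv_cellviews <- function(x, ...) {
  cat(sprintf("hv_cellviews: %d cells, %d proteins, %d sample(s)\n",
              nrow(x$Y), ncol(x$Y), length(x$sample_levels)))
  cat(sprintf("  views: Y %dx%d, S %dx%d, M %dx%d, C %dx%d, b %dx%d\n",
              nrow(x$Y), ncol(x$Y), nrow(x$S), ncol(x$S), nrow(x$M), ncol(x$M),
              nrow(x$C), ncol(x$C), nrow(x$b), ncol(x$b)))
  invisible(x)
}
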