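# Downstream analyses over latent/view embeddings: Leiden clustering,
# per-cluster feature ranking, cluster prevalence, clinical association
# by logistic regression, Cox survival models, and the segmentation
# quality check.

#' Default Leiden resolutions per embedding space
#'
#' Integrated 1.0, expression 0.5, nuclear co-localization 1.0,
#' morphology 0.1, spatial context 0.5; 100 nearest neighbours
#' throughout.
#' @export
default_resolutions <- function() {
  c(integrated = 1.0, E = 0.5, NC = 1.0, M = 0.1, SC = 0.5)
}

#' Leiden clustering over an embedding
#'
#' Builds an exact Euclidean k-nearest-neighbour graph (symmetrized by
#' union, unweighted) and partitions it with the Leiden algorithm
#' (modularity objective, so `resolution` behaves like the standard
#' single-cell workflow). Cluster IDs are relabelled to be contiguous
#' from 0 in order of first appearance, making labels deterministic
#' given the seed.
#'
#' @param embedding N x d numeric matrix (d >= 2)
#' @param n_neighbours neighbours for the kNN graph (default 100; must
#'   be < N)
#' @param resolution Leiden resolution parameter
#' @param seed RNG seed for the (stochastic) Leiden refinement
#' @return integer vector of length N with 0-based cluster IDs
#' @export
cluster_cells <- function(embedding, n_neighbours = 100L, resolution = 1.0,
                          seed = 0L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (ncol(embedding) < 2L) hv_stop("embedding must have >= 2 columns")
  if (n <= n_neighbours)
    hv_stop("n_neighbours (%d) must be smaller than the number of cells (%d)",
            n_neighbours, n)
  dm <- as.matrix(stats::dist(embedding))
  diag(dm) <- Inf
  ii <- integer(0); jj <- integer(0)
  for (a in seq_len(n)) {
    nb <- order(dm[a, ], seq_len(n))[seq_len(n_neighbours)]
    ii <- c(ii, rep(a, n_neighbours)); jj <- c(jj, nb)
  }
  adj <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  adj <- (adj + Matrix::t(adj)) > 0            # union symmetrization
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  memb <- igraph::membership(cl)
  as.integer(factor(memb, levels = unique(memb))) - 1L
}

#' Cluster every embedding space of a latent object
#'
#' @param latent an `hv_latent` from [embed_all()]
#' @param spaces subset of `c("integrated", "E", "NC", "M", "SC")`
#' @param n_neighbours kNN graph size (default 100)
#' @param resolutions named resolutions; defaults per space from
#'   [default_resolutions()]
#' @param seed RNG seed
#' @return long data.frame (cell_id, sample_id, space, cluster_id)
#' @export
assign_clusters <- function(latent, spaces = c("integrated", "E", "NC", "M", "SC"),
                            n_neighbours = 100L,
                            resolutions = default_resolutions(), seed = 0L) {
  stopifnot(inherits(latent, "hv_latent"))
  out <- lapply(spaces, function(sp) {
    emb <- if (sp == "integrated") latent$z else latent$emb[[sp]]
    data.frame(cell_id = latent$cell_ids, sample_id = latent$sample_ids,
               space = sp,
               cluster_id = cluster_cells(emb, n_neighbours,
                                          resolutions[[sp]], seed))
  })
  do.call(rbind, out)
}

# Welch two-sample t statistic and two-sided p for x (cluster) vs y
# (rest); NA when either side is (near) constant or too small.
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) return(c(t = NA_real_, p = NA_real_))
  vx <- stats::var(x); vy <- stats::var(y)
  if (!is.finite(vx) || !is.finite(vy) || (vx < 1e-24 && vy < 1e-24))
    return(c(t = NA_real_, p = NA_real_))
  se2 <- vx / nx + vy / ny
  tt <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  c(t = tt, p = 2 * stats::pt(-abs(tt), df))
}

#' Rank the features driving each cluster
#'
#' Welch (unequal-variance) t-test of every feature, cluster vs rest,
#' with Benjamini-Hochberg adjustment across features within each
#' cluster. Per cluster, the top three features by t-value among those
#' with t > 0 and adjusted p < alpha are selected; the reported table
#' covers the union of selected features across clusters with their
#' statistics for every cluster (relaxed reporting). Constant features
#' are never selected; single-cell clusters are skipped with a warning.
#'
#' @param features N x F numeric matrix with column names
#' @param clusters integer vector of cluster IDs, length N
#' @param alpha significance threshold on adjusted p (default 0.05)
#' @param top number of features selected per cluster (default 3)
#' @return list with `table` (cluster, feature, t, p, p_adj, selected)
#'   restricted to the selected-feature union, `full` (all features),
#'   and `selected` (character vector)
#' @export
rank_features <- function(features, clusters, alpha = 0.05, top = 3L) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  cl_ids <- sort(unique(clusters))
  if (length(cl_ids) < 2L) hv_stop("need >= 2 clusters to rank features")
  rows <- list()
  for (cid in cl_ids) {
    inside <- clusters == cid
    if (sum(inside) < 2L) {
      hv_warn("cluster %s has < 2 cells; skipped in feature ranking", cid)
      next
    }
    st <- t(vapply(seq_len(ncol(features)), function(j)
      welch_t(features[inside, j], features[!inside, j]), numeric(2)))
    p_adj <- bh_adjust(st[, 2])
    ok <- which(is.finite(st[, 1]) & st[, 1] > 0 & p_adj < alpha)
    sel <- ok[order(-st[ok, 1])][seq_len(min(top, length(ok)))]
    rows[[as.character(cid)]] <- data.frame(
      cluster_id = cid, feature = colnames(features),
      t = st[, 1], p = st[, 2], p_adj = p_adj,
      selected = seq_len(ncol(features)) %in% sel)
  }
  full <- do.call(rbind, rows)
  rownames(full) <- NULL
  selected <- unique(full$feature[full$selected])
  list(table = full[full$feature %in% selected, , drop = FALSE],
       full = full, selected = selected)
}

#' Cluster prevalence per sample
#'
#' Two prevalence summaries per (sample, cluster): the cluster
#' proportion (count over the sample's total cell count) and cluster
#' instances per mm^2 of tissue (count over the image pixel area,
#' scaled by 1e6; at the 1 um/pixel acquisition resolution a 1000 x
#' 1000 image is 1 mm^2). All (sample, cluster) combinations are
#' reported, including zeros, so proportions sum to 1 within a sample.
#'
#' @param clusters integer cluster IDs, one per cell
#' @param sample_ids sample ID per cell
#' @param image_dims named list mapping sample_id to the (rows, cols)
#'   pixel dimensions of its image
#' @return data.frame (sample_id, cluster_id, n_cells, proportion,
#'   per_mm2)
#' @export
prevalence <- function(clusters, sample_ids, image_dims) {
  samples <- sort(unique(sample_ids))
  cl_ids <- sort(unique(clusters))
  out <- expand.grid(cluster_id = cl_ids, sample_id = samples,
                     stringsAsFactors = FALSE)[, c(2, 1)]
  cnt <- table(factor(sample_ids, samples), factor(clusters, cl_ids))
  out$n_cells <- vapply(seq_len(nrow(out)), function(i)
    as.integer(cnt[out$sample_id[i], as.character(out$cluster_id[i])]),
    integer(1))
  tot <- rowSums(cnt)
  out$proportion <- out$n_cells / tot[out$sample_id]
  area <- vapply(out$sample_id, function(s) {
    d <- image_dims[[s]]
    if (is.null(d)) hv_stop("no image dimensions recorded for sample '%s'", s)
    prod(unlist(d)[1:2])
  }, numeric(1))
  out$per_mm2 <- out$n_cells / area * 1e6
  rownames(out) <- NULL
  out
}

# Wald z ("t-value") and p for each requested coefficient of a logistic
# fit, dropping aliased (singular) predictors and refitting.
logistic_wald <- function(df, response, predictors) {
  fit <- suppressWarnings(stats::glm(
    stats::reformulate(predictors, response), family = stats::binomial(),
    data = df))
  if (anyNA(stats::coef(fit))) {
    keep <- predictors[!is.na(stats::coef(fit))[predictors]]
    if (!length(keep)) return(NULL)
    fit <- suppressWarnings(stats::glm(
      stats::reformulate(keep, response), family = stats::binomial(),
      data = df))
  }
  sm <- summary(fit)$coefficients
  sm[setdiff(rownames(sm), "(Intercept)"), , drop = FALSE]
}

clinical_categoricals <- function(clinical) {
  setdiff(names(clinical), c("sample_id", "survival_time", "event_indicator"))
}

#' Associate latent dimensions with clinical variables
#'
#' For each sample the median cell embedding of every latent dimension
#' is computed; for each category of each categorical clinical variable
#' a logistic regression of category membership (1 vs rest across
#' samples) on all median latent dimensions is fitted. Aliased
#' dimensions (singular design) are dropped and the model refitted.
#' Categories with fewer members than `min_samples` get NA rows.
#'
#' @param z N x d latent matrix
#' @param sample_ids sample ID per cell
#' @param clinical clinical table (one row per sample); every column
#'   other than sample_id / survival_time / event_indicator is treated
#'   as a categorical variable
#' @param min_samples minimum samples per category (default 5)
#' @return data.frame (predictor, variable, category, t_value, p,
#'   p_adj); BH family = latent dimensions within (variable, category)
#' @export
associate_latent <- function(z, sample_ids, clinical, min_samples = 5L) {
  z <- as.matrix(z)
  samples <- sort(unique(sample_ids))
  med <- t(vapply(samples, function(s)
    apply(z[sample_ids == s, , drop = FALSE], 2, stats::median),
    numeric(ncol(z))))
  colnames(med) <- paste0("z", seq_len(ncol(z)))
  df0 <- data.frame(sample_id = samples, med, check.names = FALSE)
  df0 <- merge(df0, clinical, by = "sample_id")
  out <- list()
  for (v in clinical_categoricals(clinical)) {
    for (cat in sort(unique(stats::na.omit(df0[[v]])))) {
      member <- as.integer(df0[[v]] == cat)
      base <- data.frame(predictor = colnames(med), variable = v,
                         category = as.character(cat), t_value = NA_real_,
                         p = NA_real_, p_adj = NA_real_)
      if (sum(member) >= min_samples && sum(1 - member) >= min_samples) {
        df0$.y <- member
        sm <- logistic_wald(df0, ".y", colnames(med))
        if (!is.null(sm)) {
          idx <- match(rownames(sm), base$predictor)
          base$t_value[idx] <- sm[, "z value"]
          base$p[idx] <- sm[, "Pr(>|z|)"]
          base$p_adj <- bh_adjust(base$p)
        }
      }
      out[[paste(v, cat)]] <- base
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Associate cluster prevalence with clinical variables
#'
#' With `metric = "proportion"`, one logistic regression per cluster
#' (1 vs rest over clusters) of category membership on that cluster's
#' proportion — the univariate design avoids the degeneracy of
#' compositional proportions. With `metric = "per_mm2"`, a single joint
#' logistic regression over all clusters' densities. BH adjustment is
#' across clusters within each (variable, category) family.
#'
#' @param prev prevalence table from [prevalence()]
#' @param clinical clinical table, one row per sample
#' @param metric `"proportion"` or `"per_mm2"`
#' @param min_samples minimum samples per category (default 5)
#' @return data.frame (predictor, variable, category, t_value, p, p_adj)
#' @export
associate_proportion <- function(prev, clinical,
                                 metric = c("proportion", "per_mm2"),
                                 min_samples = 5L) {
  metric <- match.arg(metric)
  wide <- stats::reshape(prev[, c("sample_id", "cluster_id", metric)],
                         idvar = "sample_id", timevar = "cluster_id",
                         direction = "wide")
  names(wide) <- sub(paste0("^", metric, "\\."), "cl", names(wide))
  cl_cols <- grep("^cl", names(wide), value = TRUE)
  df0 <- merge(wide, clinical, by = "sample_id")
  out <- list()
  for (v in clinical_categoricals(clinical)) {
    for (cat in sort(unique(stats::na.omit(df0[[v]])))) {
      member <- as.integer(df0[[v]] == cat)
      base <- data.frame(predictor = cl_cols, variable = v,
                         category = as.character(cat), t_value = NA_real_,
                         p = NA_real_, p_adj = NA_real_)
      if (sum(member) >= min_samples && sum(1 - member) >= min_samples) {
        df0$.y <- member
        if (metric == "proportion") {
          for (i in seq_along(cl_cols)) {
            if (stats::sd(df0[[cl_cols[i]]]) < 1e-12) next  # constant predictor
            sm <- logistic_wald(df0, ".y", cl_cols[i])
            if (!is.null(sm) && cl_cols[i] %in% rownames(sm)) {
              base$t_value[i] <- sm[cl_cols[i], "z value"]
              base$p[i] <- sm[cl_cols[i], "Pr(>|z|)"]
            }
          }
        } else {
          sm <- logistic_wald(df0, ".y", cl_cols)
          if (!is.null(sm)) {
            idx <- match(rownames(sm), base$predictor)
            base$t_value[idx] <- sm[, "z value"]
            base$p[idx] <- sm[, "Pr(>|z|)"]
          }
        }
        base$p_adj <- bh_adjust(base$p)
      }
      out[[paste(v, cat)]] <- base
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cox proportional-hazards survival analysis per cluster
#'
#' One Cox model per cluster relating the chosen prevalence metric to
#' survival, adjusting for disease stage and grade as covariates where
#' those columns are available. Hazard-ratio p-values are BH-adjusted
#' across clusters; the model concordance index is reported.
#'
#' @param prev prevalence table from [prevalence()]
#' @param clinical clinical table with `survival_time` and
#'   `event_indicator` (plus optional `stage`, `grade`)
#' @param metric `"proportion"` or `"per_mm2"`
#' @param covariates clinical columns to adjust for; defaults to
#'   whichever of stage/grade are present
#' @return data.frame (cluster_id, metric, coef, hazard_ratio, p,
#'   p_adj, concordance)
#' @export
survival_analysis <- function(prev, clinical,
                              metric = c("proportion", "per_mm2"),
                              covariates = intersect(c("stage", "grade"),
                                                     names(clinical))) {
  metric <- match.arg(metric)
  if (!all(c("survival_time", "event_indicator") %in% names(clinical)))
    hv_stop("clinical table lacks survival_time/event_indicator")
  if (any(clinical$survival_time <= 0, na.rm = TRUE))
    hv_stop("non-positive survival times")
  if (sum(clinical$event_indicator, na.rm = TRUE) == 0L)
    hv_stop("no events in the clinical table; cannot fit a Cox model")
  cl_ids <- sort(unique(prev$cluster_id))
  rows <- lapply(cl_ids, function(cid) {
    sub <- prev[prev$cluster_id == cid, c("sample_id", metric)]
    names(sub)[2] <- "x"
    df0 <- merge(sub, clinical, by = "sample_id")
    if (stats::sd(df0$x) < 1e-12)
      return(data.frame(cluster_id = cid, metric = metric, coef = NA_real_,
                        hazard_ratio = NA_real_, p = NA_real_,
                        concordance = NA_real_))
    form <- stats::reformulate(c("x", covariates),
                               "survival::Surv(survival_time, event_indicator)")
    fit <- survival::coxph(form, data = df0)
    sm <- summary(fit)$coefficients
    data.frame(cluster_id = cid, metric = metric, coef = sm["x", "coef"],
               hazard_ratio = sm["x", "exp(coef)"],
               p = sm["x", "Pr(>|z|)"],
               concordance = unname(summary(fit)$concordance[1]))
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res <- res[, c("cluster_id", "metric", "coef", "hazard_ratio", "p",
                 "p_adj", "concordance")]
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment within one declared family; NAs are
#' preserved and excluded from the family size.
#'
#' @param p numeric vector of p-values
#' @return adjusted p-values, same order, clipped to `[0, 1]`
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(out)
  o <- ok[order(p[ok], decreasing = TRUE)]
  ro <- m:1
  out[o] <- pmin(1, cummin(p[o] * m / ro))
  out
}

#' Segmentation quality check on non-co-expressed protein pairs
#'
#' For each pair, the per-protein median over all cells is computed and
#' the percentage of cells with expression strictly above both medians
#' is reported; high percentages for biologically exclusive pairs flag
#' segmentation errors (signal bleeding between adjacent cells).
#'
#' @param Y N x P mean-expression matrix with protein column names
#' @param pairs list of length-2 character vectors; defaults to the
#'   canonical exclusive pairs (CD3/CD20, CK8/18 vs CK5, CD45 vs CK8/18,
#'   SMA/PanCK, GATA3/CK14) restricted to proteins present in the panel
#' @return data.frame (protein_a, protein_b, pct_double_positive)
#' @export
segmentation_qc <- function(Y, pairs = NULL) {
  if (is.null(pairs)) {
    canon <- list(c("CD3", "CD20"), c("CK8/18", "CK5"), c("CD45", "CK8/18"),
                  c("SMA", "PanCK"), c("GATA3", "CK14"))
    pairs <- Filter(function(p) all(p %in% colnames(Y)), canon)
    if (!length(pairs))
      hv_stop("no default QC pairs match the panel; supply `pairs`")
  }
  med <- apply(Y, 2, stats::median)
  rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% colnames(Y)))
      hv_stop("QC pair (%s) not in panel", paste(pr, collapse = ", "))
    dp <- mean(Y[, pr[1]] > med[pr[1]] & Y[, pr[2]] > med[pr[2]])
    data.frame(protein_a = pr[1], protein_b = pr[2],
               pct_double_positive = 100 * dp)
  })
  do.call(rbind, rows)
}
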