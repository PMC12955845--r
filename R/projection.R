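# Reference -> query latent projection: covariate harmonization, KNN
# label transfer, and (balanced) ARI evaluation of partitions.

#' Conform query covariates to a reference model's schema
#'
#' The protein panels must be identical (up to order; query views are
#' reordered to the reference order). Background-stain covariates are
#' matched by name: query extras are dropped and covariates missing in
#' the query are zero-filled. The sample one-hot block is replaced by a
#' random valid one-hot of the reference width, so the total covariate
#' width equals what the reference model expects.
#'
#' @param model reference `hmivae_model`
#' @param query an `hv_cellviews` from the query dataset
#' @param seed seed for the randomized one-hot assignment
#' @return list with `cv` (query views, protein columns reordered) and
#'   `b` (conformed covariate matrix)
#' @export
harmonize_covariates <- function(model, query, seed = 0L) {
  ref_prot <- model$proteins
  if (!setequal(ref_prot, query$proteins)) {
    hv_stop("protein panels differ; unmatched: %s",
            paste(union(setdiff(ref_prot, query$proteins),
                        setdiff(query$proteins, ref_prot)), collapse = ", "))
  }
  ord <- match(ref_prot, query$proteins)
  cv <- query
  cv$Y <- query$Y[, ord, drop = FALSE]
  cv$S <- query$S[, ord, drop = FALSE]
  # C concatenates scaled [Y | S | M]; reorder its protein blocks too
  P <- length(ref_prot)
  cv$C <- query$C[, c(ord, P + ord, 2L * P + 1:5), drop = FALSE]
  cv$proteins <- ref_prot
  onehot_cols <- grepl("^onehot_", model$b_names)
  ref_bg <- model$b_names[!onehot_cols]
  n <- nrow(query$b)
  bg <- matrix(0, n, length(ref_bg), dimnames = list(NULL, ref_bg))
  shared <- intersect(ref_bg, colnames(query$b))
  bg[, shared] <- query$b[, shared, drop = FALSE]
  R <- sum(onehot_cols)
  set.seed(seed)
  oh <- matrix(0, n, R, dimnames = list(NULL, model$b_names[onehot_cols]))
  oh[cbind(seq_len(n), sample.int(R, n, replace = TRUE))] <- 1
  b <- cbind(bg, oh)[, , drop = FALSE]
  b <- b[, model$b_names, drop = FALSE]
  list(cv = cv, b = b)
}

# Pairwise distances between query rows and reference rows under the
# requested metric (cosine distance = 1 - cosine similarity).
pairwise_dist <- function(query, ref, metric) {
  if (metric == "euclidean") {
    qs <- rowSums(query^2); rs <- rowSums(ref^2)
    d2 <- outer(qs, rs, "+") - 2 * tcrossprod(query, ref)
    sqrt(pmax(d2, 0))
  } else {
    qn <- query / pmax(sqrt(rowSums(query^2)), 1e-12)
    rn <- ref / pmax(sqrt(rowSums(ref^2)), 1e-12)
    1 - tcrossprod(qn, rn)
  }
}

#' KNN label transfer from reference to query embeddings
#'
#' Each query cell receives the majority label among its k nearest
#' reference cells under the chosen metric; distance ties favour the
#' earlier reference cell, vote ties the smallest label.
#'
#' @param ref_emb reference embedding matrix
#' @param ref_labels labels aligned to `ref_emb` rows
#' @param query_emb query embedding matrix (same width)
#' @param k neighbour count (default 15)
#' @param metric `"euclidean"` or `"cosine"`
#' @return vector of transferred labels, one per query row
#' @export
transfer_labels <- function(ref_emb, ref_labels, query_emb, k = 15L,
                            metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  ref_emb <- as.matrix(ref_emb); query_emb <- as.matrix(query_emb)
  if (ncol(ref_emb) != ncol(query_emb))
    hv_stop("embedding widths differ (%d vs %d)", ncol(ref_emb), ncol(query_emb))
  k <- min(k, nrow(ref_emb))
  dm <- pairwise_dist(query_emb, ref_emb, metric)
  out <- vapply(seq_len(nrow(query_emb)), function(i) {
    nb <- order(dm[i, ], seq_len(ncol(dm)))[seq_len(k)]
    votes <- table(ref_labels[nb])
    nm <- names(votes)[votes == max(votes)]
    sort(nm)[1]
  }, character(1))
  if (is.integer(ref_labels)) as.integer(out)
  else if (is.numeric(ref_labels)) as.numeric(out)
  else out
}

# Pair-counting ARI on a (possibly real-valued) contingency table,
# using the comb2 extension x(x-1)/2.
ari_from_contingency <- function(tab) {
  comb2 <- function(x) x * (x - 1) / 2
  n <- sum(tab)
  sum_ij <- sum(comb2(tab))
  a <- sum(comb2(rowSums(tab)))
  b <- sum(comb2(colSums(tab)))
  expected <- a * b / comb2(n)
  mx <- (a + b) / 2
  if (abs(mx - expected) < 1e-12) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Adjusted and balanced adjusted Rand index
#'
#' The ARI is the standard pair-counting chance-adjusted agreement
#' between two partitions of the same cells. The balanced variant
#' rescales the classes of the first partition to equal mass before
#' adjustment, so under- and over-represented classes weigh equally; on
#' balanced partitions it coincides with the plain ARI.
#'
#' @param labels_a,labels_b two label vectors of equal length
#' @return list with `ari` and `balanced_ari`
#' @export
compare_partitions <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    hv_stop("partitions have different lengths")
  tab <- table(labels_a, labels_b)
  K <- nrow(tab)
  target <- sum(tab) / K
  btab <- tab * (target / pmax(rowSums(tab), 1e-300))
  list(ari = ari_from_contingency(tab),
       balanced_ari = ari_from_contingency(btab))
}

#' Project a query dataset onto a reference model
#'
#' Full projection protocol: harmonize the query covariates to the
#' reference schema, embed the query with the reference model (reference
#' feature scaling is reused — the projection never peeks at query
#' statistics), transfer the reference cluster labels by KNN in the
#' chosen space, and, when ground-truth labels for the query are given,
#' score the transfer with ARI and balanced ARI.
#'
#' @param model reference `hmivae_model`
#' @param ref_latent reference `hv_latent` from [embed_all()]
#' @param ref_labels reference cluster labels aligned to `ref_latent`
#' @param query query `hv_cellviews`
#' @param space `"integrated"` or one of `"E"`, `"NC"`, `"M"`, `"SC"`
#' @param metric `"euclidean"` or `"cosine"`
#' @param k KNN size (default 15)
#' @param seed seed for the randomized one-hot in harmonization
#' @param ground_truth optional query labels for evaluation
#' @return list of class `hv_projection`: transferred `labels`, `space`,
#'   `metric`, and `ari`/`balanced_ari` (NA without ground truth)
#' @export
project_query <- function(model, ref_latent, ref_labels, query,
                          space = "integrated",
                          metric = c("euclidean", "cosine"), k = 15L,
                          seed = 0L, ground_truth = NULL) {
  metric <- match.arg(metric)
  harm <- harmonize_covariates(model, query, seed = seed)
  q_latent <- embed_all(model, harm$cv, b = harm$b)
  pick <- function(lat) if (space == "integrated") lat$z else lat$emb[[space]]
  labels <- transfer_labels(pick(ref_latent), ref_labels, pick(q_latent),
                            k = k, metric = metric)
  ari <- balanced_ari <- NA_real_
  if (!is.null(ground_truth)) {
    sc <- compare_partitions(ground_truth, labels)
    ari <- sc$ari; balanced_ari <- sc$balanced_ari
  }
  structure(list(labels = labels, space = space, metric = metric, k = k,
                 ari = ari, balanced_ari = balanced_ari),
            class = "hv_projection")
}
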