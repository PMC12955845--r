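# The multi-view conditional VAE.
#
# Each of the four views (E = mean expression, NC = nuclear
# co-localization, M = morphology, SC = spatial context) is encoded by a
# view-specific branch (the view's features concatenated with the
# technical covariates b); the four view embeddings are concatenated,
# passed through an additional hidden layer, and mapped to the mean and
# log-variance of a diagonal-Gaussian posterior over the latent z. The
# decoder mirrors this: z concatenated with b passes through a merge
# layer and view-specific branches that reconstruct each view
# separately. The ELBO weights each view's unit-variance Gaussian
# reconstruction likelihood by lambda_j and the KL term by beta.

VIEW_NAMES <- c("E", "NC", "M", "SC")

#' Model configuration
#'
#' Holds the architecture and optimization hyperparameters of the VAE.
#' Grid defaults follow the published tuning lattice; see
#' [default_grid()].
#'
#' @param n_hidden_layers hidden layers per view branch (1 or 2)
#' @param hidden_size nodes per hidden layer (grid: 8, 32, 64)
#' @param latent_dim latent dimension (grid: 10 or 20)
#' @param lambda non-negative view weights, length 4, order E, NC, M, SC
#' @param beta_scheme `"warmup"` (KL weight 0 at epoch 0, +`beta_increment`
#'   per epoch, capped at 1) or `"constant"` (1 throughout)
#' @param beta_increment warm-up increment per epoch (default 0.1)
#' @param batch_size minibatch size (capped at the training-set size)
#' @param seed RNG seed controlling initialization, splits, shuffling and
#'   reparameterization noise
#' @param view_embed_dim width of each view embedding; defaults to
#'   `hidden_size`
#' @param learning_rate Adam learning rate (untuned default)
#' @param epochs maximum training epochs
#' @param patience early-stopping patience in epochs
#' @return a validated list of class `hv_config`
#' @export
model_config <- function(n_hidden_layers = 1L, hidden_size = 32L,
                         latent_dim = 10L,
                         lambda = c(E = 1, NC = 1, M = 1, SC = 1),
                         beta_scheme = c("warmup", "constant"),
                         beta_increment = 0.1, batch_size = 128L,
                         seed = 0L, view_embed_dim = hidden_size,
                         learning_rate = 1e-3, epochs = 200L,
                         patience = 10L) {
  beta_scheme <- match.arg(beta_scheme)
  lambda <- unlist(lambda)
  if (length(lambda) != 4L) hv_stop("lambda must have length 4 (E, NC, M, SC)")
  names(lambda) <- VIEW_NAMES
  if (any(lambda < 0)) hv_stop("view weights lambda must be non-negative")
  if (!n_hidden_layers %in% 1:2) hv_stop("n_hidden_layers must be 1 or 2")
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 hidden_size = as.integer(hidden_size),
                 latent_dim = as.integer(latent_dim), lambda = lambda,
                 beta_scheme = beta_scheme, beta_increment = beta_increment,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 view_embed_dim = as.integer(view_embed_dim),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 patience = as.integer(patience)),
            class = "hv_config")
}

#' The published hyperparameter tuning lattice
#'
#' Seeds 0/1/42/123/1234; 1 or 2 hidden layers; hidden sizes 8/32/64;
#' latent dimension 10 or 20; KL warm-up vs constant; batch sizes
#' 40000/16000/8000/5333/4000 (sized for cohorts of ~1e6 cells — shrink
#' for small fixtures).
#'
#' @return data.frame with one row per configuration
#' @export
default_grid <- function() {
  expand.grid(seed = c(0L, 1L, 42L, 123L, 1234L),
              n_hidden_layers = 1:2,
              hidden_size = c(8L, 32L, 64L),
              latent_dim = c(10L, 20L),
              beta_scheme = c("warmup", "constant"),
              batch_size = c(40000L, 16000L, 8000L, 5333L, 4000L),
              stringsAsFactors = FALSE)
}

#' KL weight at a given epoch
#'
#' Warm-up starts at zero and adds `increment` after each epoch, capped
#' at 1.0; the constant scheme keeps the weight at 1.0.
#'
#' @param epoch non-negative integer epoch index (0-based)
#' @param scheme `"warmup"` or `"constant"`
#' @param increment per-epoch increment for warm-up
#' @return beta in `[0, 1]`
#' @export
beta_at <- function(epoch, scheme = c("warmup", "constant"), increment = 0.1) {
  scheme <- match.arg(scheme)
  if (any(epoch < 0)) hv_stop("epoch must be non-negative")
  if (scheme == "constant") rep(1, length(epoch)) else pmin(1, increment * epoch)
}

#' Modify view weights for an ablation run
#'
#' Sets the ablated view's weight to 0 and all others to 1; the
#' expression-only run keeps only the expression weight at 1.
#'
#' @param cfg an `hv_config`
#' @param view one of `"E"`, `"NC"`, `"M"`, `"SC"`, `"expression_only"`
#' @return the modified configuration (nothing else changes)
#' @export
ablate <- function(cfg, view = c("E", "NC", "M", "SC", "expression_only")) {
  view <- match.arg(view)
  lam <- c(E = 1, NC = 1, M = 1, SC = 1)
  if (view == "expression_only") {
    lam[] <- 0; lam["E"] <- 1
  } else {
    lam[view] <- 0
  }
  cfg$lambda <- lam
  cfg
}

# ---- architecture -----------------------------------------------------

build_arch <- function(view_dims, b_dim, cfg) {
  h <- cfg$hidden_size; e <- cfg$view_embed_dim; nl <- cfg$n_hidden_layers
  specs <- list()
  for (v in VIEW_NAMES) {
    specs[[paste0("enc_", v)]] <- mlp_spec(
      paste0("enc_", v),
      c(view_dims[[v]] + b_dim, rep(h, nl), e), rep("elu", nl + 1L))
  }
  specs$enc_merge <- mlp_spec("enc_merge", c(4L * e, h), "elu")
  specs$enc_mu <- mlp_spec("enc_mu", c(h, cfg$latent_dim), "linear")
  specs$enc_logvar <- mlp_spec("enc_logvar", c(h, cfg$latent_dim), "linear")
  specs$dec_merge <- mlp_spec("dec_merge", c(cfg$latent_dim + b_dim, h), "elu")
  for (v in VIEW_NAMES) {
    specs[[paste0("dec_", v)]] <- mlp_spec(
      paste0("dec_", v),
      c(h, rep(h, nl), view_dims[[v]]), c(rep("elu", nl), "linear"))
  }
  specs
}

init_model_params <- function(arch) {
  P <- list()
  for (spec in arch) P <- c(P, mlp_init_params(spec))
  P
}

# Standardize the four views (zero mean, unit variance per feature) at
# model input; mixed units (counts, correlations, pixels) make raw
# concatenation ill-conditioned. Scalers are stored on the model and
# reused verbatim when projecting a query dataset.
standardize_views <- function(cv, scalers = NULL) {
  raw <- list(E = cv$Y, NC = cv$S, M = cv$M, SC = cv$C)
  out <- list(); sc <- list()
  for (v in VIEW_NAMES) {
    z <- if (is.null(scalers)) hv_zscore(raw[[v]])
         else hv_zscore(raw[[v]], scalers[[v]]$center, scalers[[v]]$scale)
    out[[v]] <- z$x
    sc[[v]] <- list(center = z$center, scale = z$scale)
  }
  list(X = out, b = as.matrix(cv$b), scalers = if (is.null(scalers)) sc else scalers)
}

check_finite_views <- function(X, b) {
  for (v in names(X))
    if (!all(is.finite(X[[v]])))
      hv_stop("non-finite values in view '%s' input", v)
  if (!all(is.finite(b))) hv_stop("non-finite values in covariates b")
}

# ---- forward / backward ----------------------------------------------

# Full forward pass. eps is the reparameterization noise matrix (0 for
# deterministic posterior-mean evaluation). Returns everything needed
# for the backward pass and for reporting.
vae_forward <- function(P, arch, X, b, eps, lambda, beta) {
  caches <- list(); emb <- list()
  for (v in VIEW_NAMES) {
    f <- mlp_forward(P, arch[[paste0("enc_", v)]], cbind(X[[v]], b))
    emb[[v]] <- f$out; caches[[paste0("enc_", v)]] <- f$cache
  }
  fm <- mlp_forward(P, arch$enc_merge, do.call(cbind, emb[VIEW_NAMES]))
  caches$enc_merge <- fm$cache
  fmu <- mlp_forward(P, arch$enc_mu, fm$out)
  flv <- mlp_forward(P, arch$enc_logvar, fm$out)
  caches$enc_mu <- fmu$cache; caches$enc_logvar <- flv$cache
  mu <- fmu$out; logvar <- flv$out
  z <- mu + exp(0.5 * logvar) * eps
  fd <- mlp_forward(P, arch$dec_merge, cbind(z, b))
  caches$dec_merge <- fd$cache
  recon <- list()
  for (v in VIEW_NAMES) {
    fr <- mlp_forward(P, arch[[paste0("dec_", v)]], fd$out)
    recon[[v]] <- fr$out; caches[[paste0("dec_", v)]] <- fr$cache
  }
  n <- nrow(mu)
  kl_row <- 0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
  sse <- vapply(VIEW_NAMES, function(v)
    sum((X[[v]] - recon[[v]])^2), numeric(1))
  loss <- (sum(lambda[VIEW_NAMES] * 0.5 * sse) + beta * sum(kl_row)) / n
  list(emb = emb, mu = mu, logvar = logvar, z = z, recon = recon,
       caches = caches, loss = loss, kl_row = kl_row)
}

vae_backward <- function(P, arch, X, b, eps, lambda, beta, fw) {
  n <- nrow(fw$mu)
  grads <- list()
  dH_dec <- 0
  for (v in VIEW_NAMES) {
    dRecon <- lambda[[v]] * (fw$recon[[v]] - X[[v]]) / n
    bk <- mlp_backward(P, arch[[paste0("dec_", v)]],
                       fw$caches[[paste0("dec_", v)]], dRecon)
    grads <- grad_accumulate(grads, bk$grads)
    dH_dec <- dH_dec + bk$dX
  }
  bk <- mlp_backward(P, arch$dec_merge, fw$caches$dec_merge, dH_dec)
  grads <- grad_accumulate(grads, bk$grads)
  d_latent <- ncol(fw$mu)
  dz <- bk$dX[, seq_len(d_latent), drop = FALSE]
  dmu <- dz + beta * fw$mu / n
  dlogvar <- dz * eps * 0.5 * exp(0.5 * fw$logvar) +
    beta * 0.5 * (exp(fw$logvar) - 1) / n
  bmu <- mlp_backward(P, arch$enc_mu, fw$caches$enc_mu, dmu)
  blv <- mlp_backward(P, arch$enc_logvar, fw$caches$enc_logvar, dlogvar)
  grads <- grad_accumulate(grads, bmu$grads)
  grads <- grad_accumulate(grads, blv$grads)
  bm <- mlp_backward(P, arch$enc_merge, fw$caches$enc_merge, bmu$dX + blv$dX)
  grads <- grad_accumulate(grads, bm$grads)
  e <- ncol(fw$emb[[1]])
  for (i in seq_along(VIEW_NAMES)) {
    v <- VIEW_NAMES[i]
    dEmb <- bm$dX[, ((i - 1L) * e + 1L):(i * e), drop = FALSE]
    bv <- mlp_backward(P, arch[[paste0("enc_", v)]],
                       fw$caches[[paste0("enc_", v)]], dEmb)
    grads <- grad_accumulate(grads, bv$grads)
  }
  grads
}

# ---- ELBO -------------------------------------------------------------

#' ELBO decomposition
#'
#' Computes the evidence lower bound
#' `sum_j lambda_j * LL_j - beta * KL`, per-cell averaged. `LL_j` is the
#' unit-variance Gaussian log-likelihood of view j's (standardized)
#' features under the reconstruction mean; the KL term is the
#' closed-form divergence between the diagonal-Gaussian posterior and a
#' standard normal, summed over latent dimensions.
#'
#' @param x named list of view feature matrices (E, NC, M, SC)
#' @param recon named list of reconstruction means, same shapes
#' @param mu,logvar posterior parameters, N x latent_dim
#' @param lambda non-negative view weights (length 4)
#' @param beta non-negative KL weight
#' @return list with `total` (per-cell mean ELBO), `ll` (named per-view
#'   per-cell mean log-likelihoods), `kl` (per-cell mean divergence)
#' @export
elbo_components <- function(x, recon, mu, logvar, lambda, beta) {
  lambda <- unlist(lambda)
  if (any(lambda < 0)) hv_stop("lambda must be non-negative")
  if (beta < 0) hv_stop("beta must be non-negative")
  if (is.null(names(lambda))) names(lambda) <- VIEW_NAMES
  n <- nrow(mu)
  ll <- vapply(VIEW_NAMES, function(v) {
    p <- ncol(x[[v]])
    sum(-0.5 * (x[[v]] - recon[[v]])^2) / n - 0.5 * p * log(2 * pi)
  }, numeric(1))
  kl <- sum(0.5 * (mu^2 + exp(logvar) - 1 - logvar)) / n
  list(total = sum(lambda[VIEW_NAMES] * ll) - beta * kl, ll = ll, kl = kl)
}

# ---- training ---------------------------------------------------------

# Stratified-by-sample train/validation/test split.
split_by_sample <- function(sample_ids, fractions = c(0.70, 0.15, 0.15)) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (s in unique(sample_ids)) {
    rows <- sample(which(sample_ids == s))
    n <- length(rows)
    n_tr <- max(1L, round(fractions[1] * n))
    n_va <- max(1L, round(fractions[2] * n))
    n_tr <- min(n_tr, n - min(n - 1L, 2L))
    out$train <- c(out$train, rows[seq_len(n_tr)])
    out$val <- c(out$val, rows[n_tr + seq_len(min(n_va, n - n_tr))])
    if (n > n_tr + n_va)
      out$test <- c(out$test, rows[(n_tr + n_va + 1L):n])
  }
  if (!length(out$test)) out$test <- out$val
  out
}

#' Train the multi-view conditional VAE
#'
#' Minibatch Adam optimization of the negative ELBO with the configured
#' KL warm-up, early stopping on validation loss (evaluated at the full
#' KL weight so epochs are comparable under warm-up), and restoration of
#' the best parameters. Deterministic given `cfg$seed`.
#'
#' @param cv an `hv_cellviews`
#' @param cfg an `hv_config`
#' @param split train/validation/test fractions (sum to 1), applied per
#'   sample
#' @param verbose print per-epoch losses
#' @return an object of class `hmivae_model` with elements `P`
#'   (parameters), `arch`, `cfg`, `scalers`, `split`, `log` (epoch,
#'   beta, train and validation loss), and the covariate schema
#' @export
train_hmivae <- function(cv, cfg = model_config(), split = c(0.70, 0.15, 0.15),
                         verbose = FALSE) {
  stopifnot(inherits(cv, "hv_cellviews"), inherits(cfg, "hv_config"))
  set.seed(cfg$seed)
  sv <- standardize_views(cv)
  check_finite_views(sv$X, sv$b)
  view_dims <- lapply(sv$X, ncol)
  arch <- build_arch(view_dims, ncol(sv$b), cfg)
  P <- init_model_params(arch)
  opt <- adam_init(P, lr = cfg$learning_rate)
  idx <- split_by_sample(cv$sample_ids, split)
  lam <- cfg$lambda
  take <- function(rows) list(
    X = lapply(sv$X, function(m) m[rows, , drop = FALSE]),
    b = sv$b[rows, , drop = FALSE])
  val <- take(idx$val)
  eval_loss <- function(rows_data, beta) {
    n <- nrow(rows_data$b)
    fw <- vae_forward(P, arch, rows_data$X, rows_data$b,
                      eps = matrix(0, n, cfg$latent_dim), lam, beta)
    fw$loss
  }
  best <- list(loss = Inf, P = P, epoch = -1L)
  log <- data.frame(epoch = integer(0), beta = numeric(0),
                    train_loss = numeric(0), val_loss = numeric(0))
  bs <- min(cfg$batch_size, length(idx$train))
  for (epoch in 0:(cfg$epochs - 1L)) {
    beta <- beta_at(epoch, cfg$beta_scheme, cfg$beta_increment)
    ord <- sample(idx$train)
    starts <- seq(1L, length(ord), by = bs)
    tr_loss <- 0
    for (s0 in starts) {
      rows <- ord[s0:min(s0 + bs - 1L, length(ord))]
      batch <- take(rows)
      eps <- matrix(stats::rnorm(length(rows) * cfg$latent_dim),
                    length(rows), cfg$latent_dim)
      fw <- vae_forward(P, arch, batch$X, batch$b, eps, lam, beta)
      if (!is.finite(fw$loss))
        hv_stop("training diverged (non-finite loss) at epoch %d; last train loss %.4g",
                epoch, tr_loss)
      g <- vae_backward(P, arch, batch$X, batch$b, eps, lam, beta, fw)
      st <- adam_step(opt, P, g)
      opt <- st$opt; P <- st$P
      tr_loss <- tr_loss + fw$loss * length(rows)
    }
    tr_loss <- tr_loss / length(idx$train)
    vl <- eval_loss(val, beta = 1)
    log <- rbind(log, data.frame(epoch = epoch, beta = beta,
                                 train_loss = tr_loss, val_loss = vl))
    if (verbose) hv_log("epoch %d beta %.2f train %.4f val %.4f", epoch, beta,
                        tr_loss, vl)
    if (vl < best$loss - 1e-8) {
      best <- list(loss = vl, P = P, epoch = epoch)
    } else if (epoch - best$epoch >= cfg$patience) {
      break
    }
  }
  structure(list(P = best$P, arch = arch, cfg = cfg, scalers = sv$scalers,
                 view_dims = view_dims, b_names = colnames(cv$b),
                 sample_levels = cv$sample_levels, proteins = cv$proteins,
                 split = idx, log = log, best_epoch = best$epoch),
            class = "hmivae_model")
}

#' @method print hmivae_model
#' @export
print.hmivae_model <- function(x, ...) {
  cat(sprintf(
    "hmivae_model: latent %d, hidden %dx%d, lambda (%s), best epoch %d (val loss %.4f)\n",
    x$cfg$latent_dim, x$cfg$n_hidden_layers, x$cfg$hidden_size,
    paste(x$cfg$lambda, collapse = ", "), x$best_epoch,
    min(x$log$val_loss)))
  invisible(x)
}

# Prepare (standardize) a cellviews object with the model's scalers,
# validating the covariate schema.
model_inputs <- function(model, cv, b = NULL) {
  sv <- standardize_views(cv, model$scalers)
  bmat <- if (is.null(b)) sv$b else as.matrix(b)
  if (ncol(bmat) != length(model$b_names))
    hv_stop("covariate width %d does not match the model's %d (harmonize first?)",
            ncol(bmat), length(model$b_names))
  check_finite_views(sv$X, bmat)
  list(X = sv$X, b = bmat)
}

#' Encode cells into the latent space
#'
#' Deterministic given parameters and inputs (no sampling); batch
#' composition does not affect per-cell outputs.
#'
#' @param model a trained `hmivae_model`
#' @param cv an `hv_cellviews` (standardized internally with the model's
#'   stored scalers)
#' @param b optional replacement covariate matrix (e.g. harmonized query
#'   covariates); defaults to `cv$b`
#' @return list with `emb` (named list of view embeddings), `mu`,
#'   `logvar`
#' @export
vae_encode <- function(model, cv, b = NULL) {
  inp <- model_inputs(model, cv, b)
  fw <- vae_forward(model$P, model$arch, inp$X, inp$b,
                    eps = matrix(0, nrow(inp$b), model$cfg$latent_dim),
                    model$cfg$lambda, beta = 1)
  list(emb = fw$emb, mu = fw$mu, logvar = fw$logvar)
}

#' Decode latent representations into view reconstruction means
#'
#' @param model a trained `hmivae_model`
#' @param z N x latent_dim matrix
#' @param b N x B covariate matrix matching the model schema
#' @return named list of four reconstruction-mean matrices with widths
#'   (P, P, 5, 2P + 5)
#' @export
vae_decode <- function(model, z, b) {
  z <- as.matrix(z); b <- as.matrix(b)
  if (ncol(z) != model$cfg$latent_dim)
    hv_stop("z has %d columns, expected latent_dim %d", ncol(z),
            model$cfg$latent_dim)
  if (ncol(b) != length(model$b_names))
    hv_stop("b has %d columns, expected %d", ncol(b), length(model$b_names))
  fd <- mlp_forward(model$P, model$arch$dec_merge, cbind(z, b))
  recon <- list()
  for (v in VIEW_NAMES)
    recon[[v]] <- mlp_forward(model$P, model$arch[[paste0("dec_", v)]], fd$out)$out
  recon
}

#' Embed a whole dataset
#'
#' Passes every cell through the trained model using the posterior mean
#' (no sampling), yielding the integrated latent space, the four
#' view-specific embeddings, and per-cell ELBO components.
#'
#' @param model a trained `hmivae_model`
#' @param cv an `hv_cellviews`
#' @param b optional replacement covariates (see [vae_encode()])
#' @return object of class `hv_latent`: `z` (N x latent_dim), `emb`
#'   (named list of view embeddings), `ll` (per-view per-cell mean
#'   reconstruction log-likelihood), `kl`, plus cell/sample ids
#' @export
embed_all <- function(model, cv, b = NULL) {
  inp <- model_inputs(model, cv, b)
  n <- nrow(inp$b)
  fw <- vae_forward(model$P, model$arch, inp$X, inp$b,
                    eps = matrix(0, n, model$cfg$latent_dim),
                    model$cfg$lambda, beta = 1)
  comp <- elbo_components(inp$X, fw$recon, fw$mu, fw$logvar,
                          model$cfg$lambda, beta = 1)
  structure(list(z = fw$mu, emb = fw$emb, ll = comp$ll, kl = comp$kl,
                 elbo = comp$total,
                 recon_mse = vapply(VIEW_NAMES, function(v)
                   mean((inp$X[[v]] - fw$recon[[v]])^2), numeric(1)),
                 cell_ids = cv$cell_ids, sample_ids = cv$sample_ids),
            class = "hv_latent")
}

#' Exhaustive hyperparameter grid search
#'
#' Trains one model per grid row (shared split fractions) and selects
#' the configuration with the best held-out per-cell mean reconstruction
#' log-likelihood over the test split. Ties break toward the smaller
#' model (fewer parameters), then the lower seed.
#'
#' @param cv an `hv_cellviews`
#' @param grid data.frame of configuration columns (any subset of the
#'   [model_config()] arguments); see [default_grid()]
#' @param epochs,patience overrides applied to every configuration
#' @return list with `best` (an `hv_config`), `table` (per-config test
#'   log-likelihood), and `models` (trained models, in grid order)
#' @export
grid_search_hmivae <- function(cv, grid, epochs = 50L, patience = 10L) {
  if (!nrow(grid)) hv_stop("empty hyperparameter grid")
  res <- vector("list", nrow(grid))
  scores <- numeric(nrow(grid)); npar <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    args <- as.list(grid[i, , drop = FALSE])
    args$beta_scheme <- as.character(args$beta_scheme %||% "warmup")
    args <- args[names(args) %in% names(formals(model_config))]
    cfg <- do.call(model_config, args)
    cfg$epochs <- as.integer(epochs); cfg$patience <- as.integer(patience)
    m <- train_hmivae(cv, cfg)
    res[[i]] <- m
    test_rows <- m$split$test
    sv <- standardize_views(cv, m$scalers)
    tX <- lapply(sv$X, function(x) x[test_rows, , drop = FALSE])
    tb <- sv$b[test_rows, , drop = FALSE]
    fw <- vae_forward(m$P, m$arch, tX, tb,
                      eps = matrix(0, length(test_rows), cfg$latent_dim),
                      cfg$lambda, beta = 1)
    comp <- elbo_components(tX, fw$recon, fw$mu, fw$logvar,
                            lambda = c(E = 1, NC = 1, M = 1, SC = 1), beta = 1)
    scores[i] <- sum(comp$ll)
    npar[i] <- sum(vapply(m$P, length, numeric(1)))
  }
  ord <- order(-scores, npar, grid$seed %||% seq_len(nrow(grid)))
  tab <- cbind(grid, test_loglik = scores, n_params = npar)
  list(best = res[[ord[1]]]$cfg, best_model = res[[ord[1]]],
       table = tab[ord, , drop = FALSE], models = res)
}

# ---- checkpoint I/O (plain text) --------------------------------------

#' Save a trained model as a plain-text checkpoint
#'
#' Writes the parameter dictionary, configuration and data schema to a
#' JSON file (full float precision).
#' @param model an `hmivae_model`
#' @param path output .json path
#' @export
save_model <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ser <- list(
    cfg = unclass(model$cfg),
    params = lapply(model$P, function(x)
      if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
      else list(dim = NULL, data = as.numeric(x))),
    scalers = model$scalers, view_dims = model$view_dims,
    b_names = model$b_names, sample_levels = model$sample_levels,
    proteins = model$proteins, best_epoch = model$best_epoch,
    log = model$log)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path .json checkpoint
#' @return an `hmivae_model`
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, ser$cfg[names(ser$cfg) %in% names(formals(model_config))])
  cfg$epochs <- as.integer(ser$cfg$epochs); cfg$patience <- as.integer(ser$cfg$patience)
  P <- lapply(ser$params, function(p)
    if (!is.null(p$dim) && length(p$dim)) array(p$data, dim = p$dim) else p$data)
  view_dims <- as.list(ser$view_dims)
  arch <- build_arch(view_dims, length(ser$b_names), cfg)
  scalers <- lapply(ser$scalers, function(s)
    list(center = unlist(s$center), scale = unlist(s$scale)))
  structure(list(P = P, arch = arch, cfg = cfg, scalers = scalers,
                 view_dims = view_dims, b_names = ser$b_names,
                 sample_levels = ser$sample_levels, proteins = ser$proteins,
                 split = NULL, log = as.data.frame(ser$log),
                 best_epoch = ser$best_epoch),
            class = "hmivae_model")
}
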