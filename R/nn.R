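# Minimal dense-network machinery: forward, reverse-mode gradients and
# Adam, in base R matrix code. No deep-learning framework is assumed.
# Parameters live in a flat named list of matrices/vectors so that the
# optimizer and finite-difference gradient checks can treat the model
# generically.
#
# Conventions: a batch is rows; a dense layer computes A = X %*% W + b
# with W of shape (in x out). Activations: "elu" or "linear".

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

# An MLP spec: list(name, sizes = c(in, h1, ..., out), acts = chr vector
# of length(sizes) - 1.
mlp_spec <- function(name, sizes, acts) {
  stopifnot(length(acts) == length(sizes) - 1L)
  list(name = name, sizes = sizes, acts = acts)
}

mlp_param_names <- function(spec) {
  unlist(lapply(seq_along(spec$acts), function(l)
    paste0(spec$name, ".l", l, c(".W", ".b"))))
}

mlp_init_params <- function(spec) {
  P <- list()
  for (l in seq_along(spec$acts)) {
    fan_in <- spec$sizes[l]; fan_out <- spec$sizes[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    P[[paste0(spec$name, ".l", l, ".W")]] <-
      matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
    P[[paste0(spec$name, ".l", l, ".b")]] <- rep(0, fan_out)
  }
  P
}

# Forward pass; returns list(out, cache). cache$X[[l]] is layer input,
# cache$A[[l]] the pre-activation.
mlp_forward <- function(P, spec, X) {
  Xs <- vector("list", length(spec$acts))
  As <- vector("list", length(spec$acts))
  H <- X
  for (l in seq_along(spec$acts)) {
    Xs[[l]] <- H
    W <- P[[paste0(spec$name, ".l", l, ".W")]]
    b <- P[[paste0(spec$name, ".l", l, ".b")]]
    A <- H %*% W
    A <- sweep(A, 2, b, "+")
    As[[l]] <- A
    H <- switch(spec$acts[l], elu = elu(A), linear = A,
                hv_stop("unknown activation '%s'", spec$acts[l]))
  }
  list(out = H, cache = list(X = Xs, A = As))
}

# Reverse pass: dOut is the gradient of the scalar loss w.r.t. the MLP
# output. Returns list(grads = named list matching parameter names,
# dX = gradient w.r.t. the input batch).
mlp_backward <- function(P, spec, cache, dOut) {
  grads <- list()
  dH <- dOut
  for (l in rev(seq_along(spec$acts))) {
    A <- cache$A[[l]]
    dA <- switch(spec$acts[l], elu = dH * elu_grad(A), linear = dH)
    Xl <- cache$X[[l]]
    grads[[paste0(spec$name, ".l", l, ".W")]] <- crossprod(Xl, dA)
    grads[[paste0(spec$name, ".l", l, ".b")]] <- colSums(dA)
    dH <- dA %*% t(P[[paste0(spec$name, ".l", l, ".W")]])
  }
  list(grads = grads, dX = dH)
}

# Adam with bias correction over a flat named parameter list.
adam_init <- function(P, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(P, function(x) x * 0), v = lapply(P, function(x) x * 0))
}

adam_step <- function(opt, P, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  for (nm in names(P)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    mhat <- opt$m[[nm]] / (1 - b1^opt$t)
    vhat <- opt$v[[nm]] / (1 - b2^opt$t)
    P[[nm]] <- P[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  list(opt = opt, P = P)
}

# Sum two flat gradient lists (union of names).
grad_accumulate <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
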