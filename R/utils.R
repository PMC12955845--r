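# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#'
#' All user-facing errors raised by the package carry class
#' `hmivae_error` so callers can trap them selectively.
#' @noRd
hv_stop <- function(msg, ..., class = "hmivae_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

hv_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

#' Column-wise z-scoring with zero-variance guard
#'
#' Columns with (near) zero variance map to all-zero columns rather
#' than NaN, keeping downstream matrices finite.
#' @param x numeric matrix
#' @param center,scale optional precomputed statistics (reused when
#'   projecting a query dataset with reference scaling)
#' @return list with `x` (scaled matrix), `center`, `scale`
#' @noRd
hv_zscore <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[!is.finite(scale) | scale < 1e-12] <- 0
  }
  out <- sweep(x, 2, center, "-")
  nz <- scale > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, scale[nz], "/")
  out[, !nz] <- 0
  list(x = out, center = center, scale = scale)
}

#' Pearson correlation returning 0 on degenerate input
#'
#' Degenerate cases (fewer than 3 observations, or a constant vector on
#' either side) yield 0 rather than NA so that feature matrices stay
#' finite for the VAE.
#' @noRd
hv_safe_cor <- function(a, b) {
  if (length(a) < 3L) return(0)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa < 1e-12 || sb < 1e-12) return(0)
  r <- stats::cor(a, b)
  if (!is.finite(r)) 0 else r
}

#' Derive a bounded child seed from a top-level seed
#'
#' A single pipeline seed fans out deterministically to per-stage seeds;
#' results stay below 2^31 so they remain valid R integers.
#' @noRd
hv_child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

hv_log <- function(fmt, ...) {
  message(sprintf("[hmivae %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}
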