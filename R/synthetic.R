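# Synthetic IMC-like fixture generator. Produces pixel-level
# multi-channel images, segmentation masks, channel tables and clinical
# tables with known ground truth, so every other module is testable
# without any external download.
#
# Cells are axis-aligned ellipses with an inner nuclear ellipse; the two
# DNA-intercalator channels are bright on nuclear pixels. Each protein's
# signal is split between nuclear and cytoplasmic pixels according to
# its nuclear_fraction, pixel counts are Poisson, and a per-sample
# intensity multiplier emulates staining-efficiency batch effects.

SYNTH_PROTEINS <- c("CD3", "CD45", "CK8/18", "GATA3", "CK5", "CK14",
                    "CD20", "SMA")

#' Specification of a synthetic dataset
#'
#' Defaults describe the package's reference fixture: 3 samples of
#' about 200 cells each on a 160 x 160 grid, 4 spatially clustered cell
#' phenotypes with two marker proteins apiece (8 proteins + 2 DNA
#' intercalators), one strongly nuclear protein (GATA3), a modest
#' per-sample intensity batch effect, and clinical labels correlated
#' with the prevalence of the first phenotype.
#'
#' @param n_samples number of samples (images)
#' @param grid image size in pixels, (rows, cols)
#' @param cells_per_sample target cell count per sample
#' @param n_cell_types number of phenotypes K
#' @param proteins protein names (panel size P)
#' @param mean_expression K x P matrix of per-type mean pixel rates;
#'   default gives each type two high markers (rate 12) on a low
#'   background (rate 1)
#' @param nuclear_fraction per-protein fraction of signal placed on
#'   nuclear pixels, in `[0, 1]`
#' @param mixing K x K spatial mixing matrix (rows sum to 1): the type
#'   composition of the image band whose primary phenotype is the row
#'   type
#' @param batch_effect per-sample intensity multipliers (length
#'   `n_samples`)
#' @param clinical_effect log-odds of the "high" grade category per unit
#'   of (centred) planted-type prevalence
#' @param survival_effect log hazard ratio per standardized
#'   planted-type prevalence
#' @param noise `"poisson"` (counts, default) or `"gaussian"`
#' @param seed RNG seed; identical seeds give bit-identical output
#' @return validated list of class `hv_synthspec`
#' @export
synthetic_spec <- function(n_samples = 3L, grid = c(160L, 160L),
                           cells_per_sample = 200L, n_cell_types = 4L,
                           proteins = SYNTH_PROTEINS,
                           mean_expression = NULL,
                           nuclear_fraction = NULL,
                           mixing = NULL,
                           batch_effect = NULL,
                           clinical_effect = 8,
                           survival_effect = 0.5,
                           noise = c("poisson", "gaussian"),
                           seed = 0L) {
  noise <- match.arg(noise)
  P <- length(proteins); K <- as.integer(n_cell_types)
  if (is.null(mean_expression)) {
    mean_expression <- matrix(1, K, P, dimnames = list(NULL, proteins))
    for (t in seq_len(K)) {
      hi <- ((t - 1L) * 2L + 1L):min((t - 1L) * 2L + 2L, P)
      mean_expression[t, ((hi - 1L) %% P) + 1L] <- 12
    }
  }
  if (is.null(nuclear_fraction)) {
    nuclear_fraction <- rep(0.15, P)
    nuclear_fraction[proteins == "GATA3"] <- 0.9
  }
  if (is.null(mixing)) {
    mixing <- matrix(0.3 / (K - 1), K, K)
    diag(mixing) <- 0.7
  }
  if (is.null(batch_effect))
    batch_effect <- exp(seq(log(0.8), log(1.25), length.out = n_samples))
  stopifnot(nrow(mean_expression) == K, ncol(mean_expression) == P,
            length(nuclear_fraction) == P, all(nuclear_fraction >= 0),
            all(nuclear_fraction <= 1), all(mean_expression >= 0),
            nrow(mixing) == K, ncol(mixing) == K,
            all(abs(rowSums(mixing) - 1) < 1e-9),
            length(batch_effect) == n_samples, all(batch_effect > 0))
  structure(list(n_samples = as.integer(n_samples), grid = as.integer(grid),
                 cells_per_sample = as.integer(cells_per_sample),
                 n_cell_types = K, proteins = proteins,
                 mean_expression = mean_expression,
                 nuclear_fraction = nuclear_fraction, mixing = mixing,
                 batch_effect = batch_effect,
                 clinical_effect = clinical_effect,
                 survival_effect = survival_effect, noise = noise,
                 seed = as.integer(seed)),
            class = "hv_synthspec")
}

# Rasterize one elliptical cell; returns linear indices of its pixels
# and of its nuclear pixels within a (ny x nx) image.
rasterize_cell <- function(cy, cx, ry, rx, ny, nx, nuc_scale = 0.55) {
  ys <- max(0, floor(cy - ry)):min(ny - 1, ceiling(cy + ry))
  xs <- max(0, floor(cx - rx)):min(nx - 1, ceiling(cx + rx))
  gy <- rep(ys, times = length(xs)); gx <- rep(xs, each = length(ys))
  inside <- ((gx - cx) / rx)^2 + ((gy - cy) / ry)^2 <= 1
  nuc <- ((gx - cx) / (nuc_scale * rx))^2 + ((gy - cy) / (nuc_scale * ry))^2 <= 1
  lin <- gy[inside] + ny * gx[inside] + 1L
  list(pixels = lin, nuclear = gy[inside & nuc] + ny * gx[inside & nuc] + 1L)
}

#' Generate a synthetic dataset
#'
#' Places non-overlapping elliptical cells on a jittered grid, assigns
#' spatially clustered phenotypes via the mixing matrix (vertical image
#' bands own a primary type), draws pixel counts, and builds per-sample
#' clinical labels whose "grade" is logistic in the planted first
#' phenotype's prevalence. Deterministic given `spec$seed`.
#'
#' @param spec an `hv_synthspec`
#' @return list with `samples` (list of `stack`/`mask`/`channels`
#'   triplets), `clinical` (data.frame with grade, stage, survival),
#'   and `truth` (per-cell sample_id, cell_id, type, centroid,
#'   realized nuclear area fraction)
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "hv_synthspec"))
  set.seed(spec$seed)
  ny <- spec$grid[1]; nx <- spec$grid[2]
  P <- length(spec$proteins); K <- spec$n_cell_types
  rmax <- 3.8
  spacing <- ceiling(2 * rmax + 2)
  cy0 <- seq(rmax + 1, ny - rmax - 2, by = spacing)
  cx0 <- seq(rmax + 1, nx - rmax - 2, by = spacing)
  n_slots <- length(cy0) * length(cx0)
  if (n_slots < spec$cells_per_sample)
    hv_stop(paste0("cannot pack %d cells of radius <= %.1f on a %dx%d grid ",
                   "(only %d slots); use a larger grid or smaller cells"),
            spec$cells_per_sample, rmax, ny, nx, n_slots)
  chan <- channel_map(data.frame(
    channel_index = 0:(P + 1L),
    protein_name = c("DNA1", "DNA2", spec$proteins),
    is_dna_intercalator = c(TRUE, TRUE, rep(FALSE, P)),
    is_background = FALSE))
  samples <- vector("list", spec$n_samples)
  truth <- list()
  prev1 <- numeric(spec$n_samples)
  for (s in seq_len(spec$n_samples)) {
    sid <- sprintf("sample_%02d", s)
    slots <- expand.grid(cy = cy0, cx = cx0)
    take <- sample(nrow(slots), spec$cells_per_sample)
    mult <- spec$batch_effect[s]
    mask <- matrix(0L, ny, nx)
    arr <- array(0, dim = c(ny, nx, P + 2L))
    is_nuc <- matrix(FALSE, ny, nx)
    rec <- vector("list", length(take))
    for (i in seq_along(take)) {
      cy <- slots$cy[take[i]] + stats::runif(1, -1, 1)
      cx <- slots$cx[take[i]] + stats::runif(1, -1, 1)
      band <- pmin(K, pmax(1L, ceiling(cx / nx * K)))   # primary type by x band
      type <- sample.int(K, 1L, prob = spec$mixing[band, ])
      ry <- stats::runif(1, 2.2, rmax); rx <- stats::runif(1, 2.2, rmax)
      px <- rasterize_cell(cy, cx, ry, rx, ny, nx)
      label <- i * 2L + 1L            # deliberately non-sequential labels
      mask[px$pixels] <- label
      is_nuc[px$nuclear] <- TRUE
      rec[[i]] <- data.frame(sample_id = sid, cell_id = label, type = type,
                             centroid_y = cy, centroid_x = cx,
                             nuclear_area_fraction =
                               length(px$nuclear) / length(px$pixels))
    }
    truth_s <- do.call(rbind, rec)
    # channel rates: DNA bright on nuclei; proteins split by nuclear_fraction
    # with rates normalized so the per-cell pixel mean stays ~ rate * mult
    draw <- function(lam) {
      lam <- pmax(lam, 0)
      if (spec$noise == "poisson") stats::rpois(length(lam), lam)
      else pmax(0, stats::rnorm(length(lam), lam, sqrt(pmax(lam, 1e-6))))
    }
    cellpix <- mask > 0L
    for (d in 1:2) {
      lam <- matrix(0.05 * mult, ny, nx)
      lam[cellpix] <- 0.3 * mult
      lam[is_nuc] <- 10 * mult
      arr[, , d] <- draw(lam)
    }
    fr_nuc <- sum(is_nuc) / max(sum(cellpix), 1L)
    for (p in seq_len(P)) {
      nf <- spec$nuclear_fraction[p]
      lam <- matrix(0.05 * mult, ny, nx)
      base <- spec$mean_expression[truth_s$type[match(mask[cellpix], truth_s$cell_id)], p]
      lam[cellpix] <- base * mult *
        ifelse(is_nuc[cellpix], nf / fr_nuc, (1 - nf) / (1 - fr_nuc))
      arr[, , p + 2L] <- draw(lam)
    }
    samples[[s]] <- list(stack = pixel_stack(arr, sid),
                         mask = segmentation_mask(mask, sid),
                         channels = chan)
    truth[[s]] <- truth_s
    prev1[s] <- mean(truth_s$type == 1L)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  sids <- sprintf("sample_%02d", seq_len(spec$n_samples))
  pgrade <- stats::plogis(spec$clinical_effect * (prev1 - mean(prev1)))
  clinical <- data.frame(
    sample_id = sids,
    grade = ifelse(stats::rbinom(spec$n_samples, 1, pgrade) == 1, "high", "low"),
    stage = sample(c("I", "II", "III"), spec$n_samples, replace = TRUE))
  x <- if (length(prev1) > 1 && stats::sd(prev1) > 0)
         (prev1 - mean(prev1)) / stats::sd(prev1)
       else prev1 * 0
  surv <- generate_survival(x, log_hr = spec$survival_effect,
                            seed = spec$seed + 1L)
  clinical <- cbind(clinical, surv[, c("survival_time", "event_indicator")])
  list(samples = samples, clinical = clinical, truth = truth, spec = spec)
}

#' Generate survival outcomes with a planted covariate effect
#'
#' Exponential event times with hazard proportional to
#' `exp(log_hr * x)` for the supplied covariate vector (used exactly as
#' given — standardize it first if the planted effect is meant per
#' standard deviation), with independent exponential censoring tuned to
#' an approximate censoring rate.
#'
#' @param x covariate vector, one value per sample
#' @param log_hr planted log hazard ratio per unit of `x`
#' @param n_samples number of samples; defaults to `length(x)`
#' @param seed RNG seed
#' @param baseline_hazard baseline event rate (time units arbitrary)
#' @param censor_rate approximate fraction censored; `>= 1` censors
#'   everything (no events)
#' @return data.frame (sample_id, x, survival_time, event_indicator)
#' @export
generate_survival <- function(x, log_hr, n_samples = length(x), seed = 0L,
                              baseline_hazard = 0.1, censor_rate = 0.15) {
  stopifnot(length(x) == n_samples)
  set.seed(seed)
  rate <- baseline_hazard * exp(log_hr * x)
  t_event <- stats::rexp(n_samples, rate)
  if (censor_rate >= 1) {
    time <- t_event * stats::runif(n_samples, 0.2, 0.8)
    event <- rep(0L, n_samples)
  } else if (censor_rate <= 0) {
    time <- t_event
    event <- rep(1L, n_samples)
  } else {
    c_rate <- baseline_hazard * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(n_samples, c_rate)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  data.frame(sample_id = sprintf("sample_%02d", seq_len(n_samples)),
             x = x, survival_time = time, event_indicator = event)
}

#' Ground-truth phenotype prevalence per sample
#' @param truth the `truth` table from [generate_synthetic()]
#' @return data.frame (sample_id, type, proportion)
#' @export
truth_prevalence <- function(truth) {
  tab <- table(truth$sample_id, truth$type)
  props <- tab / rowSums(tab)
  out <- as.data.frame(props, stringsAsFactors = FALSE)
  names(out) <- c("sample_id", "type", "proportion")
  out$type <- as.integer(out$type)
  out[order(out$sample_id, out$type), ]
}

#' Write a synthetic dataset to the on-disk ingest layout
#'
#' Emits exactly the file formats [load_sample()] reads, plus the
#' clinical table and ground truth.
#'
#' @param gen output of [generate_synthetic()]
#' @param dir output directory; one subdirectory per sample
#' @return `dir`, invisibly
#' @export
write_synthetic <- function(gen, dir) {
  for (s in gen$samples)
    write_sample(s$stack, s$mask, s$channels, file.path(dir, s$stack$sample_id))
  write_table(gen$clinical, file.path(dir, "clinical.csv"))
  write_table(gen$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
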