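# Ingestion of image-space inputs and on-disk table/bundle formats.
#
# Stacks and masks are exchanged as a directory-of-arrays layout: one
# headerless CSV matrix per channel (channel_###.csv, ordered by
# channel_index) plus a mask CSV and an external channel table. Arrays
# are indexed (row, column) = (y, x); centroids are reported in pixel
# units, 0-based.

#' Construct a pixel stack
#'
#' A pixel stack holds the raw pixel-level protein counts for one
#' acquisition: a 3-D non-negative array indexed (y, x, channel).
#'
#' @param pixels numeric 3-D array, dimensions (y, x, channel), all
#'   values non-negative
#' @param sample_id character scalar identifying the acquisition
#' @return an object of class `hv_stack`
#' @export
pixel_stack <- function(pixels, sample_id) {
  if (length(dim(pixels)) != 3L)
    hv_stop("pixel stack must be a 3-D array, got %d dims", length(dim(pixels)))
  if (any(pixels < 0))
    hv_stop("pixel stack for sample '%s' contains negative values", sample_id)
  structure(list(pixels = pixels, sample_id = as.character(sample_id)),
            class = "hv_stack")
}

#' Construct a segmentation mask
#'
#' @param labels integer matrix (y, x); 0 denotes background, positive
#'   integers are cell IDs (need not be sequential)
#' @param sample_id character scalar
#' @return an object of class `hv_mask`
#' @export
segmentation_mask <- function(labels, sample_id) {
  labels <- as.matrix(labels)
  if (any(labels < 0)) hv_stop("mask for sample '%s' has negative labels", sample_id)
  if (any(labels != round(labels))) hv_stop("mask labels must be integers")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, sample_id = as.character(sample_id)),
            class = "hv_mask")
}

#' Construct and validate a channel map
#'
#' Associates each z-slice of a pixel stack with a protein and flags the
#' two DNA-intercalator channels and any background channels.
#'
#' @param df data.frame with columns `channel_index` (0-based integers
#'   covering the stack depth bijectively), `protein_name` (unique),
#'   `is_dna_intercalator` and `is_background` (logical)
#' @return validated data.frame of class `hv_channels`
#' @export
channel_map <- function(df) {
  df <- as.data.frame(df)
  need <- c("channel_index", "protein_name", "is_dna_intercalator", "is_background")
  miss <- setdiff(need, names(df))
  if (length(miss)) hv_stop("channel table missing columns: %s", paste(miss, collapse = ", "))
  df$channel_index <- as.integer(df$channel_index)
  df$protein_name <- as.character(df$protein_name)
  df$is_dna_intercalator <- as.logical(df$is_dna_intercalator)
  df$is_background <- as.logical(df$is_background)
  if (anyDuplicated(df$protein_name)) hv_stop("protein names must be unique")
  if (!setequal(df$channel_index, seq_len(nrow(df)) - 1L))
    hv_stop("channel_index must cover 0..%d bijectively", nrow(df) - 1L)
  if (sum(df$is_dna_intercalator) != 2L)
    hv_stop("expected exactly 2 DNA-intercalator channels, found %d",
            sum(df$is_dna_intercalator))
  df <- df[order(df$channel_index), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hv_channels", "data.frame")
  df
}

#' Load one sample (stack + mask + channel table) from disk
#'
#' @param stack_path directory containing one headerless CSV matrix per
#'   channel, named `channel_<index>.csv` with 0-based indices
#' @param mask_path headerless CSV integer matrix, same (y, x) shape
#' @param channel_table_path CSV with the [channel_map()] columns
#' @param sample_id sample identifier; defaults to the stack directory name
#' @return list with elements `stack`, `mask`, `channels`
#' @export
load_sample <- function(stack_path, mask_path, channel_table_path,
                        sample_id = basename(normalizePath(stack_path))) {
  for (p in c(stack_path, mask_path, channel_table_path))
    if (!file.exists(p)) hv_stop("input path does not exist: %s", p)
  chmap <- channel_map(utils::read.csv(channel_table_path))
  files <- file.path(stack_path, sprintf("channel_%03d.csv", chmap$channel_index))
  missing <- files[!file.exists(files)]
  if (length(missing))
    hv_stop("stack directory %s lacks channel files: %s", stack_path,
            paste(basename(missing), collapse = ", "))
  planes <- lapply(files, function(f) {
    m <- as.matrix(data.table::fread(f, header = FALSE))
    dimnames(m) <- NULL
    m
  })
  d <- dim(planes[[1]])
  if (!all(vapply(planes, function(p) identical(dim(p), d), logical(1))))
    hv_stop("channel planes in %s have inconsistent shapes", stack_path)
  mask <- as.matrix(data.table::fread(mask_path, header = FALSE))
  dimnames(mask) <- NULL
  if (!identical(dim(mask), d))
    hv_stop("stack shape (%s) does not match mask shape (%s)",
            paste(d, collapse = "x"), paste(dim(mask), collapse = "x"))
  arr <- array(0, dim = c(d, nrow(chmap)))
  for (k in seq_along(planes)) arr[, , k] <- planes[[k]]
  list(stack = pixel_stack(arr, sample_id),
       mask = segmentation_mask(mask, sample_id),
       channels = chmap)
}

#' Write one sample to the directory-of-arrays layout
#'
#' Inverse of [load_sample()]; integer data round-trips bit-identically.
#'
#' @param stack an `hv_stack`
#' @param mask an `hv_mask`
#' @param channels an `hv_channels` table
#' @param dir output directory (created); channel planes are written to
#'   `dir/stack/`, the mask to `dir/mask.csv`, the table to `dir/channels.csv`
#' @return `dir`, invisibly
#' @export
write_sample <- function(stack, mask, channels, dir) {
  stopifnot(inherits(stack, "hv_stack"), inherits(mask, "hv_mask"))
  dir.create(file.path(dir, "stack"), recursive = TRUE, showWarnings = FALSE)
  for (k in seq_len(dim(stack$pixels)[3])) {
    data.table::fwrite(data.table::as.data.table(stack$pixels[, , k]),
                       file.path(dir, "stack", sprintf("channel_%03d.csv", channels$channel_index[k])),
                       col.names = FALSE)
  }
  data.table::fwrite(data.table::as.data.table(mask$labels),
                     file.path(dir, "mask.csv"), col.names = FALSE)
  write_table(as.data.frame(channels), file.path(dir, "channels.csv"))
  invisible(dir)
}

# fwrite with doubles rendered as shortest-round-trip decimal (%.17g),
# so reads reproduce values bit-for-bit.
fwrite_lossless <- function(dt, path, col.names = TRUE) {
  dt <- data.table::as.data.table(dt)
  for (j in names(dt)) {
    col <- dt[[j]]
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      fin <- which(is.finite(col))
      short <- sprintf("%.15g", col[fin])
      keep <- as.numeric(short) == col[fin]
      out[fin[keep]] <- short[keep]
      out[is.na(col)] <- NA
      data.table::set(dt, j = j, value = out)
    }
  }
  data.table::fwrite(dt, path, col.names = col.names)
}

#' Write a tabular result as CSV
#'
#' Column order is preserved; numeric values are written losslessly so a
#' write-then-read round-trip reproduces them to full float precision.
#'
#' @param table non-empty data.frame
#' @param path output file
#' @export
write_table <- function(table, path) {
  table <- as.data.frame(table)
  if (nrow(table) == 0L || ncol(table) == 0L)
    hv_stop("refusing to write an empty table to %s", path)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dirname(path))) hv_stop("cannot create directory for %s", path)
  fwrite_lossless(table, path)
  invisible(path)
}

#' Read a CSV table written by [write_table()]
#' @param path CSV file
#' @return data.frame
#' @export
read_table <- function(path) {
  if (!file.exists(path)) hv_stop("no such table: %s", path)
  as.data.frame(data.table::fread(path))
}

#' Load a clinical table
#'
#' Validates sample uniqueness and, when survival columns are present,
#' that event indicators are 0/1 and event times positive.
#'
#' @param path CSV with a `sample_id` column, optional categorical
#'   clinical variables, and optional `survival_time` / `event_indicator`
#' @return data.frame
#' @export
load_clinical <- function(path) {
  cl <- read_table(path)
  if (!"sample_id" %in% names(cl)) hv_stop("clinical table lacks sample_id")
  cl$sample_id <- as.character(cl$sample_id)
  if (anyDuplicated(cl$sample_id)) hv_stop("duplicate sample_ids in clinical table")
  if ("event_indicator" %in% names(cl) &&
      !all(cl$event_indicator %in% c(0, 1, NA)))
    hv_stop("event_indicator must be 0/1")
  if (all(c("survival_time", "event_indicator") %in% names(cl))) {
    bad <- !is.na(cl$survival_time) & cl$survival_time <= 0
    if (any(bad)) hv_stop("non-positive survival_time for %d sample(s)", sum(bad))
  }
  cl
}

#' Save a cell-views bundle to disk
#'
#' The bundle is a directory of plain-text CSVs plus a JSON manifest and
#' is the hand-off format between pipeline stages.
#'
#' @param cv an `hv_cellviews` object from [derive_cell_views()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
save_cellviews <- function(cv, dir) {
  stopifnot(inherits(cv, "hv_cellviews"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mats <- list(Y = cv$Y, S = cv$S, M = cv$M, C = cv$C, b = cv$b,
               centroids = cv$centroids)
  for (nm in names(mats)) {
    dt <- data.table::as.data.table(mats[[nm]])
    data.table::setnames(dt, colnames(mats[[nm]]) %||% paste0("V", seq_len(ncol(dt))))
    fwrite_lossless(dt, file.path(dir, paste0(nm, ".csv")))
  }
  write_table(data.frame(cell_id = cv$cell_ids, sample_id = cv$sample_ids),
              file.path(dir, "cells.csv"))
  jsonlite::write_json(
    list(proteins = cv$proteins, covariate_names = colnames(cv$b),
         sample_levels = cv$sample_levels, k_spatial = cv$k_spatial,
         image_dims = cv$image_dims),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a cell-views bundle written by [save_cellviews()]
#' @param dir bundle directory
#' @return an `hv_cellviews` object
#' @export
load_cellviews <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  rd <- function(nm) {
    m <- as.matrix(data.table::fread(file.path(dir, paste0(nm, ".csv"))))
    rownames(m) <- NULL
    m
  }
  cells <- read_table(file.path(dir, "cells.csv"))
  structure(list(
    Y = rd("Y"), S = rd("S"), M = rd("M"), C = rd("C"), b = rd("b"),
    centroids = rd("centroids"),
    cell_ids = cells$cell_id, sample_ids = as.character(cells$sample_id),
    proteins = meta$proteins, sample_levels = meta$sample_levels,
    k_spatial = meta$k_spatial,
    image_dims = meta$image_dims), class = "hv_cellviews")
}
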