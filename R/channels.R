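#' Channel metadata table
#'
#' Builds and validates the table describing the channels of a multiplexed
#' image: the marker name, the metal or fluorophore tag, the channel index
#' and the role the channel plays downstream.
#'
#' @param channel_name character vector of marker names (e.g. `"CD3"`);
#'   must be unique.
#' @param label character vector of tags (e.g. `"Er170"`), recycled if
#'   length 1.
#' @param index integer vector of 0-based channel indices; must be unique
#'   and contiguous from 0. Defaults to `0:(n-1)` in input order.
#' @param role one of `"nucleus"`, `"membrane"`, `"marker"`, `"ignore"`
#'   per channel; defaults to `"marker"`.
#'
#' @return A `data.frame` of class `channel_metadata` with columns
#'   `channel_name`, `label`, `index`, `role`, ordered by `index`.
#' @export
channel_metadata <- function(channel_name, label = channel_name,
                             index = seq_along(channel_name) - 1L,
                             role = "marker") {
  channel_name <- as.character(channel_name)
  n <- length(channel_name)
  if (n < 1L) stop("channel table must have at least one channel")
  label <- rep_len(as.character(label), n)
  role <- rep_len(as.character(role), n)
  index <- as.integer(index)
  ok_roles <- c("nucleus", "membrane", "marker", "ignore")
  if (!all(role %in% ok_roles)) {
    stop("invalid channel role(s): ",
         paste(setdiff(role, ok_roles), collapse = ", "))
  }
  if (anyDuplicated(channel_name)) {
    stop("duplicate channel_name: ",
         paste(unique(channel_name[duplicated(channel_name)]), collapse = ", "))
  }
  if (!setequal(index, 0:(n - 1L))) {
    stop("channel indices must be unique and contiguous from 0")
  }
  out <- data.frame(channel_name = channel_name, label = label,
                    index = index, role = role, stringsAsFactors = FALSE)
  out <- out[order(out$index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("channel_metadata", "data.frame")
  out
}

#' Read / write channel metadata CSV
#'
#' The on-disk format is a CSV with header
#' `channel_name,label,index,role`.
#'
#' @param path file path.
#' @return `read_channel_metadata` returns a [channel_metadata] table;
#'   `write_channel_metadata` returns `path` invisibly.
#' @export
read_channel_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel_name", "label", "index", "role")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("channel metadata CSV missing column(s): ",
         paste(miss, collapse = ", "))
  }
  channel_metadata(df$channel_name, df$label, df$index, df$role)
}

#' @rdname read_channel_metadata
#' @param channels a [channel_metadata] table.
#' @export
write_channel_metadata <- function(channels, path) {
  utils::write.csv(as.data.frame(channels)[, c("channel_name", "label",
                                               "index", "role")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Multi-channel image stack
#'
#' The central image container: an `H x W x C` array of non-negative finite
#' intensities together with its channel metadata, the physical pixel size
#' and a sample identifier. Pixel coordinates are 0-based with the origin
#' at the top-left corner, `x` increasing along columns and `y` along rows;
#' all distances are measured between pixel centres.
#'
#' @param pixels numeric `H x W` matrix (single channel) or `H x W x C`
#'   array. All values must be finite and `>= 0`.
#' @param channels a [channel_metadata] table of length `C`.
#' @param pixel_size_um physical size of a pixel side in micrometres.
#' @param sample_id sample identifier string.
#' @param normalised logical; `TRUE` after percentile normalisation, in
#'   which case all values must be `<= 1`.
#'
#' @return An object of class `channel_stack`: a list with elements
#'   `pixels`, `channels`, `pixel_size_um`, `sample_id`, `normalised`.
#' @export
channel_stack <- function(pixels, channels, pixel_size_um = 1,
                          sample_id = "sample", normalised = FALSE) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  if (length(dim(pixels)) != 3L) {
    stop("pixels must be an H x W matrix or H x W x C array")
  }
  if (!inherits(channels, "channel_metadata")) {
    channels <- channel_metadata(channels)
  }
  if (dim(pixels)[3] != nrow(channels)) {
    stop("channel table length (", nrow(channels),
         ") does not match channel count (", dim(pixels)[3], ")")
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("pixel values must be finite")
  }
  if (any(pixels < 0)) stop("pixel values must be non-negative")
  if (normalised && any(pixels > 1)) {
    stop("normalised stack contains values > 1")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0) {
    stop("pixel_size_um must be a positive scalar")
  }
  dimnames(pixels) <- list(NULL, NULL, channels$channel_name)
  structure(list(pixels = pixels, channels = channels,
                 pixel_size_um = as.numeric(pixel_size_um),
                 sample_id = as.character(sample_id),
                 normalised = isTRUE(normalised)),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("channel_stack '%s': %d x %d px, %d channel(s), %.3g um/px%s\n",
              x$sample_id, d[1], d[2], d[3], x$pixel_size_um,
              if (x$normalised) ", normalised" else ""))
  cat("  channels:", paste(x$channels$channel_name, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$pixels)

#' Extract one channel as a matrix
#'
#' @param stack a [channel_stack].
#' @param channel channel name.
#' @return `H x W` numeric matrix.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!channel %in% stack$channels$channel_name) {
    stop("unknown channel: ", channel)
  }
  stack$pixels[, , channel]
}

#' Binary mask
#'
#' A named logical image, together with a free-text provenance string
#' recording the recipe or expression that produced it.
#'
#' @param pixels logical `H x W` matrix.
#' @param name mask name, unique within a run.
#' @param provenance description of how the mask was derived.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, name, provenance = "") {
  if (!is.matrix(pixels)) stop("mask pixels must be a matrix")
  storage.mode(pixels) <- "logical"
  if (anyNA(pixels)) stop("mask contains NA")
  structure(list(pixels = pixels, name = as.character(name),
                 provenance = as.character(provenance)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask '%s': %d x %d px, %d positive (%.1f%%)\n",
              x$name, nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels)))
  invisible(x)
}

#' Label image
#'
#' Per-cell pixel labels: 0 is background, label `k` marks the pixels of
#' cell `k`. Labels are exactly `1..n_cells` and each label's pixel set is
#' non-empty.
#'
#' @param pixels integer `H x W` matrix of labels.
#' @return An object of class `label_image` with elements `pixels` and
#'   `n_cells`.
#' @export
label_image <- function(pixels) {
  if (!is.matrix(pixels)) stop("label pixels must be a matrix")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || any(pixels < 0L)) {
    stop("labels must be non-negative integers")
  }
  n <- max(pixels, 0L)
  present <- sort(unique(pixels[pixels > 0L]))
  if (n > 0L && !identical(present, seq_len(n))) {
    stop("labels must be exactly 1..n_cells with no gaps")
  }
  structure(list(pixels = pixels, n_cells = as.integer(n)),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("label_image: %d x %d px, %d cell(s)\n",
              nrow(x$pixels), ncol(x$pixels), x$n_cells))
  invisible(x)
}
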