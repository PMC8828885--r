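#' Reconstruct an image stack from an IMC ablation text file
#'
#' Imaging-mass-cytometry acquisitions are exported as tab-delimited text
#' with one row per ablated pixel: integer `X` and `Y` coordinates plus one
#' intensity column per channel (headers typically look like
#' `"CD3(Er170Di)"`). This rebuilds the rectangular image of width
#' `max(X) + 1` and height `max(Y) + 1`; pixels absent from the file
#' (truncated ablations) are filled with 0 and counted in a warning.
#'
#' Channels are matched to the header by substring: a header token matches a
#' channel if it contains the channel's `channel_name` or `label`. Each
#' channel must match exactly one header column.
#'
#' @param path path to the tab-delimited ablation file.
#' @param channel_table a [channel_metadata] table; output channel order
#'   follows this table.
#' @param pixel_size_um pixel size in micrometres (IMC is typically
#'   1 um/px).
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @return A [channel_stack].
#' @export
parse_imc_text <- function(path, channel_table, pixel_size_um = 1,
                           sample_id = NULL) {
  if (!inherits(channel_table, "channel_metadata")) {
    channel_table <- channel_metadata(channel_table)
  }
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(path))
  }
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  hdr <- names(df)
  for (coord in c("X", "Y")) {
    if (!coord %in% hdr) {
      stop("format error: ablation file has no '", coord, "' column")
    }
  }
  x <- as.integer(df$X)
  y <- as.integer(df$Y)
  if (anyNA(x) || anyNA(y) || any(x < 0) || any(y < 0)) {
    stop("format error: X and Y must be non-negative integers")
  }
  key <- y * (max(x) + 1L) + x
  if (anyDuplicated(key)) {
    k <- key[duplicated(key)][1L]
    stop(sprintf("format error: duplicate pixel at (X=%d, Y=%d)",
                 k %% (max(x) + 1L), k %/% (max(x) + 1L)))
  }
  data_cols <- setdiff(hdr, c("X", "Y"))
  col_for <- vapply(seq_len(nrow(channel_table)), function(i) {
    nm <- channel_table$channel_name[i]
    lb <- channel_table$label[i]
    hits <- data_cols[grepl(nm, data_cols, fixed = TRUE) |
                      grepl(lb, data_cols, fixed = TRUE)]
    if (length(hits) == 0L) {
      stop("metadata mismatch: channel '", nm,
           "' not found in ablation file header")
    }
    if (length(hits) > 1L) {
      stop("metadata mismatch: channel '", nm, "' matches several columns: ",
           paste(hits, collapse = ", "))
    }
    hits
  }, character(1))

  H <- max(y) + 1L
  W <- max(x) + 1L
  n_missing <- H * W - length(x)
  if (n_missing > 0L) {
    warning(sprintf("%d of %d pixels absent from '%s'; filled with 0",
                    n_missing, H * W, basename(path)))
  }
  px <- array(0, dim = c(H, W, nrow(channel_table)))
  idx <- cbind(y + 1L, x + 1L)
  for (c_i in seq_len(nrow(channel_table))) {
    plane <- matrix(0, H, W)
    plane[idx] <- as.numeric(df[[col_for[c_i]]])
    px[, , c_i] <- plane
  }
  channel_stack(px, channel_table, pixel_size_um = pixel_size_um,
                sample_id = sample_id)
}

# Minimal uncompressed single-strip 32-bit IEEE-float grayscale TIFF writer.
# tiff::writeTIFF rescales to integer sample formats and cannot represent
# intensities outside [0,1]; raw multiplexed intensities routinely exceed 1,
# and the package contract is a bit-exact round trip, so the few TIFF tags
# needed are emitted directly. tiff::readTIFF reads the result natively.
write_float_tiff <- function(m, path) {
  h <- nrow(m)
  w <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")      # IFD offset
  n_tags <- 9L
  data_offset <- 8L + 2L + n_tags * 12L + 4L
  writeBin(n_tags, con, size = 2, endian = "little")
  tag <- function(id, type, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (type == 3L) {                                  # SHORT padded to 4 bytes
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  tag(256L, 4L, w)              # ImageWidth
  tag(257L, 4L, h)              # ImageLength
  tag(258L, 3L, 32L)            # BitsPerSample
  tag(259L, 3L, 1L)             # Compression: none
  tag(262L, 3L, 1L)             # Photometric: BlackIsZero
  tag(273L, 4L, data_offset)    # StripOffsets
  tag(278L, 4L, h)              # RowsPerStrip
  tag(279L, 4L, h * w * 4L)     # StripByteCounts
  tag(339L, 3L, 3L)             # SampleFormat: IEEE float
  writeBin(0L, con, size = 4, endian = "little")      # no next IFD
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  invisible(path)
}

# Read one TIFF page as a numeric matrix, preserving stored values:
# integer sample formats are returned as their raw integer values (no
# rescaling to [0,1]); float formats as stored.
read_tiff_plane <- function(path) {
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) tiff::readTIFF(path))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L) {
      stop("shape error: expected a single-channel TIFF: ", path)
    }
    img <- img[, , 1L]
  }
  storage.mode(img) <- "double"
  img
}

#' Read a channel stack from TIFF files
#'
#' Accepts either one single-channel TIFF per channel (in channel-table
#' order) or one multi-page TIFF whose page count equals the table length.
#' Integer storage types are promoted to real intensities without
#' rescaling: a 16-bit pixel stored as 65535 is read as 65535.
#'
#' @param image_paths character vector of TIFF paths (length 1 for a
#'   multi-page file, otherwise one per channel).
#' @param channel_table a [channel_metadata] table.
#' @param pixel_size_um pixel size in micrometres.
#' @param sample_id sample identifier; defaults to the common prefix of the
#'   file names, or the first file name.
#' @param normalised logical flag recorded on the returned stack.
#' @return A [channel_stack].
#' @export
read_stack <- function(image_paths, channel_table, pixel_size_um = 1,
                       sample_id = NULL, normalised = FALSE) {
  if (!inherits(channel_table, "channel_metadata")) {
    channel_table <- channel_metadata(channel_table)
  }
  n_ch <- nrow(channel_table)
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(image_paths[1L]))
  }
  planes <- if (length(image_paths) == 1L && n_ch > 1L) {
    pages <- tiff::readTIFF(image_paths, all = TRUE, as.is = TRUE)
    if (length(pages) != n_ch) {
      stop("metadata mismatch: ", length(pages), " TIFF page(s) for ",
           n_ch, " channel(s)")
    }
    lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1L]
      storage.mode(p) <- "double"
      p
    })
  } else {
    if (length(image_paths) != n_ch) {
      stop("metadata mismatch: ", length(image_paths),
           " image file(s) for ", n_ch, " channel(s)")
    }
    lapply(image_paths, read_tiff_plane)
  }
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("shape error: channel images have differing dimensions")
  }
  px <- array(0, dim = c(dims[1, 1], dims[2, 1], n_ch))
  for (i in seq_len(n_ch)) px[, , i] <- planes[[i]]
  channel_stack(px, channel_table, pixel_size_um = pixel_size_um,
                sample_id = sample_id, normalised = normalised)
}

#' Write a channel stack as single-channel TIFFs plus a metadata CSV
#'
#' Each channel is written as a one-page 32-bit-float TIFF named
#' `<sample_id>_<channel_name>.tiff`; channel names that produce an empty
#' or unsafe file name are sanitised with a warning. A channel-metadata CSV
#' (`<sample_id>_channels.csv`) is written alongside.
#'
#' @param stack a [channel_stack].
#' @param out_dir output directory (created if needed).
#' @param overwrite allow clobbering existing files.
#' @return Invisibly, the vector of written file paths (TIFFs then CSV).
#' @export
write_channels <- function(stack, out_dir, overwrite = FALSE) {
  stopifnot(inherits(stack, "channel_stack"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nms <- stack$channels$channel_name
  safe <- gsub("[^A-Za-z0-9_.-]", "_", nms)
  empty <- !nzchar(safe)
  if (any(empty) || any(safe != nms)) {
    safe[empty] <- paste0("channel", which(empty) - 1L)
    warning("channel name(s) sanitised for file naming: ",
            paste(nms[safe != nms | empty], collapse = ", "))
  }
  paths <- file.path(out_dir, paste0(stack$sample_id, "_", safe, ".tiff"))
  csv_path <- file.path(out_dir, paste0(stack$sample_id, "_channels.csv"))
  existing <- c(paths, csv_path)[file.exists(c(paths, csv_path))]
  if (length(existing) && !overwrite) {
    stop("output file(s) already exist (use overwrite = TRUE): ",
         paste(basename(existing), collapse = ", "))
  }
  for (i in seq_along(paths)) {
    write_float_tiff(stack$pixels[, , i], paths[i])
  }
  write_channel_metadata(stack$channels, csv_path)
  invisible(c(paths, csv_path))
}

#' Write / read a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask a [binary_mask].
#' @param path output path.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns a
#'   [binary_mask] (positive where the stored value exceeds half range).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  tiff::writeTIFF(mask$pixels * 1.0, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @param name mask name for the returned object; defaults to the file
#'   name without extension.
#' @export
read_mask <- function(path, name = NULL) {
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  m <- read_tiff_plane(path)
  binary_mask(m > max(m, 1) / 2, name, provenance = paste0("file:", path))
}

#' Write / read a label image as a 32-bit float TIFF
#'
#' Labels are stored as 32-bit floats (exact for label counts below 2^24).
#'
#' @param labels a [label_image].
#' @param path file path.
#' @return `write_labels` returns `path` invisibly; `read_labels` a
#'   [label_image].
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_image"))
  write_float_tiff(labels$pixels, path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  m <- read_tiff_plane(path)
  label_image(matrix(as.integer(round(m)), nrow(m), ncol(m)))
}
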