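#' Segmentation parameters
#'
#' @param nucleus_channel name of the nuclear channel (DNA intercalator,
#'   DAPI, HOECHST, ...).
#' @param nucleus_threshold `"otsu"` or a fixed numeric threshold applied
#'   to the nucleus channel.
#' @param min_diameter_px,max_diameter_px size filter on the equivalent
#'   diameter `2 * sqrt(area / pi)` of candidate nuclei (inclusive bounds).
#' @param expansion how nuclei grow into whole cells: `"radial"`
#'   (nearest-nucleus growth up to `expansion_px`, restricted to a
#'   membrane mask), `"watershed"` (flooding of the distance-to-nearest-
#'   nucleus surface seeded by the nuclei, restricted to nucleus-or-
#'   membrane pixels) or `"isotropic"` (nearest-nucleus growth by
#'   `expansion_px` with no mask constraint).
#' @param expansion_px growth distance in pixels for the radial and
#'   isotropic modes.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(nucleus_channel,
                                nucleus_threshold = "otsu",
                                min_diameter_px = 4,
                                max_diameter_px = 60,
                                expansion = c("radial", "watershed",
                                              "isotropic"),
                                expansion_px = 10) {
  expansion <- match.arg(expansion)
  if (!(identical(nucleus_threshold, "otsu") ||
        (is.numeric(nucleus_threshold) && length(nucleus_threshold) == 1L))) {
    stop("nucleus_threshold must be \"otsu\" or a single number")
  }
  if (min_diameter_px >= max_diameter_px) {
    stop("min_diameter_px must be < max_diameter_px")
  }
  if (expansion %in% c("radial", "isotropic") && expansion_px <= 0) {
    stop("expansion_px must be positive")
  }
  structure(list(nucleus_channel = nucleus_channel,
                 nucleus_threshold = nucleus_threshold,
                 min_diameter_px = min_diameter_px,
                 max_diameter_px = max_diameter_px,
                 expansion = expansion,
                 expansion_px = expansion_px),
            class = "segmentation_params")
}

#' Detect nuclei
#'
#' Thresholds the nucleus channel (Otsu or fixed), labels 4-connected
#' components, and keeps those whose equivalent diameter
#' `2 * sqrt(area / pi)` lies within the configured bounds (inclusive).
#' Survivors are relabelled `1..N` in raster order of their
#' topmost-leftmost pixel. Touching nuclei are not split.
#'
#' @param stack a [channel_stack].
#' @param params a [segmentation_params].
#' @return A [label_image] of nuclei; empty (with a warning) if no
#'   component passes the size filter.
#' @export
detect_nuclei <- function(stack, params) {
  stopifnot(inherits(params, "segmentation_params"))
  ch <- get_channel(stack, params$nucleus_channel)
  mask <- if (identical(params$nucleus_threshold, "otsu")) {
    threshold_otsu(ch)$mask$pixels
  } else {
    ch > params$nucleus_threshold
  }
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) {
    warning("no nuclei detected in sample '", stack$sample_id, "'")
    return(label_image(lab))
  }
  areas <- tabulate(lab[lab > 0L], nbins = n)
  diam <- 2 * sqrt(areas / pi)
  keep <- which(diam >= params$min_diameter_px &
                diam <= params$max_diameter_px)
  if (length(keep) == 0L) {
    warning("no nuclei within the size bounds in sample '",
            stack$sample_id, "'")
    return(label_image(matrix(0L, nrow(lab), ncol(lab))))
  }
  out <- matrix(0L, nrow(lab), ncol(lab))
  sel <- lab %in% keep
  out[sel] <- match(lab[sel], keep)   # keep is sorted: raster order survives
  label_image(out)
}

# Nearest-seed expansion: for every pixel within `max_px` of a nucleus,
# the squared Euclidean distance (pixel centres, exact integer arithmetic)
# to the nearest pixel of each nucleus is compared; the pixel joins the
# closest nucleus, exact ties going to the lower label because labels are
# scanned in increasing order and only strict improvements overwrite.
nearest_seed_assignment <- function(lab, max_px) {
  H <- nrow(lab); W <- ncol(lab)
  n <- max(lab)
  reach <- as.integer(ceiling(max_px))
  best_d2 <- matrix(Inf, H, W)
  best_lab <- matrix(0L, H, W)
  best_d2[lab > 0L] <- 0
  best_lab[lab > 0L] <- lab[lab > 0L]
  for (k in seq_len(n)) {
    sel <- which(lab == k, arr.ind = TRUE)
    r0 <- max(1L, min(sel[, 1]) - reach); r1 <- min(H, max(sel[, 1]) + reach)
    c0 <- max(1L, min(sel[, 2]) - reach); c1 <- min(W, max(sel[, 2]) + reach)
    rb <- r0:r1; cb <- c0:c1
    dr2 <- outer(rb, sel[, 1], function(a, b) (a - b)^2)
    dc2 <- outer(cb, sel[, 2], function(a, b) (a - b)^2)
    d2 <- matrix(Inf, length(rb), length(cb))
    for (p in seq_len(nrow(sel))) {
      d2 <- pmin(d2, outer(dr2[, p], dc2[, p], `+`))
    }
    blk_d2 <- best_d2[rb, cb, drop = FALSE]
    blk_lab <- best_lab[rb, cb, drop = FALSE]
    upd <- d2 < blk_d2
    blk_d2[upd] <- d2[upd]
    blk_lab[upd] <- k
    best_d2[rb, cb] <- blk_d2
    best_lab[rb, cb] <- blk_lab
  }
  best_lab[best_d2 > max_px^2] <- 0L
  list(labels = best_lab, d2 = best_d2)
}

# Seeded flooding of the distance-to-nearest-nucleus surface, restricted
# to `region`. Pixels are visited in increasing surface value; an
# unlabelled pixel takes the label of its already-labelled 4-neighbour
# with the smallest surface value (ties to the lower label). Deterministic.
watershed_expand <- function(lab, region) {
  H <- nrow(lab); W <- ncol(lab)
  f <- EBImage::distmap(matrix(as.numeric(lab == 0L), H, W))
  f <- matrix(as.numeric(f), H, W)
  out <- lab
  todo <- region & out == 0L
  if (!any(todo)) return(out)
  ord <- order(f[todo], (row(out)[todo] - 1L) * W + col(out)[todo])
  idx <- which(todo)[ord]
  rr <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  repeat {
    changed <- FALSE
    for (p in seq_along(idx)) {
      if (out[idx[p]] != 0L) next
      r <- rr[p]; ci <- cc[p]
      best_f <- Inf; best <- 0L
      for (d in 1:4) {
        nr <- r + c(-1L, 1L, 0L, 0L)[d]
        nc <- ci + c(0L, 0L, -1L, 1L)[d]
        if (nr < 1L || nr > H || nc < 1L || nc > W) next
        l <- out[nr, nc]
        if (l > 0L &&
            (f[nr, nc] < best_f || (f[nr, nc] == best_f && l < best))) {
          best_f <- f[nr, nc]; best <- l
        }
      }
      if (best > 0L) { out[idx[p]] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  out
}

#' Expand nuclei into whole cells
#'
#' Three strategies share the guarantees that every nucleus pixel keeps
#' its label, cells are pairwise disjoint, and contested pixels go to the
#' nearest nucleus with exact ties resolved towards the lower label:
#'
#' * `radial`: each cell is its nucleus plus the pixels within Euclidean
#'   distance `expansion_px` of that nucleus that are membrane-positive.
#' * `watershed`: flooding of the distance-to-nearest-nucleus surface
#'   seeded by the nuclei, restricted to nucleus-or-membrane pixels.
#' * `isotropic`: nearest-nucleus growth by `expansion_px` with no mask.
#'
#' @param nuclei a [label_image] of nuclei.
#' @param params a [segmentation_params].
#' @param membrane a [binary_mask] (or logical matrix); required for the
#'   radial and watershed modes.
#' @return A [label_image] of whole cells with the nucleus labelling
#'   preserved.
#' @export
expand_cells <- function(nuclei, params, membrane = NULL) {
  stopifnot(inherits(nuclei, "label_image"),
            inherits(params, "segmentation_params"))
  lab <- nuclei$pixels
  if (nuclei$n_cells == 0L) return(nuclei)
  mode <- params$expansion
  if (mode %in% c("radial", "watershed")) {
    if (is.null(membrane)) {
      stop("parameter error: '", mode, "' expansion requires a membrane mask")
    }
    mem <- mask_px(membrane)
    if (!identical(dim(mem), dim(lab))) {
      stop("membrane mask dimensions do not match the label image")
    }
  }
  out <- switch(mode,
    isotropic = nearest_seed_assignment(lab, params$expansion_px)$labels,
    radial = {
      res <- nearest_seed_assignment(lab, params$expansion_px)
      keep <- lab > 0L | (res$labels > 0L & mem)
      res$labels * keep
    },
    watershed = watershed_expand(lab, lab > 0L | mem))
  storage.mode(out) <- "integer"
  label_image(out)
}

#' Extract per-cell features
#'
#' Computes, for every cell of a label image: the pixel area, the centroid
#' (unweighted mean of pixel centres, 0-based coordinates, also reported
#' in micrometres) and the arithmetic mean intensity of every channel over
#' the cell's pixels.
#'
#' An externally produced label image (e.g. from a deep-learning
#' segmenter) can be supplied in place of the built-in detection and
#' expansion; only the label contract matters.
#'
#' @param cells a [label_image] (or integer matrix of labels `1..n` with
#'   no gaps).
#' @param stack the matching [channel_stack].
#' @return A `cell_table` data frame with columns `cell_id`, `sample_id`,
#'   `centroid_x_px`, `centroid_y_px`, `centroid_x_um`, `centroid_y_um`,
#'   `area_px`, one mean-intensity column per channel (named after the
#'   channel), and placeholder `compartment`, `cell_type`, `cluster_id`
#'   columns.
#' @export
extract_features <- function(cells, stack) {
  if (!inherits(cells, "label_image")) cells <- label_image(cells)
  stopifnot(inherits(stack, "channel_stack"))
  lab <- cells$pixels
  if (!identical(dim(lab), dim(stack$pixels)[1:2])) {
    stop("label image dimensions do not match the stack")
  }
  n <- cells$n_cells
  if (n == 0L) {
    return(empty_cell_table(stack$channels$channel_name))
  }
  fg <- lab > 0L
  l <- lab[fg]
  area <- tabulate(l, nbins = n)
  cx <- as.vector(rowsum(col(lab)[fg] - 1, l)) / area
  cy <- as.vector(rowsum(row(lab)[fg] - 1, l)) / area
  out <- data.frame(cell_id = seq_len(n),
                    sample_id = stack$sample_id,
                    centroid_x_px = cx, centroid_y_px = cy,
                    centroid_x_um = cx * stack$pixel_size_um,
                    centroid_y_um = cy * stack$pixel_size_um,
                    area_px = area,
                    stringsAsFactors = FALSE)
  for (ci in seq_len(nrow(stack$channels))) {
    ch <- stack$pixels[, , ci]
    out[[stack$channels$channel_name[ci]]] <-
      as.vector(rowsum(ch[fg], l)) / area
  }
  out$compartment <- NA_character_
  out$cell_type <- NA_character_
  out$cluster_id <- NA_integer_
  class(out) <- c("cell_table", "data.frame")
  out
}

empty_cell_table <- function(channel_names) {
  out <- data.frame(cell_id = integer(), sample_id = character(),
                    centroid_x_px = numeric(), centroid_y_px = numeric(),
                    centroid_x_um = numeric(), centroid_y_um = numeric(),
                    area_px = integer(), stringsAsFactors = FALSE)
  for (nm in channel_names) out[[nm]] <- numeric()
  out$compartment <- character()
  out$cell_type <- character()
  out$cluster_id <- integer()
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Write / read a cell table CSV
#'
#' @param cells a `cell_table` data frame.
#' @param path file path.
#' @return `write_cell_table` returns `path` invisibly; `read_cell_table`
#'   the table.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cell_table", "data.frame")
  out
}
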