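#' Synthetic tissue specification
#'
#' Describes a simulated multiplexed image with exact ground truth:
#' rectangular tissue compartments with per-channel background intensity,
#' and disk-shaped cells (with a concentric nuclear disk) whose marker
#' expression is drawn per cell from a zero-truncated Gaussian. Disk cells
#' keep every oracle analytic (a disk centred on a pixel centre has that
#' centre as its exact pixel centroid) while exercising every pipeline
#' contract.
#'
#' @param image_size `c(H, W)` in pixels.
#' @param pixel_size_um pixel size in micrometres.
#' @param channels a [channel_metadata] table; exactly one channel should
#'   have role `"nucleus"`.
#' @param compartments named list of regions, each a list with `x_range`
#'   and `y_range` (0-based pixel bounds, inclusive) and optionally
#'   `background`, a named per-channel intensity painted over the region.
#' @param cell_types list of cell-type descriptions: `name`, `count`,
#'   `radius_px`, `nucleus_radius_px` (`<= radius_px`), `expression`
#'   (named per-channel mean), `expression_sd` (scalar or named; default
#'   0), and optional `compartment` (cells are placed inside it).
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (clamped at zero to keep intensities non-negative); default 0.
#' @param seed RNG seed; a fixed seed makes the output fully
#'   reproducible.
#' @return A list of class `tissue_spec`.
#' @export
tissue_spec <- function(image_size, pixel_size_um = 1, channels,
                        compartments = list(), cell_types = list(),
                        noise_sd = 0, seed = 1L) {
  if (!inherits(channels, "channel_metadata")) {
    channels <- channel_metadata(channels)
  }
  for (ct in cell_types) {
    if (is.null(ct$name) || is.null(ct$count) || is.null(ct$radius_px)) {
      stop("each cell type needs name, count and radius_px")
    }
    if (ct$radius_px < 1) stop("cell radius must be >= 1 px")
    nr <- if (is.null(ct$nucleus_radius_px)) ct$radius_px else ct$nucleus_radius_px
    if (nr > ct$radius_px) stop("nucleus radius cannot exceed cell radius")
    if (ct$count < 0) stop("cell counts must be >= 0")
  }
  structure(list(image_size = as.integer(image_size),
                 pixel_size_um = pixel_size_um, channels = channels,
                 compartments = compartments, cell_types = cell_types,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "tissue_spec")
}

# pixels of a disk of radius r centred on integer pixel centre (cy, cx),
# as an index matrix into an H x W image (1-based rows/cols)
disk_pixels <- function(cy, cx, r, H, W) {
  d <- -floor(r):floor(r)
  sel <- which(outer(d^2, d^2, `+`) <= r^2, arr.ind = TRUE)
  rr <- cy + d[sel[, 1]] + 1L
  cc <- cx + d[sel[, 2]] + 1L
  keep <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
  cbind(rr[keep], cc[keep])
}

#' Generate a synthetic tissue image with ground truth
#'
#' Places non-overlapping disk cells (rejection sampling, at most 10^4
#' attempts per cell) inside their compartments, paints the nucleus
#' channel on the nuclear disks and each marker channel on whole cells
#' with per-cell expression drawn from a zero-truncated Gaussian, then
#' adds optional Gaussian pixel noise (clamped at zero). Cells of
#' different types never touch (centre distance exceeds the radius sum by
#' 2 px), so segmentation ground truth is exact.
#'
#' @param spec a [tissue_spec].
#' @return A list with `stack` (a [channel_stack]), `cells` (ground-truth
#'   `cell_table` with exact centroids, areas, types, compartments and
#'   the planted per-cell expression in the channel columns) and `masks`
#'   (named list of compartment [binary_mask]s).
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  set.seed(spec$seed)
  H <- spec$image_size[1L]; W <- spec$image_size[2L]
  chans <- spec$channels
  px <- array(0, dim = c(H, W, nrow(chans)))

  region_bounds <- function(name) {
    if (is.null(name)) {
      return(list(x = c(0L, W - 1L), y = c(0L, H - 1L)))
    }
    comp <- spec$compartments[[name]]
    if (is.null(comp)) stop("unknown compartment '", name, "'")
    list(x = c(max(0L, comp$x_range[1L]), min(W - 1L, comp$x_range[2L])),
         y = c(max(0L, comp$y_range[1L]), min(H - 1L, comp$y_range[2L])))
  }

  masks <- list()
  for (nm in names(spec$compartments)) {
    comp <- spec$compartments[[nm]]
    m <- matrix(FALSE, H, W)
    b <- region_bounds(nm)
    m[(b$y[1L]:b$y[2L]) + 1L, (b$x[1L]:b$x[2L]) + 1L] <- TRUE
    masks[[nm]] <- binary_mask(m, nm, provenance = "synthetic compartment")
    if (!is.null(comp$background)) {
      for (ch in names(comp$background)) {
        ci <- match(ch, chans$channel_name)
        if (is.na(ci)) stop("background channel '", ch, "' not in panel")
        plane <- px[, , ci]
        plane[m] <- plane[m] + comp$background[[ch]]
        px[, , ci] <- plane
      }
    }
  }

  placed <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0))
  truth <- list()
  cell_id <- 0L
  for (ct in spec$cell_types) {
    r <- ct$radius_px
    nr <- if (is.null(ct$nucleus_radius_px)) r else ct$nucleus_radius_px
    b <- region_bounds(ct$compartment)
    for (i in seq_len(ct$count)) {
      ok <- FALSE
      for (attempt in seq_len(10000L)) {
        cx <- sample(max(b$x[1L], ceiling(r)):min(b$x[2L], W - 1L - ceiling(r)), 1L)
        cy <- sample(max(b$y[1L], ceiling(r)):min(b$y[2L], H - 1L - ceiling(r)), 1L)
        if (nrow(placed) == 0L ||
            all((placed$cx - cx)^2 + (placed$cy - cy)^2 >
                (placed$r + r + 2)^2)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("generation error: could not place cell of type '",
             ct$name, "' after 10000 attempts")
      }
      placed <- rbind(placed, data.frame(cx = cx, cy = cy, r = r))
      cell_id <- cell_id + 1L
      cell_idx <- disk_pixels(cy, cx, r, H, W)
      nuc_idx <- disk_pixels(cy, cx, nr, H, W)
      expr_drawn <- stats::setNames(numeric(nrow(chans)),
                                    chans$channel_name)
      for (ci in seq_len(nrow(chans))) {
        ch <- chans$channel_name[ci]
        mu <- if (!is.null(ct$expression) && ch %in% names(ct$expression)) {
          ct$expression[[ch]]
        } else 0
        sdv <- 0
        if (!is.null(ct$expression_sd)) {
          sdv <- if (length(ct$expression_sd) == 1L &&
                     is.null(names(ct$expression_sd))) {
            ct$expression_sd
          } else if (ch %in% names(ct$expression_sd)) {
            ct$expression_sd[[ch]]
          } else 0
        }
        v <- max(0, stats::rnorm(1L, mu, sdv))
        expr_drawn[ch] <- v
        if (v > 0) {
          idx <- if (chans$role[ci] == "nucleus") nuc_idx else cell_idx
          plane <- px[, , ci]
          plane[idx] <- plane[idx] + v
          px[, , ci] <- plane
        }
      }
      comp_name <- if (is.null(ct$compartment)) NA_character_ else ct$compartment
      truth[[cell_id]] <- c(list(cell_id = cell_id,
                                 centroid_x_px = cx, centroid_y_px = cy,
                                 area_px = nrow(cell_idx),
                                 nucleus_area_px = nrow(nuc_idx),
                                 cell_type = ct$name,
                                 compartment = comp_name),
                            as.list(expr_drawn))
    }
  }

  if (spec$noise_sd > 0) {
    px <- pmax(px + stats::rnorm(length(px), 0, spec$noise_sd), 0)
  }
  stack <- channel_stack(px, chans, pixel_size_um = spec$pixel_size_um,
                         sample_id = paste0("synthetic_seed", spec$seed))
  cells <- if (length(truth)) {
    out <- do.call(rbind, lapply(truth, function(x) {
      as.data.frame(x, stringsAsFactors = FALSE)
    }))
    out$sample_id <- stack$sample_id
    out$centroid_x_um <- out$centroid_x_px * spec$pixel_size_um
    out$centroid_y_um <- out$centroid_y_px * spec$pixel_size_um
    class(out) <- c("cell_table", "data.frame")
    out
  } else {
    empty_cell_table(chans$channel_name)
  }
  list(stack = stack, cells = cells, masks = masks)
}

#' Generate grouped samples of cell positions with a planted distance shift
#'
#' Produces two groups of samples, each sample a set of cell centroids
#' with types `source`, `target` and `other`, for calibrating and
#' powering the heterotypic distance machinery:
#'
#' * `shift_um = 0`: all positions are i.i.d. uniform over the region and
#'   types are assigned to exchangeable positions, so cell identities are
#'   exchangeable within each sample — the permutation null holds
#'   exactly.
#' * `shift_um > 0`: the same draws, except that each source cell in
#'   group A is displaced towards its nearest target by `shift_um`
#'   (stopping 1 um short), planting a median nearest-distance reduction
#'   of about `shift_um` in group A. With the same seed, only source
#'   positions differ from the `shift_um = 0` output.
#'
#' @param n_per_group samples per group.
#' @param shift_um planted median-distance shift in micrometres (>= 0).
#' @param n_sources,n_targets,n_other cells of each type per sample.
#' @param region_um `c(width, height)` of the sampled region in
#'   micrometres.
#' @param source_type,target_type type labels used in the output.
#' @param seed RNG seed.
#' @return A list with `cells` (a `cell_table`-style data frame with
#'   `sample_id`, `cell_id`, `centroid_x_um`, `centroid_y_um`,
#'   `cell_type`) and `group_map` (named vector sample -> `"A"`/`"B"`).
#' @export
generate_grouped_samples <- function(n_per_group = 8L, shift_um = 0,
                                     n_sources = 30L, n_targets = 40L,
                                     n_other = 60L,
                                     region_um = c(1000, 1000),
                                     source_type = "source",
                                     target_type = "target",
                                     seed = 1L) {
  if (shift_um < 0) stop("shift_um must be >= 0")
  set.seed(seed)
  n_cells <- n_sources + n_targets + n_other
  types <- c(rep(source_type, n_sources), rep(target_type, n_targets),
             rep("other", n_other))
  samples <- list()
  group_map <- character(0)
  for (g in c("A", "B")) {
    for (s in seq_len(n_per_group)) {
      sid <- sprintf("%s_%02d", g, s)
      x <- stats::runif(n_cells, 0, region_um[1L])
      y <- stats::runif(n_cells, 0, region_um[2L])
      if (shift_um > 0 && g == "A") {
        src <- seq_len(n_sources)
        tgt <- n_sources + seq_len(n_targets)
        for (i in src) {
          d <- sqrt((x[tgt] - x[i])^2 + (y[tgt] - y[i])^2)
          j <- tgt[which.min(d)]
          dm <- min(d)
          step <- min(shift_um, max(dm - 1, 0))
          if (dm > 0 && step > 0) {
            x[i] <- x[i] + (x[j] - x[i]) * step / dm
            y[i] <- y[i] + (y[j] - y[i]) * step / dm
          }
        }
      }
      samples[[sid]] <- data.frame(sample_id = sid,
                                   cell_id = seq_len(n_cells),
                                   centroid_x_um = x, centroid_y_um = y,
                                   cell_type = types,
                                   stringsAsFactors = FALSE)
      group_map[sid] <- g
    }
  }
  cells <- do.call(rbind, samples)
  rownames(cells) <- NULL
  class(cells) <- c("cell_table", "data.frame")
  list(cells = cells, group_map = group_map)
}
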