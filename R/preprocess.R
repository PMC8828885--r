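#' Normalisation parameters
#'
#' @param percentile percentile in `(0, 100]` used as the per-channel
#'   rescaling reference; default 99.
#' @param scope `"per_image"` (percentile computed within each image) or
#'   `"pooled_across_samples"` (per channel, pooled over all samples'
#'   pixels).
#' @return A list of class `normalisation_params`.
#' @export
normalisation_params <- function(percentile = 99,
                                 scope = c("per_image",
                                           "pooled_across_samples")) {
  scope <- match.arg(scope)
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile > 100) {
    stop("percentile must be in (0, 100]")
  }
  structure(list(percentile = percentile, scope = scope),
            class = "normalisation_params")
}

# percentile by linear interpolation between order statistics
# (inclusive method; quantile type 7)
channel_percentile <- function(v, percentile) {
  unname(stats::quantile(v, probs = percentile / 100, type = 7, names = FALSE))
}

#' Percentile normalisation of channel intensities
#'
#' Rescales each channel so that its chosen percentile (default the 99th)
#' maps to 1: every value `v` becomes `min(v / P, 1)`, where `P` is the
#' percentile of the channel's pixel distribution. Values above the
#' percentile are clipped to 1. A channel whose percentile is 0 becomes all
#' zeros, with a warning. The percentile uses linear interpolation between
#' order statistics.
#'
#' With `scope = "pooled_across_samples"` pass a list of stacks: the
#' percentile of each channel is computed on the pooled pixels of all
#' samples and applied to each.
#'
#' @param stack a [channel_stack], or a list of them for pooled scope.
#' @param params a [normalisation_params].
#' @return A normalised [channel_stack] (or list of them), flagged
#'   `normalised`.
#' @export
normalise_percentile <- function(stack, params = normalisation_params()) {
  stopifnot(inherits(params, "normalisation_params"))
  if (params$scope == "pooled_across_samples") {
    if (inherits(stack, "channel_stack")) stack <- list(stack)
    if (any(vapply(stack, function(s) s$normalised, logical(1)))) {
      stop("state error: input stack is already normalised")
    }
    n_ch <- nrow(stack[[1L]]$channels)
    P <- vapply(seq_len(n_ch), function(ci) {
      channel_percentile(unlist(lapply(stack, function(s) s$pixels[, , ci])),
                         params$percentile)
    }, numeric(1))
    out <- lapply(stack, function(s) rescale_stack(s, P))
    if (length(out) == 1L) out[[1L]] else out
  } else {
    stopifnot(inherits(stack, "channel_stack"))
    if (stack$normalised) stop("state error: input stack is already normalised")
    n_ch <- nrow(stack$channels)
    P <- vapply(seq_len(n_ch), function(ci) {
      channel_percentile(stack$pixels[, , ci], params$percentile)
    }, numeric(1))
    rescale_stack(stack, P)
  }
}

rescale_stack <- function(stack, P) {
  px <- stack$pixels
  for (ci in seq_along(P)) {
    if (P[ci] <= 0) {
      warning("channel '", stack$channels$channel_name[ci],
              "' has zero percentile; set to all zeros")
      px[, , ci] <- 0
    } else {
      px[, , ci] <- pmin(px[, , ci] / P[ci], 1)
    }
  }
  channel_stack(px, stack$channels, pixel_size_um = stack$pixel_size_um,
                sample_id = stack$sample_id, normalised = TRUE)
}

# 256-bin histogram over the channel's range; returns counts, bin centres
# and upper bin edges shared by the single- and multi-class Otsu variants
otsu_histogram <- function(v, n_bins = 256L) {
  rng <- range(v)
  if (rng[1] == rng[2]) {
    stop("degenerate input: channel is constant, cannot threshold")
  }
  width <- (rng[2] - rng[1]) / n_bins
  bin <- pmin(floor((v - rng[1]) / width), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  centres <- rng[1] + (seq_len(n_bins) - 0.5) * width
  edges <- rng[1] + seq_len(n_bins) * width       # upper edge of each bin
  list(counts = counts, centres = centres, edges = edges)
}

#' Otsu threshold of a single channel
#'
#' Computes the threshold maximising the between-class variance over a
#' 256-bin histogram of the channel's range and returns the mask of pixels
#' strictly greater than the threshold. The threshold is the upper edge of
#' the last background bin; on ties the lowest maximising split is taken.
#'
#' @param channel numeric `H x W` matrix.
#' @param name name for the returned mask.
#' @return A list with elements `mask` (a [binary_mask]) and `threshold`.
#' @export
threshold_otsu <- function(channel, name = "otsu") {
  h <- otsu_histogram(channel)
  n <- sum(h$counts)
  w0 <- cumsum(h$counts)[-256L]
  s0 <- cumsum(h$counts * h$centres)[-256L]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (sum(h$counts * h$centres) - s0) / w1, 0)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  t_idx <- which.max(sigma_b)
  thr <- h$edges[t_idx]
  list(mask = binary_mask(channel > thr, name,
                          provenance = sprintf("otsu(threshold=%.6g)", thr)),
       threshold = thr)
}

#' Multi-class Otsu threshold
#'
#' Finds `classes - 1` thresholds maximising the multi-class between-class
#' variance over a 256-bin histogram of the channel's range, and returns
#' the mask of pixels in the top `classes - background_classes` classes
#' (strictly greater than the `background_classes`-th threshold). With
#' `classes = 2, background_classes = 1` this reduces to [threshold_otsu].
#'
#' @param channel numeric `H x W` matrix.
#' @param classes total number of intensity classes (>= 2).
#' @param background_classes number of lowest classes treated as
#'   background (`1 <= background_classes < classes`).
#' @param name name for the returned mask.
#' @return A list with elements `mask` (a [binary_mask]) and `thresholds`
#'   (increasing numeric vector of length `classes - 1`).
#' @export
threshold_multiotsu <- function(channel, classes = 3L,
                                background_classes = classes - 1L,
                                name = "multiotsu") {
  classes <- as.integer(classes)
  background_classes <- as.integer(background_classes)
  if (classes < 2L) stop("classes must be >= 2")
  if (background_classes < 1L || background_classes >= classes) {
    stop("background_classes must be in [1, classes - 1]")
  }
  if (length(unique(as.vector(channel))) < classes) {
    stop("degenerate input: fewer distinct values than requested classes")
  }
  h <- otsu_histogram(channel)
  # maximising sum_k w_k mu_k^2 is equivalent to maximising the
  # between-class variance; cumulative sums make each segment O(1)
  W <- c(0, cumsum(h$counts))
  S <- c(0, cumsum(h$counts * h$centres))
  seg <- function(a, b) {            # bins a..b (1-based, inclusive)
    w <- W[b + 1L] - W[a]
    s <- S[b + 1L] - S[a]
    ifelse(w > 0, s^2 / w, 0)
  }
  splits <- utils::combn(255L, classes - 1L)   # split after these bins
  crit <- numeric(ncol(splits))
  bounds <- rbind(rep(0L, ncol(splits)), splits, rep(256L, ncol(splits)))
  for (k in seq_len(classes)) {
    crit <- crit + seg(bounds[k, ] + 1L, bounds[k + 1L, ])
  }
  best <- which.max(crit)
  thr <- h$edges[splits[, best]]
  cut <- thr[background_classes]
  list(mask = binary_mask(channel > cut, name,
                          provenance = sprintf(
                            "multiotsu(classes=%d, background=%d, cut=%.6g)",
                            classes, background_classes, cut)),
       thresholds = thr)
}

#' Fixed threshold
#'
#' @param channel numeric matrix.
#' @param t threshold; mask is `channel > t` (strict).
#' @param name mask name.
#' @return A list with elements `mask` and `threshold`.
#' @export
threshold_fixed <- function(channel, t, name = "fixed") {
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t))
  list(mask = binary_mask(channel > t, name,
                          provenance = sprintf("fixed(threshold=%.6g)", t)),
       threshold = t)
}

# symmetric (edge-inclusive) reflection padding of a matrix
pad_reflect <- function(m, r) {
  ri <- c(r:1, seq_len(nrow(m)), nrow(m):(nrow(m) - r + 1L))
  ci <- c(r:1, seq_len(ncol(m)), ncol(m):(ncol(m) - r + 1L))
  m[ri, ci, drop = FALSE]
}

#' Gaussian smoothing
#'
#' Convolution with an isotropic Gaussian of standard deviation
#' `radius_px`, using a symmetric reflective boundary. The kernel is
#' truncated at four standard deviations and normalised to unit mass, so a
#' constant image is unchanged and total intensity is conserved.
#'
#' @param channel numeric `H x W` matrix.
#' @param radius_px Gaussian standard deviation in pixels (> 0).
#' @return Smoothed `H x W` matrix.
#' @export
smooth_gaussian <- function(channel, radius_px) {
  if (!is.numeric(radius_px) || radius_px <= 0) {
    stop("radius_px must be positive")
  }
  r <- max(1L, as.integer(ceiling(4 * radius_px)))
  k <- exp(-(( -r:r)^2) / (2 * radius_px^2))
  k <- k / sum(k)
  if (nrow(channel) < 2L || ncol(channel) < 2L) {
    stop("channel must be at least 2 x 2")
  }
  # reflection padding longer than the image is folded by repeated padding
  pad_once <- min(r, nrow(channel) - 1L, ncol(channel) - 1L)
  p <- channel
  left <- r
  while (left > 0L) {
    step <- min(pad_once, left)
    p <- pad_reflect(p, step)
    left <- left - step
  }
  H <- nrow(channel); W <- ncol(channel)
  # separable convolution: rows then columns, on the padded image
  tmp <- matrix(0, nrow(p), W)
  for (d in seq_along(k)) {
    tmp <- tmp + k[d] * p[, (d - 1L) + seq_len(W), drop = FALSE]
  }
  out <- matrix(0, H, W)
  for (d in seq_along(k)) {
    out <- out + k[d] * tmp[(d - 1L) + seq_len(H), , drop = FALSE]
  }
  out
}

#' Disk structuring element
#'
#' Rasterised as all pixels whose centre lies within `radius` of the
#' central pixel's centre.
#'
#' @param radius disk radius in pixels (> 0).
#' @return A 0/1 integer matrix of odd dimensions.
#' @export
disk_kernel <- function(radius) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  r <- floor(radius)
  d <- -r:r
  k <- outer(d^2, d^2, `+`) <= radius^2
  storage.mode(k) <- "integer"
  k
}

mask_px <- function(m) if (inherits(m, "binary_mask")) m$pixels else m

#' Binary morphology with a disk structuring element
#'
#' `mask_dilate` and `mask_erode` are the usual Minkowski operations;
#' `mask_opening` is erosion followed by dilation with the same disk.
#'
#' @param mask logical matrix or [binary_mask].
#' @param radius_px disk radius.
#' @return Logical matrix.
#' @export
mask_dilate <- function(mask, radius_px) {
  m <- mask_px(mask)
  EBImage::dilate(m * 1.0, disk_kernel(radius_px)) > 0.5
}

#' @rdname mask_dilate
#' @export
mask_erode <- function(mask, radius_px) {
  m <- mask_px(mask)
  EBImage::erode(m * 1.0, disk_kernel(radius_px)) > 0.5
}

#' @rdname mask_dilate
#' @export
mask_opening <- function(mask, radius_px) {
  mask_dilate(mask_erode(mask, radius_px), radius_px)
}

#' Connected-component labelling (4-connectivity)
#'
#' Labels the `TRUE` pixels of a mask into 4-connected components,
#' numbered `1..N` in raster order of each component's topmost-leftmost
#' pixel.
#'
#' @param mask logical matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  m <- mask_px(mask)
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  if (!any(m)) return(lab)
  # raster (row-major) linear index as initial label: its minimum over a
  # component is attained at the topmost-leftmost pixel
  raster <- (row(m) - 1L) * W + col(m)
  lab[m] <- raster[m]
  big <- H * W + 1L
  repeat {
    cur <- lab
    cur[!m] <- big
    up    <- rbind(cur[-1, , drop = FALSE], rep(big, W))
    down  <- rbind(rep(big, W), cur[-H, , drop = FALSE])
    left  <- cbind(cur[, -1, drop = FALSE], rep(big, H))
    right <- cbind(rep(big, H), cur[, -W, drop = FALSE])
    new <- pmin(cur, up, down, left, right)
    new[!m] <- 0L
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0L]))
  lab[m] <- match(lab[m], ids)
  lab
}

#' Fill small interior holes of a mask
#'
#' Background-connected components (4-connectivity) of area strictly less
#' than `max_area_px` that do not touch the image border are filled.
#' Border-touching background stays background regardless of size.
#'
#' @param mask logical matrix or [binary_mask].
#' @param max_area_px hole-area cutoff (strict).
#' @return Logical matrix.
#' @export
mask_fill_holes <- function(mask, max_area_px) {
  m <- mask_px(mask)
  if (!is.numeric(max_area_px) || max_area_px <= 0) {
    stop("max_area_px must be positive")
  }
  bg <- label_components(!m)
  if (max(bg) == 0L) return(m)
  border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  areas <- tabulate(bg[bg > 0L], nbins = max(bg))
  fill <- setdiff(which(areas < max_area_px), border_ids)
  out <- m
  out[bg %in% fill] <- TRUE
  out
}

#' Mask recipe
#'
#' An ordered list of operations turning one or more channels or existing
#' masks into a named binary mask. Channel sources may first be smoothed
#' (`smooth_gaussian`) and must then pass a thresholding step
#' (`threshold_otsu`, `threshold_multiotsu` or `threshold_fixed`) before
#' any morphological or boolean step; mask sources are used as-is.
#' Multiple sources are combined with a `union` step. Available steps:
#'
#' * `step("smooth_gaussian", radius_px = )` — channel stage only
#' * `step("threshold_otsu")`,
#'   `step("threshold_multiotsu", classes = , background_classes = )`,
#'   `step("threshold_fixed", t = )`
#' * `step("dilate", radius_px = )`, `step("opening", radius_px = )`,
#'   `step("fill_holes", max_area_px = )`
#' * `step("union")` — OR of all current sources (plus any masks named in
#'   `masks = c(...)`)
#' * `step("subtract", mask = )`, `step("intersect", mask = )` — boolean
#'   combination with a previously defined mask
#'
#' @param name name of the resulting mask.
#' @param source character vector of channel names and/or existing mask
#'   names.
#' @param steps list of steps; each a named list with element `op` plus
#'   its parameters (see above).
#' @return An object of class `mask_recipe`.
#' @export
mask_recipe <- function(name, source, steps) {
  stopifnot(is.character(source), length(source) >= 1L, is.list(steps))
  steps <- lapply(steps, function(s) {
    if (is.character(s)) s <- list(op = s)
    if (is.null(s$op)) stop("each recipe step needs an 'op' element")
    s
  })
  structure(list(name = as.character(name), source = source, steps = steps),
            class = "mask_recipe")
}

is_threshold_op <- function(op) {
  op %in% c("threshold_otsu", "threshold_multiotsu", "threshold_fixed")
}

#' Run a mask recipe
#'
#' Applies the recipe's steps in order (see [mask_recipe] for semantics).
#' Dilation and opening use a disk structuring element; hole filling is
#' 4-connected and exempts border-touching background.
#'
#' @param stack a [channel_stack] supplying channel sources.
#' @param recipe a [mask_recipe].
#' @param existing named list of previously computed [binary_mask]s
#'   available as sources or operands.
#' @return A [binary_mask] named after the recipe.
#' @export
run_mask_recipe <- function(stack, recipe, existing = list()) {
  stopifnot(inherits(recipe, "mask_recipe"))
  chan_names <- if (!is.null(stack)) stack$channels$channel_name else character()
  items <- lapply(recipe$source, function(s) {
    if (s %in% names(existing)) {
      list(kind = "mask", px = mask_px(existing[[s]]))
    } else if (s %in% chan_names) {
      list(kind = "channel", px = get_channel(stack, s))
    } else {
      stop("recipe error: unknown source '", s, "' in recipe '",
           recipe$name, "'")
    }
  })
  need_one <- function(op, i) {
    if (length(items) > 1L) {
      stop("recipe error at step ", i, " ('", op,
           "'): multiple sources must be combined with a union step first")
    }
  }
  get_operand <- function(s, i) {
    nm <- s$mask
    if (is.null(nm) || !nm %in% names(existing)) {
      stop("recipe error at step ", i, " ('", s$op,
           "'): unknown mask operand '", if (is.null(nm)) "" else nm, "'")
    }
    mask_px(existing[[nm]])
  }
  for (i in seq_along(recipe$steps)) {
    s <- recipe$steps[[i]]
    op <- s$op
    if (op == "smooth_gaussian") {
      items <- lapply(items, function(it) {
        if (it$kind != "channel") {
          stop("recipe error at step ", i,
               ": smooth_gaussian applies to channels, not masks")
        }
        it$px <- smooth_gaussian(it$px, s$radius_px)
        it
      })
    } else if (is_threshold_op(op)) {
      items <- lapply(items, function(it) {
        if (it$kind != "channel") {
          stop("recipe error at step ", i,
               ": thresholding applies to channels, not masks")
        }
        res <- switch(op,
          threshold_otsu = threshold_otsu(it$px),
          threshold_multiotsu = threshold_multiotsu(
            it$px, classes = s$classes,
            background_classes = s$background_classes),
          threshold_fixed = threshold_fixed(it$px, t = s$t))
        list(kind = "mask", px = res$mask$pixels)
      })
    } else if (op == "union") {
      extra <- lapply(s$masks, function(nm) {
        list(kind = "mask", px = get_operand(list(mask = nm, op = "union"), i))
      })
      all_items <- c(items, extra)
      if (any(vapply(all_items, function(it) it$kind != "mask", logical(1)))) {
        stop("recipe error at step ", i,
             ": union requires thresholded (mask) inputs")
      }
      px <- Reduce(`|`, lapply(all_items, `[[`, "px"))
      items <- list(list(kind = "mask", px = px))
    } else if (op %in% c("dilate", "opening", "fill_holes")) {
      need_one(op, i)
      if (items[[1L]]$kind != "mask") {
        stop("recipe error at step ", i, " ('", op,
             "'): channel source must be thresholded first")
      }
      items[[1L]]$px <- switch(op,
        dilate = mask_dilate(items[[1L]]$px, s$radius_px),
        opening = mask_opening(items[[1L]]$px, s$radius_px),
        fill_holes = mask_fill_holes(items[[1L]]$px, s$max_area_px))
    } else if (op %in% c("subtract", "intersect")) {
      need_one(op, i)
      if (items[[1L]]$kind != "mask") {
        stop("recipe error at step ", i, " ('", op,
             "'): channel source must be thresholded first")
      }
      operand <- get_operand(s, i)
      items[[1L]]$px <- if (op == "subtract") {
        items[[1L]]$px & !operand
      } else {
        items[[1L]]$px & operand
      }
    } else {
      stop("recipe error at step ", i, ": unknown op '", op, "'")
    }
  }
  if (length(items) > 1L) {
    stop("recipe '", recipe$name,
         "' ends with multiple sources; add a union step")
  }
  if (items[[1L]]$kind != "mask") {
    stop("recipe '", recipe$name, "' never thresholds its channel source")
  }
  binary_mask(items[[1L]]$px, recipe$name,
              provenance = paste(vapply(recipe$steps, `[[`, "", "op"),
                                 collapse = " -> "))
}
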