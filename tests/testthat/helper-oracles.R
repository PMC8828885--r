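# Independent brute-force oracles. Each reimplements a contract by the
# most direct route available (exhaustive scan, double loop, per-pixel
# accumulation) without sharing code with the package internals.

# exhaustive Otsu: same 256-bin histogram contract, but the between-class
# variance of every split is computed directly from class members
oracle_otsu <- function(v) {
  rng <- range(v)
  width <- (rng[2] - rng[1]) / 256
  bin <- pmin(floor((v - rng[1]) / width), 255)
  centres <- rng[1] + (0:255 + 0.5) * width
  best <- -Inf
  best_t <- NA
  for (t in 0:254) {
    lo <- bin <= t
    if (!any(lo) || all(lo)) next
    w0 <- mean(lo)
    w1 <- 1 - w0
    mu0 <- mean(centres[bin[lo] + 1])
    mu1 <- mean(centres[bin[!lo] + 1])
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best + 1e-12) {
      best <- s
      best_t <- rng[1] + (t + 1) * width
    }
  }
  best_t
}

# exhaustive multi-Otsu over all split pairs/triples
oracle_multiotsu <- function(v, classes) {
  rng <- range(v)
  width <- (rng[2] - rng[1]) / 256
  bin <- pmin(floor((v - rng[1]) / width), 255)
  centres <- rng[1] + (0:255 + 0.5) * width
  val <- centres[bin + 1]
  splits <- utils::combn(255, classes - 1)
  best <- -Inf
  best_s <- NULL
  for (i in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, i], 256)
    s <- 0
    for (k in seq_len(classes)) {
      sel <- bin >= cuts[k] & bin < cuts[k + 1]
      if (any(sel)) s <- s + mean(sel) * mean(val[sel])^2
    }
    if (s > best + 1e-12) {
      best <- s
      best_s <- rng[1] + splits[, i] * width
    }
  }
  best_s
}

# dense 2-D Gaussian convolution with symmetric reflection, pixel by pixel
oracle_gauss <- function(m, sd) {
  r <- max(1L, as.integer(ceiling(4 * sd)))
  k1 <- exp(-((-r:r)^2) / (2 * sd^2))
  k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  H <- nrow(m); W <- ncol(m)
  reflect <- function(i, n) {
    # symmetric (edge-inclusive) reflection of out-of-range indices
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          acc <- acc + K[di + r + 1, dj + r + 1] *
            m[reflect(i + di, H), reflect(j + dj, W)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

oracle_disk_area <- function(radius) {
  r <- ceiling(radius)
  count <- 0L
  for (dx in -r:r) {
    for (dy in -r:r) {
      if (dx^2 + dy^2 <= radius^2) count <- count + 1L
    }
  }
  count
}

# per-pixel accumulation of cell features
oracle_features <- function(lab, px3d) {
  n <- max(lab)
  H <- nrow(lab); W <- ncol(lab); C <- dim(px3d)[3]
  area <- integer(n); sx <- numeric(n); sy <- numeric(n)
  sums <- matrix(0, n, C)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      l <- lab[i, j]
      if (l == 0) next
      area[l] <- area[l] + 1L
      sx[l] <- sx[l] + (j - 1)
      sy[l] <- sy[l] + (i - 1)
      for (c in seq_len(C)) sums[l, c] <- sums[l, c] + px3d[i, j, c]
    }
  }
  list(area = area, cx = sx / area, cy = sy / area,
       means = sums / area)
}

# O(n*m) nearest-target scan with self-exclusion
oracle_nearest <- function(sx, sy, sid_s, tx, ty, sid_t) {
  n <- length(sx)
  d <- numeric(n); j_best <- integer(n)
  for (i in seq_len(n)) {
    best <- Inf; jb <- NA_integer_
    for (j in seq_along(tx)) {
      if (!is.null(sid_s) && sid_s[i] == sid_t[j]) next
      dd <- sqrt((sx[i] - tx[j])^2 + (sy[i] - ty[j])^2)
      if (dd < best) { best <- dd; jb <- j }
    }
    d[i] <- best; j_best[i] <- jb
  }
  list(dist = d, idx = j_best)
}

# textbook DBSCAN on the all-pairs distance matrix, matching the package's
# deterministic border rule (nearest core, ties by core coordinates)
oracle_dbscan <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  D <- as.matrix(dist(xy))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  is_core <- lengths(nb) >= min_pts
  comp <- integer(n)
  cid <- 0
  for (s in which(is_core)) {
    if (comp[s] != 0) next
    cid <- cid + 1
    stack <- s
    comp[s] <- cid
    while (length(stack)) {
      p <- stack[1]; stack <- stack[-1]
      for (q in nb[[p]]) {
        if (is_core[q] && comp[q] == 0) {
          comp[q] <- cid
          stack <- c(stack, q)
        }
      }
    }
  }
  labels <- integer(n)
  labels[is_core] <- comp[is_core]
  for (i in which(!is_core)) {
    cores <- nb[[i]][is_core[nb[[i]]]]
    if (!length(cores)) next
    ord <- cores[order(D[i, cores], xy[cores, 1], xy[cores, 2])]
    labels[i] <- comp[ord[1]]
  }
  # renumber by size desc, ties by smallest member coordinates
  ids <- setdiff(sort(unique(labels)), 0)
  if (!length(ids)) return(labels)
  sizes <- sapply(ids, function(k) sum(labels == k))
  minx <- sapply(ids, function(k) min(xy[labels == k, 1]))
  miny <- sapply(ids, function(k) min(xy[labels == k, 2]))
  ord <- ids[order(-sizes, minx, miny)]
  out <- labels
  out[labels > 0] <- match(labels[labels > 0], ord)
  out
}

# exact Wilcoxon rank-sum statistic by enumeration of ranks
oracle_rank_sum_W <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# paint a set of disks (value on full disk, labels for truth)
paint_disks <- function(H, W, centres, radius, value = 1) {
  m <- matrix(0, H, W)
  lab <- matrix(0L, H, W)
  for (k in seq_len(nrow(centres))) {
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        if ((i - 1 - centres[k, 2])^2 + (j - 1 - centres[k, 1])^2 <=
            radius^2) {
          m[i, j] <- value
          lab[i, j] <- k
        }
      }
    }
  }
  list(channel = m, labels = lab)
}

# distance-table rows for group-comparison tests
cells_dist <- function(d, sid, st = "x", tt = "y") {
  data.frame(cell_id = seq_along(d), sample_id = sid,
             source_type = st, target_type = tt,
             nearest_distance_um = d, stringsAsFactors = FALSE)
}

# small helper: single-channel stack from a matrix
mat_stack <- function(m, name = "ch1", pixel_size_um = 1, role = "marker",
                      sample_id = "s1") {
  channel_stack(m, channel_metadata(name, role = role),
                pixel_size_um = pixel_size_um, sample_id = sample_id)
}
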