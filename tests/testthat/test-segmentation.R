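test_that("planted disks are detected with accurate centroids and areas", {
  centres <- cbind(x = c(10, 30), y = c(12, 25))   # 5-px-radius disks
  pd <- paint_disks(40, 40, centres, 5)
  st <- mat_stack(pd$channel, "DNA1", role = "nucleus")
  p <- segmentation_params("DNA1", min_diameter_px = 4, max_diameter_px = 60)
  nuc <- detect_nuclei(st, p)
  expect_equal(nuc$n_cells, 2L)
  cells <- extract_features(nuc, st)
  ord <- order(cells$centroid_x_px)
  expect_true(all(abs(cells$centroid_x_px[ord] - centres[, "x"]) < 0.5))
  expect_true(all(abs(cells$centroid_y_px[ord] - centres[, "y"]) < 0.5))
})

test_that("the size filter removes out-of-range components", {
  m <- matrix(0, 20, 20)
  m[10, 10:11] <- 1                      # 2-px blob: diameter ~1.6
  st <- mat_stack(m, "DNA1", role = "nucleus")
  p <- segmentation_params("DNA1", nucleus_threshold = 0.5,
                           min_diameter_px = 4, max_diameter_px = 60)
  expect_warning(nuc <- detect_nuclei(st, p), "no nuclei")
  expect_equal(nuc$n_cells, 0L)
})

test_that("thirty random planted disks are recovered exactly with planted areas", {
  set.seed(21)
  H <- W <- 120
  r <- 3
  centres <- matrix(NA_real_, 0, 2)
  while (nrow(centres) < 30) {
    cand <- c(sample(5:(W - 6), 1), sample(5:(H - 6), 1))
    if (nrow(centres) == 0 ||
        all((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2 >
            (2 * r + 2)^2)) {
      centres <- rbind(centres, cand)
    }
  }
  colnames(centres) <- c("x", "y")
  pd <- paint_disks(H, W, centres, r)
  st <- mat_stack(pd$channel, "DNA1", role = "nucleus")
  p <- segmentation_params("DNA1", nucleus_threshold = 0.5,
                           min_diameter_px = 2, max_diameter_px = 20)
  nuc <- detect_nuclei(st, p)
  expect_equal(nuc$n_cells, 30L)
  areas <- tabulate(nuc$pixels[nuc$pixels > 0], 30)
  expect_true(all(areas == oracle_disk_area(r)))
})

test_that("isotropic expansion equals brute-force nearest-seed dilation", {
  m <- matrix(0, 30, 30); m[14:16, 14:16] <- 1    # 3x3 nucleus
  st <- mat_stack(m, "DNA1", role = "nucleus")
  p <- segmentation_params("DNA1", nucleus_threshold = 0.5,
                           min_diameter_px = 1, max_diameter_px = 20,
                           expansion = "isotropic", expansion_px = 5)
  nuc <- detect_nuclei(st, p)
  cells <- expand_cells(nuc, p)
  # brute force: all pixels within 5 px of any nucleus pixel
  ref <- matrix(FALSE, 30, 30)
  nuc_idx <- which(m == 1, arr.ind = TRUE)
  for (i in 1:30) for (j in 1:30) {
    ref[i, j] <- any((nuc_idx[, 1] - i)^2 + (nuc_idx[, 2] - j)^2 <= 25)
  }
  expect_equal(cells$pixels > 0, ref)
})

test_that("contested pixels go to the nearest nucleus, exact ties to the lower label", {
  m <- matrix(0, 15, 21)
  m[8, 8] <- 1; m[8, 14] <- 1                     # two 1-px nuclei 6 px apart
  st <- mat_stack(m, "DNA1", role = "nucleus")
  p <- segmentation_params("DNA1", nucleus_threshold = 0.5,
                           min_diameter_px = 1, max_diameter_px = 5,
                           expansion = "isotropic", expansion_px = 5)
  nuc <- detect_nuclei(st, p)
  cells <- expand_cells(nuc, p)
  lab <- cells$pixels
  expect_true(all(lab[, 1:10][lab[, 1:10] > 0] == 1))
  expect_true(all(lab[, 12:21][lab[, 12:21] > 0] == 2))
  expect_true(all(lab[, 11][lab[, 11] > 0] == 1))  # equidistant column: lower label
})

test_that("radial expansion saturates to the nucleus on an empty membrane mask", {
  m <- matrix(0, 20, 20); m[9:11, 9:11] <- 1
  st <- mat_stack(m, "DNA1", role = "nucleus")
  p <- segmentation_params("DNA1", nucleus_threshold = 0.5,
                           min_diameter_px = 1, max_diameter_px = 20,
                           expansion = "radial", expansion_px = 10)
  nuc <- detect_nuclei(st, p)
  empty <- binary_mask(matrix(FALSE, 20, 20), "membrane")
  cells <- expand_cells(nuc, p, empty)
  expect_identical(cells$pixels, nuc$pixels)
  expect_error(expand_cells(nuc, p), "membrane")
})

test_that("radial expansion grows only into membrane-positive pixels", {
  m <- matrix(0, 20, 20); m[9:11, 9:11] <- 1
  st <- mat_stack(m, "DNA1", role = "nucleus")
  p <- segmentation_params("DNA1", nucleus_threshold = 0.5,
                           min_diameter_px = 1, max_diameter_px = 20,
                           expansion = "radial", expansion_px = 4)
  nuc <- detect_nuclei(st, p)
  mem <- matrix(FALSE, 20, 20); mem[, 1:10] <- TRUE
  cells <- expand_cells(nuc, p, binary_mask(mem, "membrane"))
  lab <- cells$pixels
  grown <- lab > 0 & nuc$pixels == 0
  expect_true(all(mem[grown]))                       # growth inside mask only
  expect_true(all(lab[nuc$pixels > 0] == nuc$pixels[nuc$pixels > 0]))
})

test_that("watershed expansion fills the allowed region disjointly, seeds preserved", {
  m <- matrix(0, 24, 24); m[6, 6] <- 1; m[18, 18] <- 1
  st <- mat_stack(m, "DNA1", role = "nucleus")
  p <- segmentation_params("DNA1", nucleus_threshold = 0.5,
                           min_diameter_px = 1, max_diameter_px = 5,
                           expansion = "watershed")
  nuc <- detect_nuclei(st, p)
  mem <- matrix(TRUE, 24, 24)
  cells <- expand_cells(nuc, p, binary_mask(mem, "membrane"))
  lab <- cells$pixels
  expect_equal(sort(unique(as.vector(lab))), c(1L, 2L))   # full coverage
  expect_equal(lab[6, 6], 1L)
  expect_equal(lab[18, 18], 2L)
  expect_gt(sum(lab == 1), 100)
  expect_gt(sum(lab == 2), 100)
  # restricted region: labels never escape nucleus-or-membrane pixels
  mem2 <- matrix(FALSE, 24, 24); mem2[1:12, ] <- TRUE
  cells2 <- expand_cells(nuc, p, binary_mask(mem2, "membrane"))
  outside <- !(mem2 | nuc$pixels > 0)
  expect_true(all(cells2$pixels[outside] == 0))
})

test_that("feature extraction matches hand computation and per-pixel oracle", {
  lab <- matrix(0L, 4, 4); lab[1:2, 1:2] <- 1L
  px <- array(0, c(4, 4, 2))
  px[1:2, 1:2, 1] <- matrix(c(1, 3, 2, 4), 2, 2)  # values 1..4 in the cell
  st <- channel_stack(px, channel_metadata(c("A", "Zero")))
  cells <- extract_features(label_image(lab), st)
  expect_equal(cells$A, 2.5)
  expect_equal(cells$Zero, 0)
  expect_equal(cells$centroid_x_px, 0.5)
  expect_equal(cells$centroid_y_px, 0.5)
  expect_equal(cells$area_px, 4L)

  set.seed(31)
  centres <- expand.grid(x = c(8, 20, 32, 44), y = c(8, 20, 32, 44, 56))
  pd <- paint_disks(64, 52, as.matrix(centres), 3)
  px2 <- array(runif(64 * 52 * 2), c(64, 52, 2))
  st2 <- channel_stack(px2, channel_metadata(c("c1", "c2")))
  cells2 <- extract_features(label_image(pd$labels), st2)
  orc <- oracle_features(pd$labels, px2)
  expect_equal(cells2$area_px, orc$area)
  expect_equal(cells2$centroid_x_px, orc$cx)
  expect_equal(cells2$centroid_y_px, orc$cy)
  expect_equal(cells2$c1, orc$means[, 1])
  expect_equal(cells2$c2, orc$means[, 2])
})

test_that("label images with gaps are rejected; external labels flow through", {
  expect_error(label_image(matrix(c(0L, 1L, 3L, 3L), 2, 2)), "no gaps")
  # externally supplied labels (no detect/expand) feed extract_features
  ext <- label_image(matrix(c(1L, 1L, 0L, 2L), 2, 2))
  st <- mat_stack(matrix(1:4, 2, 2) * 1.0)
  cells <- extract_features(ext, st)
  expect_equal(nrow(cells), 2L)
  expect_equal(cells$area_px, c(2L, 1L))
})

test_that("micrometre centroids scale with pixel size", {
  lab <- label_image(matrix(c(0L, 0L, 1L, 1L), 2, 2))
  st <- mat_stack(matrix(1, 2, 2), pixel_size_um = 0.5)
  cells <- extract_features(lab, st)
  expect_equal(cells$centroid_x_um, cells$centroid_x_px * 0.5)
  expect_equal(cells$centroid_y_um, cells$centroid_y_px * 0.5)
})
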