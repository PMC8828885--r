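make_cells_with_labels <- function(lab_matrix, n_channels = 1) {
  lab <- label_image(lab_matrix)
  px <- array(1, c(nrow(lab_matrix), ncol(lab_matrix), n_channels))
  st <- channel_stack(px, channel_metadata(paste0("ch", seq_len(n_channels))))
  list(labels = lab, cells = extract_features(lab, st))
}

test_that("compartment overlap boundary is inclusive at the configured fraction", {
  lab <- matrix(0L, 5, 5)
  lab[1, 1:5] <- 1L; lab[2, 1:5] <- 1L          # 10-px cell
  x <- make_cells_with_labels(lab)
  m <- matrix(FALSE, 5, 5); m[1, 1:3] <- TRUE   # 3 of 10 px inside
  out <- assign_compartment(x$cells, x$labels,
                            overlap_rule("lamina", 0.30),
                            binary_mask(m, "lamina"))
  expect_equal(out$compartment, "lamina")       # 0.30 >= 0.30: assigned
  out2 <- assign_compartment(x$cells, x$labels,
                             overlap_rule("lamina", 0.31),
                             binary_mask(m, "lamina"))
  expect_true(is.na(out2$compartment))
  # fully outside
  m0 <- matrix(FALSE, 5, 5); m0[5, ] <- TRUE
  out3 <- assign_compartment(x$cells, x$labels,
                             overlap_rule("lamina", 0.1),
                             binary_mask(m0, "lamina"))
  expect_true(is.na(out3$compartment))
})

test_that("compartment assignment matches a per-pixel counting oracle on a half-plane", {
  set.seed(41)
  centres <- as.matrix(expand.grid(x = seq(6, 56, by = 10),
                                   y = seq(6, 66, by = 10)))
  pd <- paint_disks(72, 62, centres, 3)
  x <- make_cells_with_labels(pd$labels)
  half <- col(pd$labels) <= 31
  out <- assign_compartment(x$cells, x$labels, overlap_rule("left", 0.5),
                            binary_mask(half, "left"))
  for (k in seq_len(nrow(centres))) {
    frac <- sum(pd$labels == k & half) / sum(pd$labels == k)
    expect_equal(!is.na(out$compartment[out$cell_id == k]), frac >= 0.5)
  }
})

test_that("highest-overlap typing applies eligibility then argmax with first-listed ties", {
  lab <- matrix(0L, 10, 10); lab[1, 1:10] <- 1L   # one 10-px cell
  x <- make_cells_with_labels(lab)
  mk <- function(n) { m <- matrix(FALSE, 10, 10); m[1, seq_len(n)] <- TRUE; m }
  masks <- list(IgA = binary_mask(mk(2), "IgA"),     # fraction 0.2
                CD3 = binary_mask(mk(1), "CD3"))     # fraction 0.1
  rules <- list(IgA = overlap_rule("IgA", 0.15), CD3 = overlap_rule("CD3", 0.15))
  out <- assign_type_by_highest_overlap(x$cells, x$labels, rules, masks)
  expect_equal(out$cell_type, "IgA")               # CD3 ineligible at 0.10

  masks2 <- list(CD3 = binary_mask(mk(3), "CD3"),   # 0.30 vs min 0.15
                 CD68 = binary_mask(mk(2), "CD68")) # 0.20 vs min 0.25
  rules2 <- list(CD3 = overlap_rule("CD3", 0.15),
                 CD68 = overlap_rule("CD68", 0.25))
  out2 <- assign_type_by_highest_overlap(x$cells, x$labels, rules2, masks2)
  expect_equal(out2$cell_type, "CD3")

  # exact tie: first-listed rule wins, tie is reported
  masks3 <- list(A = binary_mask(mk(2), "A"), B = binary_mask(mk(2), "B"))
  rules3 <- list(A = overlap_rule("A", 0.1), B = overlap_rule("B", 0.1))
  expect_message(out3 <- assign_type_by_highest_overlap(x$cells, x$labels,
                                                        rules3, masks3),
                 "tied")
  expect_equal(out3$cell_type, "A")

  expect_error(assign_type_by_highest_overlap(
    x$cells, x$labels,
    list(a = overlap_rule("A", 0.1), b = overlap_rule("A", 0.2)), masks3),
    "duplicate mask_name")
})

test_that("typing equals a brute-force eligibility+argmax oracle on random fractions", {
  set.seed(43)
  centres <- as.matrix(expand.grid(x = seq(5, 95, by = 10),
                                   y = seq(5, 95, by = 10)))
  pd <- paint_disks(101, 101, centres, 2)
  x <- make_cells_with_labels(pd$labels)
  masks <- list()
  for (nm in c("m1", "m2", "m3")) {
    masks[[nm]] <- binary_mask(matrix(runif(101 * 101) > 0.5, 101, 101), nm)
  }
  mins <- c(m1 = 0.3, m2 = 0.45, m3 = 0.6)
  rules <- lapply(names(mins), function(nm) overlap_rule(nm, mins[[nm]]))
  names(rules) <- names(mins)
  out <- assign_type_by_highest_overlap(x$cells, x$labels, rules, masks)
  for (k in x$cells$cell_id) {
    cellpx <- pd$labels == k
    fr <- vapply(names(mins),
                 function(nm) sum(cellpx & masks[[nm]]$pixels) / sum(cellpx),
                 numeric(1))
    ok <- fr >= mins
    expected <- if (any(ok)) names(mins)[ok][which.max(fr[ok])] else NA_character_
    expect_identical(out$cell_type[out$cell_id == k], expected)
  }
  # each cell receives at most one type
  expect_true(all(is.na(out$cell_type) | nchar(out$cell_type) > 0))
})

test_that("gating boundaries are inclusive and logical combinations intersect", {
  cells <- data.frame(cell_id = 1:3, sample_id = "s",
                      CD4 = c(0.05, 0.1, 0.2),
                      CD8 = c(0.02, 0.005, 0.02),
                      PD1 = c(0.006, 0.001, 0.004),
                      cell_type = NA_character_)
  g <- gate_cells(cells, gate_spec("CD4_T", "CD4 >= 0.1"))
  expect_equal(g$cell_id, 2:3)                     # 0.1 included
  expect_true(all(g$cell_type == "CD4_T"))

  g2 <- gate_cells(cells, gate_spec("PD1_CD8", "CD8 >= 0.01 & PD1 >= 0.005"))
  a <- gate_cells(cells, gate_spec("a", "CD8 >= 0.01"))
  b <- gate_cells(cells, gate_spec("b", "PD1 >= 0.005"))
  expect_equal(g2$cell_id, intersect(a$cell_id, b$cell_id))
})

test_that("gates match direct per-cell evaluation on random expressions", {
  set.seed(44)
  cells <- data.frame(cell_id = 1:50, sample_id = "s",
                      A = runif(50), B = runif(50), C = runif(50),
                      cell_type = NA_character_)
  exprs <- c("A > 0.5", "A >= 0.5 & B < 0.3", "(A > 0.2 | B > 0.8) & !(C <= 0.5)",
             "!(A < 0.1) & (B >= 0.4 | C > 0.9)")
  for (e in exprs) {
    g <- gate_cells(cells, gate_spec("g", e))
    manual <- which(vapply(seq_len(50), function(i) {
      A <- cells$A[i]; B <- cells$B[i]; C <- cells$C[i]
      isTRUE(eval(parse(text = e)))
    }, logical(1)))
    expect_equal(g$cell_id, manual)
  }
})

test_that("gate parsing rejects unknown channels and disallowed operators", {
  cells <- data.frame(cell_id = 1, A = 1, cell_type = NA_character_)
  expect_error(gate_cells(cells, gate_spec("g", "NoSuch > 1")),
               "unknown name 'NoSuch'")
  expect_error(gate_cells(cells, gate_spec("g", "system('ls') > 1")),
               "not allowed")
  expect_error(gate_cells(cells, gate_spec("g", "A >")), "parse error")
})

test_that("raising a >= threshold never adds cells (gating is monotone)", {
  set.seed(45)
  cells <- data.frame(cell_id = 1:100, A = runif(100),
                      cell_type = NA_character_)
  prev <- Inf
  for (t in c(0.2, 0.4, 0.6, 0.8)) {
    n <- nrow(gate_cells(cells, gate_spec("g", paste("A >=", t))))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("nested gates evaluate within the parent subset", {
  cells <- data.frame(cell_id = 1:4, sample_id = "s",
                      CD4 = c(0.2, 0.2, 0.05, 0.2),
                      PD1 = c(0.2, 0.01, 0.2, 0.16),
                      cell_type = NA_character_)
  gates <- list(gate_spec("CD4_T", "CD4 >= 0.1"),
                gate_spec("PD1_CD4_T", "PD1 >= 0.15", parent_gate = "CD4_T"))
  out <- apply_gates(cells, gates)
  expect_equal(out$cell_type, c("PD1_CD4_T", "CD4_T", NA, "PD1_CD4_T"))
})

test_that("clustering recovers three well-separated expression blobs", {
  set.seed(46)
  n_per <- 60
  means <- diag(3)
  X <- do.call(rbind, lapply(1:3, function(k) {
    matrix(rnorm(n_per * 3, mean = rep(means[k, ], each = n_per), sd = 0.01),
           n_per, 3)
  }))
  cells <- data.frame(cell_id = seq_len(3 * n_per), sample_id = "s",
                      m1 = X[, 1], m2 = X[, 2], m3 = X[, 3],
                      cluster_id = NA_integer_)
  truth <- rep(1:3, each = n_per)
  res <- cluster_cells(cells, cluster_params(c("m1", "m2", "m3"),
                                             n_pcs = 2, k_neighbours = 20,
                                             resolution = 0.8, seed = 7))
  expect_equal(length(unique(res$cells$cluster_id)), 3L)
  expect_gte(adjusted_rand_index(res$cells$cluster_id, truth), 0.95)
  # profile table reports mean raw intensity per cluster
  expect_equal(nrow(res$profiles), 3L)
  expect_true(all(c("m1", "m2", "m3") %in% names(res$profiles)))
  for (cl in res$profiles$cluster_id) {
    sel <- res$cells$cluster_id == cl
    expect_equal(res$profiles$m1[res$profiles$cluster_id == cl],
                 mean(cells$m1[sel]))
  }
})

test_that("identical cells collapse to one cluster; fixed seed reproduces labels", {
  cells <- data.frame(cell_id = 1:30, m1 = 1, m2 = 2,
                      cluster_id = NA_integer_)
  res <- cluster_cells(cells, cluster_params(c("m1", "m2"), n_pcs = 1,
                                             k_neighbours = 5, seed = 1))
  expect_true(all(res$cells$cluster_id == 1L))

  set.seed(47)
  cells2 <- data.frame(cell_id = 1:80, m1 = rnorm(80), m2 = rnorm(80),
                       m3 = rnorm(80), cluster_id = NA_integer_)
  p <- cluster_params(c("m1", "m2", "m3"), n_pcs = 2, k_neighbours = 10,
                      resolution = 1, seed = 5)
  r1 <- cluster_cells(cells2, p)
  r2 <- cluster_cells(cells2, p)
  expect_identical(r1$cells$cluster_id, r2$cells$cluster_id)
})

test_that("shuffling cell order permutes labels but not the partition", {
  set.seed(48)
  n_per <- 40
  X <- rbind(matrix(rnorm(n_per * 2, 0, 0.05), n_per, 2),
             matrix(rnorm(n_per * 2, 3, 0.05), n_per, 2))
  cells <- data.frame(cell_id = seq_len(2 * n_per), m1 = X[, 1], m2 = X[, 2],
                      cluster_id = NA_integer_)
  p <- cluster_params(c("m1", "m2"), n_pcs = 2, k_neighbours = 10,
                      resolution = 0.8, seed = 3)
  r1 <- cluster_cells(cells, p)
  perm <- sample(nrow(cells))
  r2 <- cluster_cells(cells[perm, ], p)
  expect_equal(adjusted_rand_index(r1$cells$cluster_id[perm],
                                   r2$cells$cluster_id), 1)
})

test_that("threshold gating and clustering agree on strongly separated phenotypes", {
  set.seed(49)
  n_per <- 50
  # two phenotypes: marker hi vs lo, separation >> 5 sd
  cells <- data.frame(cell_id = seq_len(2 * n_per), sample_id = "s",
                      CD4 = c(rnorm(n_per, 0.8, 0.02), rnorm(n_per, 0.05, 0.02)),
                      CD8 = c(rnorm(n_per, 0.05, 0.02), rnorm(n_per, 0.7, 0.02)),
                      cell_type = NA_character_, cluster_id = NA_integer_)
  cells$CD4 <- pmax(cells$CD4, 0); cells$CD8 <- pmax(cells$CD8, 0)
  gated <- apply_gates(cells, list(gate_spec("CD4_T", "CD4 >= 0.4"),
                                   gate_spec("CD8_T", "CD8 >= 0.4")))
  res <- cluster_cells(cells, cluster_params(c("CD4", "CD8"), n_pcs = 2,
                                             k_neighbours = 20, seed = 2))
  expect_gte(adjusted_rand_index(as.integer(factor(gated$cell_type)),
                                 res$cells$cluster_id), 0.9)
})

test_that("the 2-D embedding is deterministic, shape-preserving and separates blobs", {
  set.seed(50)
  n_per <- 30
  cells <- data.frame(cell_id = seq_len(2 * n_per),
                      m1 = c(rnorm(n_per, 0, 0.05), rnorm(n_per, 5, 0.05)),
                      m2 = c(rnorm(n_per, 0, 0.05), rnorm(n_per, 5, 0.05)),
                      m3 = rnorm(2 * n_per, 1, 0.05))
  p <- cluster_params(c("m1", "m2", "m3"), n_pcs = 2, k_neighbours = 5,
                      seed = 9)
  e1 <- embed_2d(cells, p)
  e2 <- embed_2d(cells, p)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), nrow(cells))
  g1 <- colMeans(e1[1:n_per, c("dim1", "dim2")])
  g2 <- colMeans(e1[(n_per + 1):(2 * n_per), c("dim1", "dim2")])
  between <- sqrt(sum((g1 - g2)^2))
  within <- mean(sqrt((e1$dim1[1:n_per] - g1[1])^2 +
                      (e1$dim2[1:n_per] - g1[2])^2))
  expect_gt(between, within)
})
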