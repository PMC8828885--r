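cells_from_xy <- function(x, y, type = "t", sid = "s1", id = NULL) {
  data.frame(sample_id = sid,
             cell_id = if (is.null(id)) seq_along(x) else id,
             centroid_x_um = x, centroid_y_um = y, cell_type = type,
             stringsAsFactors = FALSE)
}

test_that("the density-derived eps matches the disk-density reading", {
  p <- homotypic_params(min_points = 5, density_per_mm2 = 5)
  expect_equal(p$eps_um, sqrt(5 / (pi * 5)) * 1000)
  expect_error(homotypic_params(5, density_per_mm2 = 5, eps_um = 10),
               "exactly one")
  expect_error(homotypic_params(5), "exactly one")
})

test_that("DBSCAN finds a planted aggregate and flags isolated cells as noise", {
  set.seed(61)
  theta <- runif(20, 0, 2 * pi); rad <- sqrt(runif(20)) * 50
  x <- c(500 + rad * cos(theta), c(50, 1950, 50, 1950))
  y <- c(500 + rad * sin(theta), c(50, 50, 1950, 1950))
  cells <- cells_from_xy(x, y)
  p <- homotypic_params(min_points = 5, eps_um = 100)
  lab <- homotypic_clusters(cells, p)
  expect_equal(sum(lab == 1), 20)
  expect_true(all(lab[21:24] == 0))
})

test_that("fewer cells than min_points yields all noise", {
  cells <- cells_from_xy(c(0, 1, 2), c(0, 0, 0))
  expect_equal(homotypic_clusters(cells, homotypic_params(5, eps_um = 10)),
               c(0L, 0L, 0L))
})

test_that("DBSCAN equals the textbook all-pairs implementation on random cells", {
  set.seed(62)
  for (rep in 1:3) {
    n <- 200
    x <- runif(n, 0, 600); y <- runif(n, 0, 600)
    cells <- cells_from_xy(x, y)
    p <- homotypic_params(min_points = 5, eps_um = 45)
    got <- homotypic_clusters(cells, p)
    want <- oracle_dbscan(cbind(x, y), 45, 5)
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("DBSCAN labels are invariant to input order up to renumbering", {
  set.seed(63)
  n <- 150
  cells <- cells_from_xy(runif(n, 0, 500), runif(n, 0, 500))
  p <- homotypic_params(min_points = 4, eps_um = 40)
  l1 <- homotypic_clusters(cells, p)
  perm <- sample(n)
  l2 <- homotypic_clusters(cells[perm, ], p)
  expect_identical(l1[perm], l2)
})

test_that("nearest distances honour geometry, units and self-exclusion", {
  src <- cells_from_xy(0, 0, "a", id = 1L)
  tgt <- cells_from_xy(c(3, 10), c(4, 0), "b", id = 2:3)
  d <- nearest_distances(src, tgt)
  expect_equal(d$nearest_distance_um, 5)          # 3-4-5 triangle
  expect_equal(d$nearest_target_id, 2L)

  # a cell in both sets matches the second target, not itself
  both <- cells_from_xy(c(0, 8), c(0, 0), "a", id = c(1L, 2L))
  d2 <- nearest_distances(both[1, ], both)
  expect_equal(d2$nearest_distance_um, 8)
  expect_equal(d2$nearest_target_id, 2L)

  # empty targets: skipped with warning
  expect_warning(d3 <- nearest_distances(src, tgt[0, ]), "no target cells")
  expect_equal(nrow(d3), 0L)
})

test_that("nearest distances match the O(n*m) brute-force scan exactly", {
  set.seed(64)
  ns <- 300; nt <- 400
  src <- cells_from_xy(runif(ns, 0, 1000), runif(ns, 0, 1000), "a",
                       id = seq_len(ns))
  tgt <- cells_from_xy(runif(nt, 0, 1000), runif(nt, 0, 1000), "b",
                       id = ns + seq_len(nt))
  d <- nearest_distances(src, tgt)
  orc <- oracle_nearest(src$centroid_x_um, src$centroid_y_um, src$cell_id,
                        tgt$centroid_x_um, tgt$centroid_y_um, tgt$cell_id)
  expect_equal(d$nearest_distance_um, orc$dist)
  expect_equal(d$nearest_target_id, tgt$cell_id[orc$idx])
})

test_that("proximity is strict at the cutoff", {
  d <- data.frame(nearest_distance_um = c(11.9, 12, 12.1))
  out <- classify_proximity(d, 12)
  expect_equal(out$proximity, c("proximal", "distal", "distal"))
  expect_error(classify_proximity(d, 0), "positive")
})

test_that("group comparison reproduces the exact rank-sum and flags relevance correctly", {
  d <- rbind(cells_dist(c(1, 2, 3), "s1"), cells_dist(c(10, 11, 12), "s2"))
  gm <- c(s1 = "A", s2 = "B")
  out <- compare_groups(d, gm, relevance_um = 8, q_cutoff = 0.1)
  # exact rank-sum by enumeration: all A below all B -> W = 0
  expect_equal(oracle_rank_sum_W(c(1, 2, 3), c(10, 11, 12)), 0)
  expect_lt(out$wilcoxon_p, 0.2)
  expect_equal(out$delta_median_um, -9)
  expect_equal(out$median_a_um, 2)
  expect_equal(out$n_a, 3L)

  # identical groups: p ~ 1 under the corrected normal approximation
  d2 <- rbind(cells_dist(1:20, "s1"), cells_dist(1:20, "s2"))
  out2 <- compare_groups(d2, gm)
  expect_gte(out2$wilcoxon_p, 0.99)
  expect_false(out2$relevant)

  # small median difference is irrelevant even at tiny q
  d3 <- rbind(cells_dist(rnorm(100, 10), "s1"),
              cells_dist(rnorm(100, 15), "s2"))
  out3 <- compare_groups(d3, gm, relevance_um = 8, q_cutoff = 0.1)
  expect_false(out3$relevant)   # |delta| ~ 5 < 8 regardless of q
})

test_that("the Wilcoxon statistic agrees with wilcox.test's tie-corrected approximation", {
  set.seed(65)
  a <- sample(1:30, 40, replace = TRUE)
  b <- sample(5:40, 50, replace = TRUE)
  d <- rbind(cells_dist(a, "s1"), cells_dist(b, "s2"))
  out <- compare_groups(d, c(s1 = "A", s2 = "B"))
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(out$wilcoxon_p, ref$p.value)
})

test_that("permutation p attains its floor when the observation beats every draw", {
  set.seed(66)
  # group A sources on top of targets, group B far away: extreme observed
  mk <- function(sid, near) {
    tx <- runif(10, 0, 200); ty <- runif(10, 0, 200)
    sx <- if (near) tx + 0.5 else tx + 150
    rbind(cells_from_xy(tx, ty, "tgt", sid, id = 1:10),
          cells_from_xy(sx, ty, "src", sid, id = 11:20))
  }
  cells <- rbind(mk("a1", TRUE), mk("b1", FALSE))
  gm <- c(a1 = "A", b1 = "B")
  K <- 99
  res <- permutation_null(cells, gm, "src", "tgt", K = K, seed = 2)
  expect_equal(res$p_two_tailed, 1 / (K + 1))
  expect_equal(length(res$null_deltas), K)
})

test_that("permutation nulls are reproducible under a fixed seed", {
  set.seed(67)
  g <- generate_grouped_samples(n_per_group = 2, shift_um = 0,
                                n_sources = 10, n_targets = 10, n_other = 10,
                                seed = 5)
  r1 <- permutation_null(g$cells, g$group_map, "source", "target",
                         K = 50, seed = 11)
  r2 <- permutation_null(g$cells, g$group_map, "source", "target",
                         K = 50, seed = 11)
  expect_identical(r1$null_deltas, r2$null_deltas)
  expect_identical(r1$p_two_tailed, r2$p_two_tailed)
  expect_true(r1$p_two_tailed > 0 && r1$p_two_tailed <= 1)
})

test_that("medians and rank statistics are invariant under a consistent unit change", {
  set.seed(68)
  g <- generate_grouped_samples(n_per_group = 2, shift_um = 30,
                                n_sources = 10, n_targets = 15, n_other = 5,
                                seed = 9)
  d1 <- nearest_distances(g$cells[g$cells$cell_type == "source", ],
                          g$cells[g$cells$cell_type == "target", ])
  scaled <- g$cells
  scaled$centroid_x_um <- scaled$centroid_x_um * 2
  scaled$centroid_y_um <- scaled$centroid_y_um * 2
  d2 <- nearest_distances(scaled[scaled$cell_type == "source", ],
                          scaled[scaled$cell_type == "target", ])
  expect_equal(d2$nearest_distance_um, 2 * d1$nearest_distance_um)
  c1 <- compare_groups(d1, g$group_map, relevance_um = 8)
  c2 <- compare_groups(d2, g$group_map, relevance_um = 16)
  expect_equal(c2$wilcoxon_p, c1$wilcoxon_p)
  expect_equal(c2$delta_median_um, 2 * c1$delta_median_um)
  expect_equal(c2$relevant, c1$relevant)
})
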