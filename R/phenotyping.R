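#' Overlap rule
#'
#' @param mask_name name of the mask a cell must overlap.
#' @param min_fraction minimum fraction of the cell's area (in `[0, 1]`,
#'   inclusive boundary) that must fall inside the mask.
#' @return A list of class `overlap_rule`.
#' @export
overlap_rule <- function(mask_name, min_fraction) {
  if (!is.numeric(min_fraction) || min_fraction < 0 || min_fraction > 1) {
    stop("min_fraction must be in [0, 1]")
  }
  structure(list(mask_name = as.character(mask_name),
                 min_fraction = min_fraction),
            class = "overlap_rule")
}

# fraction of each cell's pixels inside the mask; denominator is cell area
cell_mask_overlap <- function(labels, mask) {
  lab <- labels$pixels
  m <- mask_px(mask)
  if (!identical(dim(lab), dim(m))) {
    stop("mask and label image dimensions differ")
  }
  n <- labels$n_cells
  if (n == 0L) return(numeric(0))
  inside <- tabulate(lab[m & lab > 0L], nbins = n)
  area <- tabulate(lab[lab > 0L], nbins = n)
  inside / area
}

#' Assign cells to a tissue compartment by mask overlap
#'
#' A cell is assigned to the compartment when the fraction of its pixels
#' inside the mask is at least `min_fraction` (inclusive, e.g. "at least
#' 30%" keeps a 10-pixel cell with exactly 3 pixels inside). Other cells
#' keep their current compartment value.
#'
#' @param cells a `cell_table`.
#' @param labels the [label_image] the table was extracted from.
#' @param rule an [overlap_rule]; `mask_name` becomes the compartment.
#' @param mask the compartment [binary_mask].
#' @return The cell table with `compartment` filled in for assigned cells.
#' @export
assign_compartment <- function(cells, labels, rule, mask) {
  stopifnot(inherits(rule, "overlap_rule"))
  frac <- cell_mask_overlap(labels, mask)
  hit <- frac[cells$cell_id] >= rule$min_fraction
  cells$compartment[hit] <- rule$mask_name
  cells
}

#' Assign cell types by highest qualifying mask overlap
#'
#' For each cell the overlap fraction with every rule's mask is computed;
#' rules whose own `min_fraction` is met are eligible, and the cell takes
#' the type of the eligible rule with the highest fraction. Cells with no
#' eligible rule keep `cell_type = NA`. Exact ties go to the rule listed
#' first; ties are counted and reported in a message.
#'
#' @param cells a `cell_table`.
#' @param labels the matching [label_image].
#' @param rules named list of [overlap_rule]s; names are the cell types.
#' @param masks named list of [binary_mask]s covering every
#'   `rule$mask_name`.
#' @return The cell table with `cell_type` filled in.
#' @export
assign_type_by_highest_overlap <- function(cells, labels, rules, masks) {
  mask_names <- vapply(rules, `[[`, "", "mask_name")
  if (anyDuplicated(mask_names)) {
    stop("configuration error: duplicate mask_name across overlap rules: ",
         paste(unique(mask_names[duplicated(mask_names)]), collapse = ", "))
  }
  type_names <- names(rules)
  if (is.null(type_names) || any(!nzchar(type_names))) {
    type_names <- mask_names
  }
  frac <- vapply(rules, function(r) {
    if (!r$mask_name %in% names(masks)) {
      stop("configuration error: no mask named '", r$mask_name, "'")
    }
    cell_mask_overlap(labels, masks[[r$mask_name]])
  }, numeric(labels$n_cells))
  if (labels$n_cells == 1L) frac <- matrix(frac, nrow = 1L)
  mins <- vapply(rules, `[[`, numeric(1), "min_fraction")
  elig <- sweep(frac, 2L, mins, `>=`)
  score <- frac
  score[!elig] <- -Inf
  n_ties <- 0L
  assigned <- apply(score, 1L, function(s) {
    if (all(s == -Inf)) return(NA_integer_)
    best <- which(s == max(s))
    if (length(best) > 1L) n_ties <<- n_ties + 1L
    best[1L]
  })
  if (n_ties > 0L) {
    message(n_ties, " cell(s) had tied overlap fractions; ",
            "first-listed rule used")
  }
  idx <- assigned[cells$cell_id]
  cells$cell_type <- ifelse(is.na(idx), cells$cell_type, type_names[idx])
  cells
}

#' Gate specification
#'
#' A gate is a boolean expression over mean marker intensities, e.g.
#' `"CD4 >= 0.1"` or `"CD8 >= 0.01 & PD1 >= 0.005"`. Allowed operators:
#' `>`, `>=`, `<`, `<=`, `&`, `|`, `!` and parentheses; atoms are channel
#' names and numeric constants. A gate may be nested inside a parent gate,
#' in which case it is evaluated only on the parent's cells.
#'
#' @param name resulting cell type.
#' @param expression the boolean expression as a string.
#' @param parent_gate optional name of the enclosing gate.
#' @return A list of class `gate_spec`.
#' @export
gate_spec <- function(name, expression, parent_gate = NULL) {
  structure(list(name = as.character(name),
                 expression = as.character(expression),
                 parent_gate = parent_gate),
            class = "gate_spec")
}

parse_bool_expr <- function(text, atom_names, what = "gate") {
  expr <- tryCatch(str2lang(text), error = function(e) {
    stop("parse error in ", what, " expression '", text, "': ",
         conditionMessage(e))
  })
  allowed <- c(">", ">=", "<", "<=", "&", "|", "!", "(")
  check <- function(e) {
    if (is.numeric(e)) return(invisible())
    if (is.name(e)) {
      nm <- as.character(e)
      if (!nm %in% atom_names) {
        stop("unknown name '", nm, "' in ", what, " expression '", text, "'")
      }
      return(invisible())
    }
    if (is.call(e)) {
      op <- as.character(e[[1L]])
      if (!op %in% allowed) {
        stop("operator '", op, "' not allowed in ", what,
             " expression '", text, "'")
      }
      for (i in seq_along(e)[-1L]) check(e[[i]])
      return(invisible())
    }
    stop("invalid token in ", what, " expression '", text, "'")
  }
  check(expr)
  expr
}

#' Gate cells by a boolean marker-threshold expression
#'
#' Evaluates the gate expression on each cell's mean intensities and
#' returns the satisfying subset with `cell_type` set to the gate name.
#' All comparison boundaries follow the expression exactly (`>=` is
#' inclusive). When the gate has a `parent_gate`, pass the parent's
#' already-gated subset as `cells`.
#'
#' @param cells a `cell_table` (or the parent gate's subset).
#' @param gate a [gate_spec].
#' @return The subset of `cells` passing the gate, `cell_type` set.
#' @export
gate_cells <- function(cells, gate) {
  stopifnot(inherits(gate, "gate_spec"))
  atom_names <- names(cells)
  expr <- parse_bool_expr(gate$expression, atom_names)
  hit <- eval(expr, envir = as.data.frame(cells), enclos = baseenv())
  if (!is.logical(hit) || length(hit) != nrow(cells)) {
    stop("gate expression '", gate$expression,
         "' did not evaluate to one logical per cell")
  }
  out <- cells[which(hit), , drop = FALSE]
  out$cell_type <- gate$name
  rownames(out) <- NULL
  out
}

#' Apply a list of gates, honouring parent nesting
#'
#' Gates with a `parent_gate` are evaluated on the parent's subset.
#' Returns the input table with `cell_type` set to the name of the most
#' deeply nested gate each cell passes (later gates in the list overwrite
#' earlier ones on overlap).
#'
#' @param cells a `cell_table`.
#' @param gates list of [gate_spec]s; parents must precede children.
#' @return The cell table with `cell_type` filled for gated cells.
#' @export
apply_gates <- function(cells, gates) {
  subsets <- list()
  out <- cells
  key <- cells$cell_id
  if (!is.null(cells$sample_id)) key <- paste(cells$sample_id, cells$cell_id)
  for (g in gates) {
    base <- if (!is.null(g$parent_gate)) {
      if (is.null(subsets[[g$parent_gate]])) {
        stop("gate '", g$name, "' references parent '", g$parent_gate,
             "' which has not been evaluated yet")
      }
      subsets[[g$parent_gate]]
    } else {
      cells
    }
    sub <- gate_cells(base, g)
    subsets[[g$name]] <- sub
    sub_key <- sub$cell_id
    if (!is.null(sub$sample_id)) sub_key <- paste(sub$sample_id, sub$cell_id)
    out$cell_type[key %in% sub_key] <- g$name
  }
  out
}

#' Clustering parameters
#'
#' @param markers channel names used as clustering features.
#' @param scale z-score each marker before PCA (constant markers are
#'   dropped with a warning); default `TRUE`.
#' @param n_pcs number of principal components (capped at the number of
#'   markers).
#' @param k_neighbours neighbours per cell in the kNN graph; default 20.
#' @param resolution Louvain modularity resolution (> 0).
#' @param seed RNG seed controlling the Louvain run.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(markers, scale = TRUE, n_pcs = 10L,
                           k_neighbours = 20L, resolution = 0.8,
                           seed = 1L) {
  if (n_pcs < 1L) stop("n_pcs must be >= 1")
  if (n_pcs > length(markers)) stop("n_pcs cannot exceed number of markers")
  if (k_neighbours < 2L) stop("k_neighbours must be >= 2")
  if (resolution <= 0) stop("resolution must be positive")
  structure(list(markers = markers, scale = isTRUE(scale),
                 n_pcs = as.integer(n_pcs),
                 k_neighbours = as.integer(k_neighbours),
                 resolution = resolution, seed = as.integer(seed)),
            class = "cluster_params")
}

# PCA scores with a deterministic sign convention: each component is
# flipped so its largest-magnitude loading is positive
pca_scores <- function(X, n_pcs) {
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(p$rotation))
  rot <- p$rotation[, seq_len(n_pcs), drop = FALSE]
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  sweep(p$x[, seq_len(n_pcs), drop = FALSE], 2L, flip, `*`)
}

cluster_feature_matrix <- function(cells, params) {
  miss <- setdiff(params$markers, names(cells))
  if (length(miss)) {
    stop("marker(s) absent from the cell table: ",
         paste(miss, collapse = ", "))
  }
  X <- as.matrix(as.data.frame(cells)[, params$markers, drop = FALSE])
  if (params$scale) {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0)) {
      warning("constant marker(s) dropped from clustering: ",
              paste(colnames(X)[sds == 0], collapse = ", "))
      X <- X[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
      if (ncol(X) == 0L) stop("no non-constant markers left for clustering")
    }
    X <- scale(X)
  }
  X
}

#' Cluster cells on marker expression
#'
#' Cells are optionally z-scored per marker, projected onto principal
#' components, connected in a k-nearest-neighbour graph (undirected: an
#' edge joins two cells if either lists the other among its `k` nearest
#' in PC space, all edge weights 1), and partitioned with the Louvain
#' modularity algorithm at the requested resolution. Cluster ids are
#' renumbered `1..K` by descending cluster size.
#'
#' @param cells a `cell_table` with at least `k_neighbours + 1` rows.
#' @param params a [cluster_params].
#' @return A list with `cells` (input table with `cluster_id` filled) and
#'   `profiles` (per-cluster size and mean raw intensity of each marker).
#' @export
cluster_cells <- function(cells, params) {
  stopifnot(inherits(params, "cluster_params"))
  n <- nrow(cells)
  if (n < params$k_neighbours + 1L) {
    stop("need at least k_neighbours + 1 cells (",
         params$k_neighbours + 1L, "), got ", n)
  }
  raw <- as.matrix(as.data.frame(cells)[, intersect(params$markers,
                                                    names(cells)),
                                        drop = FALSE])
  if (nrow(unique(raw)) == 1L) {
    # all cells identical: single cluster, no graph needed
    cells$cluster_id <- 1L
    return(list(cells = cells,
                profiles = cluster_profiles(cells, params$markers)))
  }
  X <- cluster_feature_matrix(cells, params)
  S <- pca_scores(X, params$n_pcs)
  D <- as.matrix(stats::dist(S))
  diag(D) <- Inf
  k <- params$k_neighbours
  nn <- apply(D, 1L, function(d) order(d)[seq_len(k)])
  edges <- cbind(rep(seq_len(n), each = k), as.vector(nn))
  edges <- t(apply(edges, 1L, sort))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  set.seed(params$seed)
  cl <- igraph::cluster_louvain(g, resolution = params$resolution)
  memb <- igraph::membership(cl)
  sizes <- table(memb)
  new_id <- rank(-as.vector(sizes), ties.method = "first")
  cells$cluster_id <- as.integer(new_id[match(memb, names(sizes))])
  list(cells = cells, profiles = cluster_profiles(cells, params$markers))
}

cluster_profiles <- function(cells, markers) {
  ids <- sort(unique(cells$cluster_id))
  prof <- data.frame(cluster_id = ids,
                     n_cells = as.vector(table(cells$cluster_id)[as.character(ids)]))
  for (m in markers) {
    prof[[m]] <- vapply(ids, function(i) {
      mean(cells[[m]][cells$cluster_id == i])
    }, numeric(1))
  }
  prof
}

#' Deterministic 2-D embedding of cells for reporting
#'
#' Projects the (optionally z-scored) marker matrix onto its first two
#' principal components with a fixed sign convention. The embedding is
#' fully deterministic and intended only for visual reporting of cluster
#' structure.
#'
#' @param cells a `cell_table`.
#' @param params a [cluster_params].
#' @return A data frame with `cell_id`, `dim1`, `dim2` (one row per cell).
#' @export
embed_2d <- function(cells, params) {
  X <- cluster_feature_matrix(cells, params)
  S <- pca_scores(X, 2L)
  if (ncol(S) < 2L) S <- cbind(S, 0)
  data.frame(cell_id = cells$cell_id, dim1 = S[, 1L], dim2 = S[, 2L])
}
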