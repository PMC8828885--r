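#' Validate a run configuration file
#'
#' Parses a YAML configuration and cross-checks every reference: sample
#' image files must exist, mask-recipe sources must be channels or
#' previously defined masks, the segmentation membrane mask and the
#' overlap-typing masks must be defined, gate expressions must parse and
#' reference known channels, clustering markers must be channels, and
#' pixel-area expressions must reference defined masks. The first dangling
#' reference raises an error naming it.
#'
#' Configuration sections (all optional except `samples`, `channels` and
#' `output_dir`): `normalisation` (`percentile`, `scope`), `masks` (list
#' of recipes: `name`, `source`, `steps`), `segmentation`
#' (`nucleus_channel`, `nucleus_threshold`, `min_diameter_px`,
#' `max_diameter_px`, `expansion`, `expansion_px`, `membrane_mask`),
#' `compartment` (`mask`, `min_fraction`, `filter`), `cell_types`
#' (overlap rules: `name`, `mask`, `min_fraction`), `gates` (`name`,
#' `expression`, `parent_gate`), `clustering` (`markers`, `n_pcs`,
#' `k_neighbours`, `resolution`, `scale`), `spatial` (`homotypic`:
#' per-type DBSCAN specs; `heterotypic`: `comparisons`, `cutoff_um`,
#' `relevance_um`, `q_cutoff`, `permutations`), `pixel_area` (list of
#' `numerator` / `denominator`). Each sample row carries `sample_id`,
#' optional `group`, and one of `images` (TIFF path list), `imc_text`
#' (ablation file), or externally produced `label_image` / `cell_table`
#' paths to skip upstream stages.
#'
#' @param path YAML file path.
#' @param check_files verify that referenced input files exist
#'   (default `TRUE`).
#' @return A validated configuration object of class `run_config`.
#' @export
validate_config <- function(path, check_files = TRUE) {
  cfg <- yaml::read_yaml(path)
  for (field in c("samples", "channels", "output_dir")) {
    if (is.null(cfg[[field]])) {
      stop("configuration error: missing required field '", field, "'")
    }
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  cfg$channels <- resolve(cfg$channels)
  if (check_files && !file.exists(cfg$channels)) {
    stop("configuration error: channel metadata file not found: ",
         cfg$channels)
  }
  channels <- read_channel_metadata(cfg$channels)
  chan_names <- channels$channel_name

  for (i in seq_along(cfg$samples)) {
    s <- cfg$samples[[i]]
    if (is.null(s$sample_id)) {
      stop("configuration error: sample ", i, " has no sample_id")
    }
    for (fld in c("imc_text", "label_image", "cell_table")) {
      cfg$samples[[i]][[fld]] <- resolve(s[[fld]])
    }
    if (!is.null(s$images)) {
      cfg$samples[[i]]$images <- vapply(s$images, resolve, character(1))
    }
    if (check_files) {
      fs <- c(cfg$samples[[i]]$images, cfg$samples[[i]]$imc_text,
              cfg$samples[[i]]$label_image, cfg$samples[[i]]$cell_table)
      missing <- fs[!file.exists(fs)]
      if (length(missing)) {
        stop("configuration error: sample '", s$sample_id,
             "' input file not found: ", missing[1L])
      }
    }
  }
  sample_ids <- vapply(cfg$samples, `[[`, "", "sample_id")
  if (anyDuplicated(sample_ids)) {
    stop("configuration error: duplicate sample_id")
  }

  mask_names <- character(0)
  for (m in cfg$masks) {
    if (is.null(m$name) || is.null(m$source) || is.null(m$steps)) {
      stop("configuration error: each mask recipe needs name, source, steps")
    }
    for (src in m$source) {
      if (!src %in% chan_names && !src %in% mask_names) {
        stop("configuration error: mask '", m$name,
             "' references undefined source '", src, "'")
      }
    }
    for (st in m$steps) {
      if (is.list(st) && !is.null(st$mask) && !st$mask %in% mask_names) {
        stop("configuration error: mask '", m$name,
             "' references undefined mask operand '", st$mask, "'")
      }
      if (is.list(st) && !is.null(st$masks)) {
        bad <- setdiff(unlist(st$masks), mask_names)
        if (length(bad)) {
          stop("configuration error: mask '", m$name,
               "' references undefined mask operand '", bad[1L], "'")
        }
      }
    }
    mask_names <- c(mask_names, m$name)
  }

  if (!is.null(cfg$segmentation)) {
    sg <- cfg$segmentation
    if (is.null(sg$nucleus_channel) ||
        !sg$nucleus_channel %in% chan_names) {
      stop("configuration error: segmentation nucleus_channel '",
           sg$nucleus_channel, "' is not a channel")
    }
    if (!is.null(sg$membrane_mask) && !sg$membrane_mask %in% mask_names) {
      stop("configuration error: segmentation membrane_mask '",
           sg$membrane_mask, "' is not a defined mask")
    }
  }
  if (!is.null(cfg$compartment) &&
      !cfg$compartment$mask %in% mask_names) {
    stop("configuration error: compartment mask '", cfg$compartment$mask,
         "' is not a defined mask")
  }
  for (ct in cfg$cell_types) {
    if (!ct$mask %in% mask_names) {
      stop("configuration error: cell type '", ct$name,
           "' references undefined mask '", ct$mask, "'")
    }
  }
  gate_names <- character(0)
  for (g in cfg$gates) {
    tryCatch(parse_bool_expr(g$expression, chan_names, what = "gate"),
             error = function(e) {
               stop("configuration error in gate '", g$name, "': ",
                    conditionMessage(e), call. = FALSE)
             })
    if (!is.null(g$parent_gate) && !g$parent_gate %in% gate_names) {
      stop("configuration error: gate '", g$name,
           "' references undefined parent gate '", g$parent_gate, "'")
    }
    gate_names <- c(gate_names, g$name)
  }
  if (!is.null(cfg$clustering)) {
    bad <- setdiff(unlist(cfg$clustering$markers), chan_names)
    if (length(bad)) {
      stop("configuration error: clustering marker '", bad[1L],
           "' is not a channel")
    }
  }
  for (pa in cfg$pixel_area) {
    tryCatch(parse_bool_expr(pa$numerator, mask_names, what = "pixel-area"),
             error = function(e) {
               stop("configuration error in pixel_area numerator '",
                    pa$numerator, "': ", conditionMessage(e), call. = FALSE)
             })
    den <- if (is.null(pa$denominator)) "image" else pa$denominator
    if (!identical(den, "image") && !den %in% mask_names) {
      stop("configuration error: pixel_area denominator '", den,
           "' is not a defined mask")
    }
  }
  cfg$channel_table <- channels
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$pixel_size_um <- if (is.null(cfg$pixel_size_um)) 1 else cfg$pixel_size_um
  structure(cfg, class = "run_config")
}

run_stages_all <- c("extract", "normalise", "mask", "segment",
                    "phenotype", "cluster", "spatial", "pixel")

out_path <- function(cfg, ...) file.path(cfg$output_dir, ...)

need_file <- function(path, stage) {
  if (!file.exists(path)) {
    stop("missing upstream artefact for stage '", stage,
         "': expected file ", path)
  }
  path
}

# load the (normalised, if produced) stack of one sample, preferring the
# stage handoff on disk, falling back to the raw config inputs
load_sample_stack <- function(cfg, s, stage) {
  norm_dir <- out_path(cfg, "normalised")
  safe <- gsub("[^A-Za-z0-9_.-]", "_", cfg$channel_table$channel_name)
  norm_files <- file.path(norm_dir, paste0(s$sample_id, "_", safe, ".tiff"))
  if (all(file.exists(norm_files))) {
    return(read_stack(norm_files, cfg$channel_table,
                      pixel_size_um = cfg$pixel_size_um,
                      sample_id = s$sample_id, normalised = TRUE))
  }
  load_raw_stack(cfg, s, stage)
}

load_raw_stack <- function(cfg, s, stage) {
  if (!is.null(s$imc_text)) {
    parse_imc_text(need_file(s$imc_text, stage), cfg$channel_table,
                   pixel_size_um = cfg$pixel_size_um,
                   sample_id = s$sample_id)
  } else if (!is.null(s$images)) {
    for (f in s$images) need_file(f, stage)
    read_stack(s$images, cfg$channel_table,
               pixel_size_um = cfg$pixel_size_um, sample_id = s$sample_id)
  } else {
    stop("sample '", s$sample_id, "' has neither images nor imc_text input")
  }
}

load_sample_masks <- function(cfg, s, stage) {
  masks <- list()
  for (m in cfg$masks) {
    f <- need_file(out_path(cfg, "masks",
                            paste0(s$sample_id, "_", m$name, ".tiff")),
                   stage)
    masks[[m$name]] <- read_mask(f, name = m$name)
  }
  masks
}

config_recipes <- function(cfg) {
  lapply(cfg$masks, function(m) {
    mask_recipe(m$name, unlist(m$source), m$steps)
  })
}

config_seg_params <- function(cfg) {
  sg <- cfg$segmentation
  segmentation_params(
    nucleus_channel = sg$nucleus_channel,
    nucleus_threshold = if (is.null(sg$nucleus_threshold)) "otsu"
                        else sg$nucleus_threshold,
    min_diameter_px = if (is.null(sg$min_diameter_px)) 4
                      else sg$min_diameter_px,
    max_diameter_px = if (is.null(sg$max_diameter_px)) 60
                      else sg$max_diameter_px,
    expansion = if (is.null(sg$expansion)) "isotropic" else sg$expansion,
    expansion_px = if (is.null(sg$expansion_px)) 10 else sg$expansion_px)
}

#' Run the analysis workflow
#'
#' Executes the requested stages for every sample, reading each stage's
#' inputs from the previous stage's on-disk outputs (so any prefix of
#' stages can be run first and the rest resumed later, and externally
#' produced inputs — label images, cell tables — can substitute for
#' skipped stages). Re-running with an identical configuration and seed
#' reproduces identical CSV outputs.
#'
#' Stage outputs under `output_dir`: `normalised/` (per-channel float
#' TIFFs), `masks/` (8-bit mask TIFFs), `cells/` (label TIFFs,
#' `*_cells.csv`, `*_cells_typed.csv`, `all_cells.csv`), `cluster/`
#' (`cluster_profiles.csv`), `spatial/` (homotypic labels, distance
#' tables, group comparisons, permutation summaries), `pixel/`
#' (`pixel_areas.csv`), and `run_log.yaml` (versions, seed, parameters).
#'
#' @param config a validated `run_config` (or a path to one).
#' @param stages character vector of stages to execute, a subset of
#'   `c("extract", "normalise", "mask", "segment", "phenotype",
#'   "cluster", "spatial", "pixel")`; default all applicable.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config, stages = run_stages_all) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(stages, run_stages_all)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- intersect(run_stages_all, stages)   # canonical order
  cfg <- config
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  if ("extract" %in% stages) {
    dir.create(out_path(cfg, "extracted"), showWarnings = FALSE)
    for (s in cfg$samples) {
      if (is.null(s$imc_text)) next
      stack <- parse_imc_text(s$imc_text, cfg$channel_table,
                              pixel_size_um = cfg$pixel_size_um,
                              sample_id = s$sample_id)
      write_channels(stack, out_path(cfg, "extracted"), overwrite = TRUE)
    }
  }

  if ("normalise" %in% stages && !is.null(cfg$normalisation)) {
    np <- normalisation_params(
      percentile = if (is.null(cfg$normalisation$percentile)) 99
                   else cfg$normalisation$percentile,
      scope = if (is.null(cfg$normalisation$scope)) "per_image"
              else cfg$normalisation$scope)
    dir.create(out_path(cfg, "normalised"), showWarnings = FALSE)
    if (np$scope == "pooled_across_samples") {
      stacks <- lapply(cfg$samples, load_raw_stack, cfg = cfg,
                       stage = "normalise")
      stacks <- normalise_percentile(stacks, np)
      if (inherits(stacks, "channel_stack")) stacks <- list(stacks)
      for (st in stacks) {
        write_channels(st, out_path(cfg, "normalised"), overwrite = TRUE)
      }
    } else {
      for (s in cfg$samples) {
        st <- normalise_percentile(load_raw_stack(cfg, s, "normalise"), np)
        write_channels(st, out_path(cfg, "normalised"), overwrite = TRUE)
      }
    }
  }

  if ("mask" %in% stages && length(cfg$masks)) {
    dir.create(out_path(cfg, "masks"), showWarnings = FALSE)
    recipes <- config_recipes(cfg)
    for (s in cfg$samples) {
      stack <- load_sample_stack(cfg, s, "mask")
      masks <- list()
      for (r in recipes) {
        masks[[r$name]] <- run_mask_recipe(stack, r, masks)
        write_mask(masks[[r$name]],
                   out_path(cfg, "masks",
                            paste0(s$sample_id, "_", r$name, ".tiff")))
      }
    }
  }

  if ("segment" %in% stages && !is.null(cfg$segmentation)) {
    dir.create(out_path(cfg, "cells"), showWarnings = FALSE)
    params <- config_seg_params(cfg)
    for (s in cfg$samples) {
      stack <- load_sample_stack(cfg, s, "segment")
      labels <- if (!is.null(s$label_image)) {
        read_labels(need_file(s$label_image, "segment"))
      } else {
        nuclei <- detect_nuclei(stack, params)
        membrane <- NULL
        if (!is.null(cfg$segmentation$membrane_mask)) {
          membrane <- load_sample_masks(cfg, s,
                                        "segment")[[cfg$segmentation$membrane_mask]]
        }
        expand_cells(nuclei, params, membrane)
      }
      write_labels(labels, out_path(cfg, "cells",
                                    paste0(s$sample_id, "_labels.tiff")))
      cells <- extract_features(labels, stack)
      write_cell_table(cells, out_path(cfg, "cells",
                                       paste0(s$sample_id, "_cells.csv")))
    }
  }

  if ("phenotype" %in% stages) {
    dir.create(out_path(cfg, "cells"), showWarnings = FALSE)
    for (s in cfg$samples) {
      cells <- if (!is.null(s$cell_table)) {
        read_cell_table(need_file(s$cell_table, "phenotype"))
      } else {
        read_cell_table(need_file(out_path(cfg, "cells",
                                           paste0(s$sample_id, "_cells.csv")),
                                  "phenotype"))
      }
      needs_masks <- !is.null(cfg$compartment) || length(cfg$cell_types)
      if (needs_masks) {
        labels <- read_labels(need_file(
          out_path(cfg, "cells", paste0(s$sample_id, "_labels.tiff")),
          "phenotype"))
        masks <- load_sample_masks(cfg, s, "phenotype")
        if (!is.null(cfg$compartment)) {
          rule <- overlap_rule(cfg$compartment$mask,
                               cfg$compartment$min_fraction)
          cells <- assign_compartment(cells, labels, rule,
                                      masks[[cfg$compartment$mask]])
          if (isTRUE(cfg$compartment$filter)) {
            cells <- cells[!is.na(cells$compartment), , drop = FALSE]
          }
        }
        if (length(cfg$cell_types)) {
          rules <- stats::setNames(
            lapply(cfg$cell_types, function(ct) {
              overlap_rule(ct$mask, ct$min_fraction)
            }),
            vapply(cfg$cell_types, `[[`, "", "name"))
          cells <- assign_type_by_highest_overlap(cells, labels, rules, masks)
        }
      }
      if (length(cfg$gates)) {
        gates <- lapply(cfg$gates, function(g) {
          gate_spec(g$name, g$expression, g$parent_gate)
        })
        cells <- apply_gates(cells, gates)
      }
      write_cell_table(cells,
                       out_path(cfg, "cells",
                                paste0(s$sample_id, "_cells_typed.csv")))
    }
  }

  combined_cells <- function(stage) {
    tabs <- lapply(cfg$samples, function(s) {
      typed <- out_path(cfg, "cells",
                        paste0(s$sample_id, "_cells_typed.csv"))
      plain <- out_path(cfg, "cells", paste0(s$sample_id, "_cells.csv"))
      f <- if (file.exists(typed)) typed
           else if (!is.null(s$cell_table)) s$cell_table
           else plain
      read_cell_table(need_file(f, stage))
    })
    do.call(rbind, tabs)
  }

  if ("cluster" %in% stages && !is.null(cfg$clustering)) {
    dir.create(out_path(cfg, "cluster"), showWarnings = FALSE)
    cells <- combined_cells("cluster")
    cl <- cfg$clustering
    params <- cluster_params(
      markers = unlist(cl$markers),
      scale = if (is.null(cl$scale)) TRUE else cl$scale,
      n_pcs = if (is.null(cl$n_pcs)) min(10L, length(unlist(cl$markers)))
              else cl$n_pcs,
      k_neighbours = if (is.null(cl$k_neighbours)) 20L else cl$k_neighbours,
      resolution = if (is.null(cl$resolution)) 0.8 else cl$resolution,
      seed = cfg$seed)
    res <- cluster_cells(cells, params)
    write_cell_table(res$cells, out_path(cfg, "cells", "all_cells.csv"))
    utils::write.csv(res$profiles,
                     out_path(cfg, "cluster", "cluster_profiles.csv"),
                     row.names = FALSE)
  }

  if ("spatial" %in% stages && !is.null(cfg$spatial)) {
    dir.create(out_path(cfg, "spatial"), showWarnings = FALSE)
    all_file <- out_path(cfg, "cells", "all_cells.csv")
    cells <- if (file.exists(all_file)) read_cell_table(all_file)
             else combined_cells("spatial")
    for (hs in cfg$spatial$homotypic) {
      params <- homotypic_params(
        min_points = if (is.null(hs$min_points)) 5L else hs$min_points,
        density_per_mm2 = hs$density_per_mm2, eps_um = hs$eps_um)
      rows <- lapply(unique(cells$sample_id), function(sid) {
        sub <- cells[cells$sample_id == sid &
                     !is.na(cells$cell_type) &
                     cells$cell_type == hs$cell_type, , drop = FALSE]
        if (nrow(sub) == 0L) return(NULL)
        data.frame(sample_id = sid, cell_id = sub$cell_id,
                   cell_type = hs$cell_type,
                   homotypic_cluster = homotypic_clusters(sub, params),
                   stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, rows)
      utils::write.csv(out,
                       out_path(cfg, "spatial",
                                paste0("homotypic_", hs$cell_type, ".csv")),
                       row.names = FALSE)
    }
    het <- cfg$spatial$heterotypic
    if (!is.null(het)) {
      comparisons <- do.call(rbind, lapply(het$comparisons, function(cp) {
        data.frame(source_type = cp$source_type,
                   target_type = cp$target_type, stringsAsFactors = FALSE)
      }))
      dist_all <- do.call(rbind, lapply(seq_len(nrow(comparisons)),
                                        function(i) {
        src <- cells[!is.na(cells$cell_type) &
                     cells$cell_type == comparisons$source_type[i], ,
                     drop = FALSE]
        tgt <- cells[!is.na(cells$cell_type) &
                     cells$cell_type == comparisons$target_type[i], ,
                     drop = FALSE]
        nearest_distances(src, tgt, comparisons$source_type[i],
                          comparisons$target_type[i])
      }))
      if (!is.null(het$cutoff_um)) {
        dist_all <- classify_proximity(dist_all, het$cutoff_um)
      }
      utils::write.csv(dist_all,
                       out_path(cfg, "spatial", "nearest_distances.csv"),
                       row.names = FALSE)
      groups <- vapply(cfg$samples, function(s) {
        if (is.null(s$group)) NA_character_ else s$group
      }, character(1))
      names(groups) <- vapply(cfg$samples, `[[`, "", "sample_id")
      if (length(unique(stats::na.omit(groups))) == 2L) {
        cmp <- compare_groups(
          dist_all, groups, comparisons,
          relevance_um = if (is.null(het$relevance_um)) 8
                         else het$relevance_um,
          q_cutoff = if (is.null(het$q_cutoff)) 0.1 else het$q_cutoff)
        if (!is.null(cmp)) {
          utils::write.csv(cmp,
                           out_path(cfg, "spatial",
                                    "group_comparisons.csv"),
                           row.names = FALSE)
        }
        if (!is.null(het$permutations) && het$permutations > 0) {
          perms <- permutation_tests(cells, groups, comparisons,
                                     K = het$permutations,
                                     seed = cfg$seed)
          psum <- do.call(rbind, lapply(perms, function(p) {
            data.frame(source_type = p$source_type,
                       target_type = p$target_type,
                       observed_delta_um = p$observed_delta_um,
                       n_permutations = p$n_permutations,
                       p_two_tailed = p$p_two_tailed,
                       fdr_q = p$fdr_q, seed = p$seed,
                       stringsAsFactors = FALSE)
          }))
          utils::write.csv(psum,
                           out_path(cfg, "spatial",
                                    "permutation_tests.csv"),
                           row.names = FALSE)
        }
      }
    }
  }

  if ("pixel" %in% stages && length(cfg$pixel_area)) {
    dir.create(out_path(cfg, "pixel"), showWarnings = FALSE)
    rows <- list()
    for (s in cfg$samples) {
      masks <- load_sample_masks(cfg, s, "pixel")
      for (pa in cfg$pixel_area) {
        den <- if (is.null(pa$denominator)) "image" else pa$denominator
        rows[[length(rows) + 1L]] <-
          positive_area(masks, pa$numerator, den, sample_id = s$sample_id)
      }
    }
    utils::write.csv(do.call(rbind, rows),
                     out_path(cfg, "pixel", "pixel_areas.csv"),
                     row.names = FALSE)
  }

  log <- list(package = "pixcell",
              version = as.character(utils::packageVersion("pixcell")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              seed = cfg$seed,
              stages = stages,
              n_samples = length(cfg$samples),
              pixel_size_um = cfg$pixel_size_um)
  yaml::write_yaml(log, out_path(cfg, "run_log.yaml"))
  invisible(cfg$output_dir)
}
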