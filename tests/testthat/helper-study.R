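# builds a small two-sample study on disk and returns the config path
setup_study <- function(root, groups = c("A", "B"), extra = list()) {
  input <- file.path(root, "input")
  dir.create(input, recursive = TRUE, showWarnings = FALSE)
  chans <- channel_metadata(c("DNA1", "CD3", "IgA"),
                            role = c("nucleus", "marker", "marker"))
  write_channel_metadata(chans, file.path(input, "channels.csv"))
  samples <- list()
  for (i in 1:2) {
    sp <- tissue_spec(
      c(80, 80), channels = chans,
      cell_types = list(
        list(name = "T", count = 6, radius_px = 4, nucleus_radius_px = 2,
             expression = list(DNA1 = 1, CD3 = 0.8, IgA = 0.02),
             expression_sd = 0.02),
        list(name = "IgA_cell", count = 6, radius_px = 4,
             nucleus_radius_px = 2,
             expression = list(DNA1 = 1, CD3 = 0.02, IgA = 0.9),
             expression_sd = 0.02)),
      noise_sd = 0.01, seed = 100 + i)
    out <- generate_tissue(sp)
    out$stack$sample_id <- paste0("s", i)
    files <- write_channels(out$stack, input, overwrite = TRUE)
    samples[[i]] <- list(sample_id = paste0("s", i),
                         group = groups[i],
                         images = as.list(files[1:3]))
  }
  cfg <- c(list(
    output_dir = file.path(root, "out"),
    seed = 7,
    pixel_size_um = 1,
    channels = file.path(input, "channels.csv"),
    samples = samples,
    normalisation = list(percentile = 99, scope = "per_image"),
    masks = list(
      list(name = "CD3_mask", source = "CD3",
           steps = list(list(op = "threshold_otsu"))),
      list(name = "IgA_mask", source = "IgA",
           steps = list(list(op = "threshold_otsu")))),
    segmentation = list(nucleus_channel = "DNA1",
                        nucleus_threshold = "otsu",
                        min_diameter_px = 2, max_diameter_px = 20,
                        expansion = "isotropic", expansion_px = 3),
    cell_types = list(
      list(name = "T", mask = "CD3_mask", min_fraction = 0.15),
      list(name = "IgA_cell", mask = "IgA_mask", min_fraction = 0.15)),
    clustering = list(markers = list("CD3", "IgA"), n_pcs = 2,
                      k_neighbours = 6, resolution = 0.8),
    spatial = list(
      homotypic = list(list(cell_type = "T", min_points = 3, eps_um = 60)),
      heterotypic = list(
        comparisons = list(list(source_type = "T",
                                target_type = "IgA_cell")),
        cutoff_um = 12, relevance_um = 8, q_cutoff = 0.1,
        permutations = 25)),
    pixel_area = list(
      list(numerator = "IgA_mask", denominator = "image"),
      list(numerator = "IgA_mask & CD3_mask", denominator = "CD3_mask"))),
    extra)
  path <- file.path(root, "config.yaml")
  yaml::write_yaml(cfg, path)
  path
}

csv_bytes <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", recursive = TRUE))
  setNames(lapply(files, function(f) {
    readBin(file.path(dir, f), "raw", file.size(file.path(dir, f)))
  }), files)
}

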