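#' Reference synthetic class specifications
#'
#' Five fibrous-texture classes used throughout the package's examples,
#' tests and acceptance runs: three amyloid-fiber-like classes (`APO`
#' broad-width, `BLG` and `LYS` a deliberately similar pair differing only
#' modestly in width and contrast — the hardest pair, mirroring the
#' morphological closeness of those two fibril types), a fine dense
#' polysaccharide network (`PHY`) and a coarse bundled one (`PHY_coarse`).
#'
#' @param image_shape image size for every class (default 1024 x 1024).
#' @return named list of five [fiber_spec()]s.
#' @export
demo_class_specs <- function(image_shape = c(1024L, 1024L)) {
  list(
    APO = fiber_spec(
      n_fibers = 40,
      width_modes = data.frame(mean = c(7, 17), sd = c(1.5, 3), weight = c(0.6, 0.4)),
      curvature = 150, fiber_intensity = 0.85, background_intensity = 0.12,
      texture = list(noise_sd = 0.08, corr_len = 2), image_shape = image_shape,
      name = "APO"),
    BLG = fiber_spec(
      n_fibers = 35,
      width_modes = data.frame(mean = 15, sd = 2, weight = 1),
      curvature = 200, fiber_intensity = 0.80, background_intensity = 0.12,
      texture = list(noise_sd = 0.08, corr_len = 3), image_shape = image_shape,
      name = "BLG"),
    LYS = fiber_spec(
      n_fibers = 35,
      width_modes = data.frame(mean = 13, sd = 2, weight = 1),
      curvature = 200, fiber_intensity = 0.75, background_intensity = 0.12,
      texture = list(noise_sd = 0.08, corr_len = 3), image_shape = image_shape,
      name = "LYS"),
    PHY = fiber_spec(
      n_fibers = 110,
      width_modes = data.frame(mean = 5, sd = 1, weight = 1),
      curvature = 60, fiber_intensity = 0.55, background_intensity = 0.10,
      texture = list(noise_sd = 0.06, corr_len = 1.2), image_shape = image_shape,
      name = "PHY"),
    PHY_coarse = fiber_spec(
      n_fibers = 16,
      width_modes = data.frame(mean = 25, sd = 3, weight = 1),
      curvature = 400, fiber_intensity = 0.68, background_intensity = 0.14,
      texture = list(noise_sd = 0.10, corr_len = 6), image_shape = image_shape,
      name = "PHY_coarse")
  )
}

#' Run the full width + composition pipeline on an image
#'
#' Executes segment -> distance transform -> skeletonize -> refine ->
#' local width -> cluster for one image, and (when a model is supplied)
#' classify -> composition map. All intermediates are returned; writing is
#' handled by [run_pipeline()].
#'
#' @param image a [grayscale_image].
#' @param threshold `"otsu"` or a fixed numeric threshold.
#' @param k width clusters (default 3).
#' @param spur_length spur pruning length (default 5).
#' @param convention width convention, see [measure_local_width()].
#' @param model optional `classifier_model`.
#' @param map_patch crop size for the composition map (default 224).
#' @param map_stride crop stride for the composition map.
#' @return list of stage outputs.
#' @export
analyze_image <- function(image, threshold = "otsu", k = 3L, spur_length = 5L,
                          convention = "2d-1", model = NULL,
                          map_patch = 224L, map_stride = 112L) {
  mask <- if (identical(threshold, "otsu")) segment_fibers(image, "otsu")
          else segment_fibers(image, "fixed", threshold = threshold)
  dist <- distance_transform(mask)
  skel <- skeletonize(mask)
  refined <- refine_centerline(skel, spur_length = spur_length, mask = mask)
  widths <- measure_local_width(dist, refined,
                                pixel_size = pixel_size_of(image),
                                convention = convention)
  clusters <- tryCatch(cluster_widths(widths, k = k), error = function(e) NULL)
  out <- list(mask = mask, dist = dist, centerline = refined, widths = widths,
              clusters = clusters,
              histogram = if (nrow(widths)) width_histogram(widths) else NULL)
  if (!is.null(model)) {
    out$class_map <- classify_image(model, image, patch_size = map_patch,
                                    stride = map_stride)
    out$rendered <- render_class_map(image, out$class_map)
  }
  out
}

# small polynomial rolling hash of the serialized config (provenance tag)
fnv1a_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, ascii = TRUE))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Validate a run configuration
#'
#' @param config list (or YAML path) with fields `images` (list of entries
#'   with `path` and optional `pixel_size`, `region`), `out_dir`, `seed`,
#'   and optional `width` (threshold, k, spur, convention) and `classifier`
#'   (model path, stride) blocks.
#' @return validated `run_config` list.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$images) || !length(config$images))
    stop("config must list at least one image")
  for (im in config$images) {
    if (is.null(im$path)) stop("every image entry needs a `path`")
    if (!file.exists(im$path)) stop("image file not found: ", im$path)
  }
  if (is.null(config$out_dir)) stop("config needs `out_dir`")
  config$seed <- as.integer(config$seed %||% 1L)
  w <- config$width %||% list()
  config$width <- list(threshold = w$threshold %||% "otsu",
                       k = as.integer(w$k %||% 3L),
                       spur = as.integer(w$spur %||% 5L),
                       convention = w$convention %||% "2d-1")
  cl <- config$classifier %||% list()
  if (!is.null(cl$model) && !file.exists(cl$model))
    stop("classifier model not found: ", cl$model)
  config$classifier <- cl
  structure(config, class = "run_config")
}

#' Run the pipeline over a configured set of micrographs
#'
#' For each image: width pipeline tables (width map, histogram, cluster
#' stats) and overlays; optionally a composition map from a saved
#' classifier. Writes a JSON report tying every number to the config hash
#' and seed. A stage failure stops the run naming the stage and image;
#' partial outputs are kept next to a `FAILED_<image>` marker.
#'
#' @param config a [run_config()] (or list / YAML path accepted by it).
#' @return the report list, invisibly; also written as `report.json`.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- if (!is.null(config$classifier$model))
    load_classifier(config$classifier$model) else NULL
  cfg_hash <- fnv1a_hash(unclass(config))
  report <- list(provenance = list(
    package = "fibrilmap",
    version = as.character(utils::packageVersion("fibrilmap")),
    seed = config$seed, config_hash = cfg_hash,
    width_params = config$width))
  summaries <- list()
  for (im in config$images) {
    id <- tools::file_path_sans_ext(basename(im$path))
    stage <- "read_image"
    res <- tryCatch({
      img <- read_image(im$path, pixel_size = im$pixel_size)
      stage <- "width_pipeline"
      thr <- config$width$threshold
      if (!identical(thr, "otsu")) thr <- as.numeric(thr)
      an <- analyze_image(img, threshold = thr, k = config$width$k,
                          spur_length = config$width$spur,
                          convention = config$width$convention,
                          model = model,
                          map_patch = as.integer(config$classifier$patch_size %||% 224L),
                          map_stride = as.integer(config$classifier$stride %||% 112L))
      stage <- "write_outputs"
      wm <- an$widths
      wm$cluster <- if (!is.null(an$clusters)) as.character(an$clusters$labels) else NA
      write_fm_table(wm, file.path(config$out_dir, paste0(id, "_widths.tsv")))
      if (!is.null(an$histogram))
        write_fm_table(an$histogram, file.path(config$out_dir, paste0(id, "_histogram.tsv")))
      if (!is.null(an$clusters))
        write_fm_table(an$clusters$stats, file.path(config$out_dir, paste0(id, "_clusters.tsv")))
      if (nrow(wm))
        write_overlay(render_width_colormap(img, an$widths, an$clusters),
                      file.path(config$out_dir, paste0(id, "_width_map.png")))
      s <- list(image = id, region = im$region %||% NA,
                n_width_entries = nrow(wm),
                threshold = attr(an$mask, "threshold"),
                cluster_stats = if (!is.null(an$clusters)) an$clusters$stats else NULL,
                width_summary = if (!is.null(an$clusters)) an$clusters$summary else NULL)
      if (!is.null(an$class_map)) {
        cmdf <- as.data.frame(an$class_map)
        write_fm_table(cmdf, file.path(config$out_dir, paste0(id, "_classmap.tsv")))
        write_overlay(an$rendered$overlay,
                      file.path(config$out_dir, paste0(id, "_composition.png")))
        s$class_fractions <- as.list(an$rendered$fractions)
      }
      s
    }, error = function(e) {
      writeLines(paste("stage:", stage, "-", conditionMessage(e)),
                 file.path(config$out_dir, paste0("FAILED_", id)))
      stop("pipeline failed at stage '", stage, "' on image '", id, "': ",
           conditionMessage(e), call. = FALSE)
    })
    summaries[[id]] <- res
  }
  report$images <- summaries
  # exterior/interior style comparison when region tags are present
  regions <- vapply(summaries, function(s) as.character(s$region %||% NA), character(1))
  if (any(!is.na(regions)) && !is.null(model)) {
    by_region <- lapply(split(summaries, regions), function(group) {
      fr <- lapply(group, function(s) unlist(s$class_fractions))
      fr <- fr[!vapply(fr, is.null, logical(1))]
      if (!length(fr)) return(NULL)
      as.list(colMeans(do.call(rbind, fr)))
    })
    report$region_comparison <- by_region
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(structure(report, class = "analysis_report"))
}
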