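#' Specify a synthetic fibrous image
#'
#' Describes one class of SEM-like fibrous network: how many fibers to draw,
#' their width distribution (a mixture of Gaussian modes, in pixels), how
#' curly they are (a persistence length for the centerline random walk),
#' foreground/background intensity levels, and the texture noise that gives
#' the class its learnable signature.
#'
#' Fibers are the brighter phase: `fiber_intensity` must exceed
#' `background_intensity`. Widths are realized per fiber (constant along a
#' fiber) and quantized to the nearest odd pixel count >= 3 so that the
#' rasterized ribbon has a well-defined single-pixel centerline.
#'
#' @param n_fibers number of fibers to draw (>= 0).
#' @param width_modes data frame with columns `mean`, `sd`, `weight` (one
#'   row per mixture mode, widths in px); weights must sum to 1 and all
#'   mode means must be >= 3 px.
#' @param curvature persistence length in px of the centerline random walk;
#'   larger is straighter, `Inf` gives straight fibers.
#' @param fiber_intensity mean foreground level in \[0, 1\].
#' @param background_intensity mean background level in \[0, 1\].
#' @param texture list with `noise_sd` (additive Gaussian sd) and
#'   `corr_len` (spatial correlation length in px; 0 = white noise).
#' @param image_shape integer vector `c(rows, cols)`.
#' @param seed integer RNG seed; identical (spec, seed) pairs reproduce
#'   bit-identical images.
#' @param orientation optional fixed initial direction in radians (0 points
#'   along increasing column); default random per fiber.
#' @param start optional fixed 0-based `c(row, col)` start point for every
#'   fiber; default random.
#' @param name optional class name carried into ground truth.
#' @return a `fiber_spec` list.
#' @export
fiber_spec <- function(n_fibers,
                       width_modes = data.frame(mean = 11, sd = 2, weight = 1),
                       curvature = 200,
                       fiber_intensity = 0.8,
                       background_intensity = 0.15,
                       texture = list(noise_sd = 0.05, corr_len = 1.5),
                       image_shape = c(1024L, 1024L),
                       seed = 1L,
                       orientation = NULL,
                       start = NULL,
                       name = "fiber") {
  spec <- list(n_fibers = as.integer(n_fibers), width_modes = width_modes,
               curvature = curvature, fiber_intensity = fiber_intensity,
               background_intensity = background_intensity, texture = texture,
               image_shape = as.integer(image_shape), seed = as.integer(seed),
               orientation = orientation, start = start, name = name)
  class(spec) <- "fiber_spec"
  validate_fiber_spec(spec)
  spec
}

validate_fiber_spec <- function(spec) {
  wm <- spec$width_modes
  if (!all(c("mean", "sd", "weight") %in% names(wm)))
    stop("width_modes needs columns mean, sd, weight")
  if (any(wm$mean < 3)) stop("all width-mode means must be >= 3 px")
  if (abs(sum(wm$weight) - 1) > 1e-8) stop("width-mode weights must sum to 1")
  if (spec$fiber_intensity <= spec$background_intensity)
    stop("fiber_intensity must exceed background_intensity (fibers are the brighter phase)")
  if (spec$n_fibers < 0) stop("n_fibers must be >= 0")
  if (length(spec$image_shape) != 2 || any(spec$image_shape < 8))
    stop("image_shape must be c(rows, cols) with both >= 8")
  widest <- round_odd(max(wm$mean + 3 * wm$sd))
  if (min(spec$image_shape) < 3 * widest)
    stop("image_shape ", paste(spec$image_shape, collapse = "x"),
         " is too small to contain the widest requested fiber (~", widest,
         " px); need at least ", 3 * widest, " px on the short side")
  invisible(spec)
}

# draw n fiber widths from the mixture and quantize to odd px >= 3
sample_fiber_widths <- function(width_modes, n) {
  if (n == 0L) return(integer(0))
  mode <- sample.int(nrow(width_modes), n, replace = TRUE,
                     prob = width_modes$weight)
  w <- rnorm(n, width_modes$mean[mode], width_modes$sd[mode])
  round_odd(w)
}

# bounded-turning-angle random walk from (y, x) (1-based, continuous) with
# initial direction theta; returns the visited continuous points up to the
# first frame (or region) exit
walk_direction <- function(y, x, theta, persistence, nr, nc, margin,
                           step = 0.5, region = NULL) {
  max_steps <- ceiling(4 * (nr + nc) / step)
  turn_sd <- if (is.finite(persistence)) sqrt(step / persistence) else 0
  dth <- if (turn_sd > 0) rnorm(max_steps, 0, turn_sd) else numeric(max_steps)
  th <- theta + c(0, cumsum(dth))[seq_len(max_steps)]
  ys <- y + cumsum(step * sin(th))
  xs <- x + cumsum(step * cos(th))
  bad <- ys < 1 - margin | ys > nr + margin | xs < 1 - margin | xs > nc + margin
  if (!is.null(region)) {
    ri <- as.integer(clamp(round(ys), 1, nr))
    ci <- as.integer(clamp(round(xs), 1, nc))
    bad <- bad | !region[cbind(ri, ci)]
  }
  stop_at <- which(bad)[1]
  n <- if (is.na(stop_at)) max_steps else stop_at - 1L
  cbind(ys[seq_len(n)], xs[seq_len(n)])
}

# full centerline through a start point: walk both ways, smooth out
# sub-pixel jitter (stiff fibers are smooth below the persistence scale,
# and a rough band would not honor its own width), quantize to the pixel
# grid, drop consecutive duplicates
trace_centerline <- function(start_y, start_x, theta, persistence, nr, nc,
                             margin, region = NULL) {
  fwd <- walk_direction(start_y, start_x, theta, persistence, nr, nc, margin,
                        region = region)
  bwd <- walk_direction(start_y, start_x, theta + pi, persistence, nr, nc,
                        margin, region = region)
  pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
               c(start_y, start_x), fwd)
  if (is.finite(persistence) && nrow(pts) >= 9) {
    k <- rep(1 / 9, 9)
    sm_y <- stats::filter(pts[, 1], k, sides = 2)
    sm_x <- stats::filter(pts[, 2], k, sides = 2)
    keep <- !is.na(sm_y)
    if (any(keep)) pts <- cbind(sm_y[keep], sm_x[keep])
  }
  cy <- round(pts[, 1]); cx <- round(pts[, 2])
  keep <- c(TRUE, diff(cy) != 0 | diff(cx) != 0)
  ok <- cy >= 1 & cy <= nr & cx >= 1 & cx <= nc
  cbind(cy, cx)[keep & ok, , drop = FALSE]
}

.disc_cache <- new.env(parent = emptyenv())

disc_offsets <- function(width) {
  key <- as.character(width)
  if (!is.null(.disc_cache[[key]])) return(.disc_cache[[key]])
  # pixel-coverage rasterization: a pixel belongs to the fiber when its
  # center lies inside the continuous band of halfwidth width/2; on an
  # axis-aligned fiber this gives exactly `width` rows
  r <- width / 2
  d <- seq.int(-floor(r), floor(r))
  g <- expand.grid(di = d, dj = d)
  g <- g[g$di^2 + g$dj^2 <= r^2 - 1e-9, ]
  .disc_cache[[key]] <- g
  g
}

# stamp a disc of the fiber's width at every centerline pixel
stamp_fiber <- function(mask, pts, width, region = NULL) {
  if (nrow(pts) == 0L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  off <- disc_offsets(width)
  ii <- rep(pts[, 1], each = nrow(off)) + off$di
  jj <- rep(pts[, 2], each = nrow(off)) + off$dj
  ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
  idx <- (jj[ok] - 1L) * nr + ii[ok]
  if (!is.null(region)) idx <- idx[region[idx]]
  mask[idx] <- 1L
  mask
}

# separable Gaussian smoothing with circular (wrap-around) boundaries;
# adequate for stationary noise fields
gauss_smooth <- function(m, sigma) {
  r <- max(1L, min(ceiling(3 * sigma), (min(dim(m)) - 1L) %/% 2L))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  a <- stats::filter(m, k, circular = TRUE)
  a <- t(stats::filter(t(a), k, circular = TRUE))
  matrix(as.numeric(a), nrow(m), ncol(m))
}

# spatially correlated zero-mean Gaussian field with target sd
correlated_noise <- function(nr, nc, noise_sd, corr_len) {
  if (noise_sd <= 0) return(matrix(0, nr, nc))
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (corr_len > 0.25) {
    z <- gauss_smooth(z, corr_len)
    z <- z - mean(z)
  }
  z * (noise_sd / sd(z))
}

#' Generate one synthetic fibrous image with exact ground truth
#'
#' Fiber centerlines are bounded-turning-angle random walks (persistence
#' length `spec$curvature`); each fiber has a constant width drawn from the
#' spec's mixture and is rasterized as a swept disc. Correlated Gaussian
#' texture noise is added after rasterization and intensities are clipped
#' to \[0, 1\].
#'
#' @param spec a [fiber_spec()].
#' @return list with `image` (a [grayscale_image]) and `truth` (a
#'   `ground_truth`: `fiber_mask`, per-fiber centerline pixel coordinates
#'   (0-based) and widths, `class_label`, `seed`).
#' @export
generate_fiber_image <- function(spec) {
  validate_fiber_spec(spec)
  set.seed(spec$seed)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  mask <- matrix(0L, nr, nc)
  widths <- sample_fiber_widths(spec$width_modes, spec$n_fibers)
  fibers <- vector("list", spec$n_fibers)
  for (f in seq_len(spec$n_fibers)) {
    w <- widths[f]
    sy <- if (is.null(spec$start)) runif(1, 1, nr) else spec$start[1] + 1
    sx <- if (is.null(spec$start)) runif(1, 1, nc) else spec$start[2] + 1
    th <- if (is.null(spec$orientation)) runif(1, 0, 2 * pi) else spec$orientation
    pts <- trace_centerline(sy, sx, th, spec$curvature, nr, nc,
                            margin = (w - 1) / 2)
    mask <- stamp_fiber(mask, pts, w)
    fibers[[f]] <- list(points = cbind(row = pts[, 1] - 1L, col = pts[, 2] - 1L),
                        width = w)
  }
  levels <- matrix(spec$background_intensity, nr, nc)
  levels[mask == 1L] <- spec$fiber_intensity
  noise <- correlated_noise(nr, nc, spec$texture$noise_sd, spec$texture$corr_len)
  img <- grayscale_image(clamp(levels + noise),
                         provenance = sprintf("synthetic:%s:seed=%d", spec$name, spec$seed))
  truth <- structure(list(fiber_mask = mask, fibers = fibers,
                          class_label = spec$name, region_labels = NULL,
                          seed = spec$seed, spec = spec),
                     class = "ground_truth")
  list(image = img, truth = truth)
}

#' Flatten a ground truth's centerlines into one table
#'
#' @param truth a `ground_truth` from [generate_fiber_image()].
#' @return data frame with columns `fiber`, `row`, `col`, `width` (0-based
#'   pixel coordinates, widths in px).
#' @export
centerline_truth <- function(truth) {
  if (length(truth$fibers) == 0L)
    return(data.frame(fiber = integer(0), row = integer(0),
                      col = integer(0), width = integer(0)))
  do.call(rbind, lapply(seq_along(truth$fibers), function(f) {
    fb <- truth$fibers[[f]]
    if (nrow(fb$points) == 0L) return(NULL)
    data.frame(fiber = f, row = fb$points[, "row"], col = fb$points[, "col"],
               width = fb$width)
  }))
}

#' Generate a labeled multi-class image collection
#'
#' One deterministic sub-seed per image is derived from `seed`, so the whole
#' collection is reproducible and classes can be regenerated independently.
#'
#' @param class_specs named list of [fiber_spec()]s, one per class; at least
#'   two classes whose parameters (beyond seed/name) differ.
#' @param n_images_per_class images to generate for each class.
#' @param seed master seed.
#' @return a `fiber_dataset`: lists `images`, `truths`, character vector
#'   `labels`, and `classes`.
#' @export
generate_class_dataset <- function(class_specs, n_images_per_class, seed = 1L) {
  classes <- names(class_specs)
  if (is.null(classes) || any(classes == ""))
    stop("class_specs must be a named list")
  if (anyDuplicated(classes)) stop("duplicate class names: ",
                                   paste(unique(classes[duplicated(classes)]), collapse = ", "))
  if (length(classes) < 2) stop("at least two classes are required")
  strip <- function(s) { s$seed <- NULL; s$name <- NULL; s }
  for (i in seq_along(class_specs)) for (j in seq_len(i - 1L)) {
    if (identical(strip(class_specs[[i]]), strip(class_specs[[j]])))
      stop("classes '", classes[j], "' and '", classes[i],
           "' have identical generator parameters; classes must differ in at least one width or texture parameter")
  }
  seeds <- matrix(derive_seeds(seed, length(classes) * n_images_per_class),
                  nrow = length(classes))
  images <- list(); truths <- list(); labels <- character(0)
  for (ci in seq_along(classes)) {
    for (k in seq_len(n_images_per_class)) {
      sp <- class_specs[[ci]]
      sp$seed <- seeds[ci, k]
      sp$name <- classes[ci]
      out <- generate_fiber_image(sp)
      images[[length(images) + 1L]] <- out$image
      truths[[length(truths) + 1L]] <- out$truth
      labels <- c(labels, classes[ci])
    }
  }
  structure(list(images = images, truths = truths, labels = labels,
                 classes = classes, seed = seed),
            class = "fiber_dataset")
}

#' Generate a composite image of bright fibers over a denser matrix network
#'
#' Emulates a hybrid hydrogel micrograph: a `matrix_spec` network (e.g. the
#' polysaccharide phase) fills the frame, and brighter `af_spec` fibers are
#' confined to a smooth random region covering `af_region_fraction` of the
#' pixels. The ground truth carries a per-pixel `region_labels` raster.
#'
#' @param af_spec [fiber_spec()] for the bright overlay fibers, or `NULL`
#'   for a matrix-only image.
#' @param matrix_spec [fiber_spec()] for the background network.
#' @param af_region_fraction fraction of pixels in the overlay region, in
#'   (0, 1\].
#' @param seed RNG seed for the composite (region shape and both networks).
#' @return list with `image` and `truth`; `truth$region_labels` is an
#'   integer matrix (1 = matrix class, 2 = AF class) with a `classes`
#'   attribute.
#' @export
generate_hybrid_image <- function(af_spec, matrix_spec, af_region_fraction = 0.5,
                                  seed = 1L) {
  if (!is.null(af_spec)) {
    if (af_region_fraction <= 0 || af_region_fraction > 1)
      stop("af_region_fraction must lie in (0, 1]")
    if (af_spec$fiber_intensity <= matrix_spec$fiber_intensity)
      stop("af_spec fibers must be brighter than matrix_spec fibers")
  }
  nr <- matrix_spec$image_shape[1]; nc <- matrix_spec$image_shape[2]
  seeds <- derive_seeds(seed, 3)

  mat_spec <- matrix_spec; mat_spec$seed <- seeds[1]
  base <- generate_fiber_image(mat_spec)

  classes <- c(matrix_spec$name, if (!is.null(af_spec)) af_spec$name else NULL)
  region_labels <- matrix(1L, nr, nc)

  if (is.null(af_spec)) {
    attr(region_labels, "classes") <- classes
    base$truth$region_labels <- region_labels
    return(base)
  }

  # smooth random region with exactly the requested pixel fraction
  set.seed(seeds[2])
  if (af_region_fraction >= 1) {
    region <- matrix(TRUE, nr, nc)
  } else {
    # smooth low-resolution field upscaled to full frame: one or two large
    # contiguous regions with a sharp, exact-fraction boundary, so the
    # overlay region is resolvable at patch scale
    coarse <- gauss_smooth(matrix(rnorm(8 * 8), 8, 8), sigma = 2)
    field <- as.matrix(EBImage::resize(coarse, w = nr, h = nc))
    region <- field >= quantile(field, 1 - af_region_fraction,
                                names = FALSE, type = 1)
  }
  region_labels[region] <- 2L
  attr(region_labels, "classes") <- classes

  set.seed(seeds[3])
  if (!is.null(af_spec$image_shape) &&
      any(af_spec$image_shape != matrix_spec$image_shape))
    stop("af_spec and matrix_spec must share image_shape")
  af_mask <- matrix(0L, nr, nc)
  af_widths <- sample_fiber_widths(af_spec$width_modes, af_spec$n_fibers)
  af_fibers <- vector("list", af_spec$n_fibers)
  region_idx <- which(region)
  for (f in seq_len(af_spec$n_fibers)) {
    w <- af_widths[f]
    st <- region_idx[sample.int(length(region_idx), 1)]
    sy <- ((st - 1L) %% nr) + 1L; sx <- ((st - 1L) %/% nr) + 1L
    th <- runif(1, 0, 2 * pi)
    pts <- trace_centerline(sy, sx, th, af_spec$curvature, nr, nc,
                            margin = 0, region = region)
    af_mask <- stamp_fiber(af_mask, pts, w, region = region)
    af_fibers[[f]] <- list(points = cbind(row = pts[, 1] - 1L, col = pts[, 2] - 1L),
                           width = w)
  }

  levels <- matrix(matrix_spec$background_intensity, nr, nc)
  levels[base$truth$fiber_mask == 1L] <- matrix_spec$fiber_intensity
  levels[af_mask == 1L] <- af_spec$fiber_intensity
  noise <- correlated_noise(nr, nc, matrix_spec$texture$noise_sd,
                            matrix_spec$texture$corr_len)
  noise_af <- correlated_noise(nr, nc, af_spec$texture$noise_sd,
                               af_spec$texture$corr_len)
  noise[region] <- noise_af[region]
  img <- grayscale_image(clamp(levels + noise),
                         provenance = sprintf("synthetic-hybrid:%s+%s:seed=%d",
                                              af_spec$name, matrix_spec$name, seed))
  truth <- structure(list(fiber_mask = pmax(base$truth$fiber_mask, af_mask),
                          af_mask = af_mask, matrix_mask = base$truth$fiber_mask,
                          fibers = c(base$truth$fibers, af_fibers),
                          class_label = paste0(af_spec$name, "+", matrix_spec$name),
                          region_labels = region_labels, seed = seed,
                          spec = list(af = af_spec, matrix = matrix_spec,
                                      af_region_fraction = af_region_fraction)),
                     class = "ground_truth")
  list(image = img, truth = truth)
}

#' Majority class label per patch-sized tile of a region raster
#'
#' @param region_labels integer matrix with a `classes` attribute, as
#'   produced by [generate_hybrid_image()].
#' @param patch_size tile side in px.
#' @param stride tile spacing in px (default `patch_size`).
#' @return data frame with 0-based `row`, `col` tile origins and the
#'   majority `label` of each tile.
#' @export
region_tile_labels <- function(region_labels, patch_size = 224L,
                               stride = patch_size) {
  classes <- attr(region_labels, "classes")
  nr <- nrow(region_labels); nc <- ncol(region_labels)
  r0 <- seq.int(0L, nr - patch_size, by = stride)
  c0 <- seq.int(0L, nc - patch_size, by = stride)
  grid <- expand.grid(row = r0, col = c0)
  lab <- vapply(seq_len(nrow(grid)), function(i) {
    tile <- region_labels[grid$row[i] + seq_len(patch_size),
                          grid$col[i] + seq_len(patch_size)]
    as.integer(names(which.max(table(tile))))
  }, integer(1))
  data.frame(row = grid$row, col = grid$col, label = classes[lab])
}
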