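#' Segment bright fibers from a darker background
#'
#' Global intensity thresholding: pixels strictly above the threshold are
#' foreground. The default threshold is Otsu's method (maximal between-class
#' variance over 256 gray levels); a fixed threshold can be supplied
#' instead. The threshold actually used is recorded on the mask.
#'
#' @param image a [grayscale_image] or numeric matrix in \[0, 1\].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold threshold in \[0, 1\] when `method = "fixed"`.
#' @return a `binary_mask`: integer matrix over \{0, 1\} with attributes
#'   `threshold` and `method`.
#' @export
segment_fibers <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  px <- unclass(image); attributes(px) <- list(dim = dim(px))
  if (length(px) == 0) stop("image is empty")
  if (method == "otsu") {
    if (diff(range(px)) < 1e-12) {
      warning("constant image: no threshold separates fibers from background; returning an empty mask")
      t <- NA_real_
      mask <- matrix(0L, nrow(px), ncol(px))
    } else {
      t <- EBImage::otsu(EBImage::Image(px), range = c(0, 1), levels = 256)
      mask <- matrix(as.integer(px > t), nrow(px), ncol(px))
    }
  } else {
    if (is.null(threshold)) stop("method = 'fixed' requires `threshold`")
    t <- threshold
    mask <- matrix(as.integer(px > t), nrow(px), ncol(px))
  }
  structure(mask, threshold = t, method = method,
            class = c("binary_mask", "matrix", "array"))
}

as_mask <- function(mask) {
  m <- unclass(mask); attributes(m) <- list(dim = dim(m))
  if (!all(m %in% c(0, 1))) stop("mask values must be 0/1")
  storage.mode(m) <- "integer"
  m
}

#' Exact Euclidean distance transform of a fiber mask
#'
#' Each foreground pixel receives the Euclidean distance (in px, between
#' pixel centers) to the nearest background pixel; background pixels hold 0.
#' The image border is treated as background, so fibers touching the frame
#' get finite distances.
#'
#' @param mask a `binary_mask` (or 0/1 matrix).
#' @return a `distance_map`: numeric matrix of distances.
#' @export
distance_transform <- function(mask) {
  m <- as_mask(mask)
  nr <- nrow(m); nc <- ncol(m)
  # pad with a one-pixel background ring: the frame counts as background
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  d <- if (any(p == 1L)) {
    as.matrix(EBImage::distmap(p, metric = "euclidean"))
  } else {
    matrix(0, nr + 2L, nc + 2L)
  }
  structure(d[2:(nr + 1L), 2:(nc + 1L)],
            class = c("distance_map", "matrix", "array"))
}

#' Skeletonize a fiber mask to a single-pixel centerline
#'
#' Topology-preserving Zhang-Suen thinning: foreground is iteratively peeled
#' from alternating sides until no pixel can be removed without breaking
#' connectivity, leaving a centerline one pixel wide away from junctions.
#' The passes work on foreground index vectors, so the cost scales with the
#' number of fiber pixels rather than the image area.
#'
#' @param mask a `binary_mask` (or 0/1 matrix).
#' @return a `centerline`: integer 0/1 matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- as_mask(mask)
  nr <- nrow(m); nc <- ncol(m)
  nrp <- nr + 2L
  p <- matrix(0L, nrp, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  fg <- which(p == 1L)
  # neighbour offsets in order P2..P9 = N, NE, E, SE, S, SW, W, NW
  off <- c(-1L, nrp - 1L, nrp, nrp + 1L, 1L, 1L - nrp, -nrp, -nrp - 1L)
  repeat {
    changed <- FALSE
    for (first in c(TRUE, FALSE)) {
      if (!length(fg)) break
      nb <- matrix(p[rep(fg, 8L) + rep(off, each = length(fg))],
                   length(fg), 8L)
      B <- rowSums(nb)
      A <- rowSums((nb == 0L) & (nb[, c(2:8, 1L)] == 1L))
      if (first) {
        del <- B >= 2L & B <= 6L & A == 1L &
          (nb[, 1] * nb[, 3] * nb[, 5] == 0L) &
          (nb[, 3] * nb[, 5] * nb[, 7] == 0L)
      } else {
        del <- B >= 2L & B <= 6L & A == 1L &
          (nb[, 1] * nb[, 3] * nb[, 7] == 0L) &
          (nb[, 1] * nb[, 5] * nb[, 7] == 0L)
      }
      if (any(del)) {
        p[fg[del]] <- 0L
        fg <- fg[!del]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- p[2:(nr + 1L), 2:(nc + 1L)]
  structure(out, class = c("centerline", "matrix", "array"))
}

# trace from an endpoint along the skeleton for at most max_len steps;
# returns the traced pixel indices and whether a junction was reached
trace_spur <- function(m, start_r, start_c, max_len, nbr) {
  path_r <- integer(max_len + 1L); path_c <- integer(max_len + 1L)
  r <- start_r; c <- start_c; prev_r <- -1L; prev_c <- -1L
  n <- 0L
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    n <- n + 1L
    path_r[n] <- r; path_c[n] <- c
    if (n > max_len) return(list(keep = TRUE))
    rr <- max(1L, r - 1L):min(nr, r + 1L)
    cc <- max(1L, c - 1L):min(nc, c + 1L)
    cand <- which(m[rr, cc, drop = FALSE] == 1L, arr.ind = TRUE)
    cand_r <- rr[cand[, 1]]; cand_c <- cc[cand[, 2]]
    keep <- !(cand_r == r & cand_c == c) & !(cand_r == prev_r & cand_c == prev_c)
    cand_r <- cand_r[keep]; cand_c <- cand_c[keep]
    if (length(cand_r) == 0L)
      return(list(keep = TRUE))            # isolated segment, not a spur
    if (length(cand_r) > 1L || nbr[cand_r[1], cand_c[1]] > 2L)
      return(list(keep = FALSE, rows = path_r[seq_len(n)], cols = path_c[seq_len(n)]))
    prev_r <- r; prev_c <- c
    r <- cand_r[1]; c <- cand_c[1]
  }
}

#' Refine a skeleton: close small gaps and prune short spurs
#'
#' Morphological closing (3x3 dilation then re-thinning, restricted to the
#' original fiber mask when supplied) bridges 1-px discontinuities, and
#' terminal branches shorter than `spur_length` that end at a junction are
#' removed. The pass is iterated to a fixed point, so the operation is
#' idempotent.
#'
#' @param skeleton a `centerline`.
#' @param spur_length prune spurs strictly shorter than this many pixels.
#' @param mask optional originating `binary_mask`; when given, refined
#'   centerline pixels are kept inside its foreground.
#' @return a refined `centerline`.
#' @export
refine_centerline <- function(skeleton, spur_length = 5L, mask = NULL) {
  m <- as_mask(skeleton)
  for (iter in 1:6) {
    prev <- m
    # gap closing, only when dilation actually merges skeleton fragments:
    # re-thinning an intact skeleton would erode its endpoints
    d <- matrix(as.integer(EBImage::dilate(m, EBImage::makeBrush(3, "box")) > 0),
                nrow(m), ncol(m))
    if (!is.null(mask)) d <- d * as_mask(mask)
    if (count_components8(d) < count_components8(m)) {
      m <- unclass(skeletonize(d))
    }
    # spur pruning
    repeat {
      nbr <- neighbor_count(m)
      ends <- which(m == 1L & nbr == 1L, arr.ind = TRUE)
      removed <- FALSE
      for (e in seq_len(nrow(ends))) {
        if (m[ends[e, 1], ends[e, 2]] != 1L) next
        tr <- trace_spur(m, ends[e, 1], ends[e, 2], spur_length - 1L, nbr)
        if (!tr$keep) {
          m[cbind(tr$rows, tr$cols)] <- 0L
          removed <- TRUE
        }
      }
      if (!removed) break
    }
    # clear 1-px protrusions left at spur attachment points; thinning keeps
    # clean single-pixel lines (endpoints have a single neighbour) intact
    m <- unclass(skeletonize(m))
    if (identical(m, prev)) break
  }
  structure(m, class = c("centerline", "matrix", "array"))
}

#' Measure local fiber width at every centerline pixel
#'
#' At a centerline pixel, the distance-map value `d` is the distance from
#' the fiber axis to the nearest background pixel center, so the local
#' width is `2 d - 1` px (pixel-center convention, exact on odd-width
#' ribbons; set `convention = "2d"` for the edge-to-edge alternative).
#' Centerline pixels falling on background (d = 0) are skipped and counted.
#' Three reliability flags are attached: `junction` marks entries within one
#' local half-width of a skeleton junction (fiber crossings inflate the
#' distance map there), `endcap` marks entries within one local half-width
#' of a skeleton endpoint (the map tapers off at fiber termini), and
#' `border` marks entries within one maximal width of the image frame.
#'
#' @param dist a `distance_map`.
#' @param centerline a `centerline` derived from the same mask.
#' @param pixel_size optional nm per pixel; adds a `width_nm` column.
#' @param convention `"2d-1"` (default) or `"2d"`.
#' @return a `width_map` data frame with columns `row`, `col` (0-based),
#'   `width_px`, `width_nm` (NA when no pixel size), `junction`, `endcap`,
#'   `border`; attributes `skipped`, `convention`, `pixel_size`, `summary`.
#' @export
measure_local_width <- function(dist, centerline, pixel_size = NULL,
                                convention = c("2d-1", "2d")) {
  convention <- match.arg(convention)
  if (!all(dim(dist) == dim(centerline)))
    stop("distance map and centerline have different shapes")
  cl <- as_mask(centerline)
  empty_wm <- function(skipped) {
    structure(data.frame(row = integer(0), col = integer(0),
                         width_px = numeric(0), width_nm = numeric(0),
                         junction = logical(0), endcap = logical(0),
                         border = logical(0)),
              skipped = skipped, convention = convention,
              pixel_size = pixel_size,
              summary = c(min = NA, max = NA, median = NA),
              class = c("width_map", "data.frame"))
  }
  if (!any(cl == 1L)) return(empty_wm(0L))
  nbr <- neighbor_count(cl)
  idx <- which(cl == 1L, arr.ind = TRUE)
  # read the distance map at the deepest pixel within 2 px of the centerline
  # pixel: thinning leaves a zigzag centerline on oblique fibers whose
  # pixels sit off the medial axis, and the ridge value itself oscillates
  # with lattice phase along oblique fibers — both bias the raw value low;
  # on axis-aligned ribbons the ridge is flat and the reading is unchanged
  dm <- unclass(dist)
  nr0 <- nrow(dm); nc0 <- ncol(dm)
  d <- dm[idx]
  for (di in -2:2) for (dj in -2:2) {
    if (di == 0L && dj == 0L) next
    rr <- idx[, 1] + di; cc <- idx[, 2] + dj
    ok <- rr >= 1L & rr <= nr0 & cc >= 1L & cc <= nc0
    d[ok] <- pmax(d[ok], dm[cbind(rr[ok], cc[ok])])
  }
  d[dm[idx] == 0] <- 0   # off-foreground centerline pixels stay skipped
  skipped <- sum(d == 0)
  keep <- d > 0
  if (!any(keep)) return(empty_wm(skipped))
  idx <- idx[keep, , drop = FALSE]; d <- d[keep]
  w <- if (convention == "2d-1") 2 * d - 1 else 2 * d
  nr <- nrow(cl); nc <- ncol(cl)
  maxw <- if (length(w)) max(w) else 0
  border <- pmin(idx[, 1] - 1L, idx[, 2] - 1L, nr - idx[, 1], nc - idx[, 2]) < maxw
  # flag whole crossing zones, not just the junction pixel: where fibers
  # cross, the distance map is inflated within roughly one local half-width
  # of the junction; likewise the map tapers within half a width of a fiber
  # terminus (end cap), where the local width is undefined
  zone_flag <- function(pixels) {
    if (!any(pixels)) return(rep(FALSE, nrow(idx)))
    dz <- as.matrix(EBImage::distmap(1L - pixels, metric = "euclidean"))
    dz[idx] <= d + 1
  }
  junction_zone <- zone_flag(cl == 1L & nbr > 2L)
  endcap_zone <- zone_flag(cl == 1L & nbr == 1L)
  wm <- data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                   width_px = w,
                   width_nm = if (is.null(pixel_size)) NA_real_ else w * pixel_size,
                   junction = junction_zone,
                   endcap = endcap_zone,
                   border = border)
  structure(wm, skipped = skipped, convention = convention,
            pixel_size = pixel_size,
            summary = if (nrow(wm)) c(min = min(w), max = max(w), median = median(w))
                      else c(min = NA, max = NA, median = NA),
            class = c("width_map", "data.frame"))
}

#' Cluster local widths into thin / medium / thick categories
#'
#' One-dimensional k-means on the width values, initialized at the k
#' quantile-band midpoints (deterministic). Clusters are renamed by
#' ascending mean: for k = 3 they are `thin`, `medium`, `thick`. Junction
#' entries are assigned a label by nearest center but excluded from the
#' per-cluster mean/sd statistics by default, since widths at fiber
#' crossings are inflated. The medium-cluster mean +/- sd is the headline
#' per-sample width statistic.
#'
#' @param widths a `width_map`.
#' @param k number of clusters (default 3).
#' @param exclude_junctions exclude junction-flagged entries from cluster
#'   statistics (default TRUE).
#' @return a `width_clusters` list: `k`, `centers`, `labels` (per width-map
#'   entry), `stats` (name, mean, sd, count, lower, upper), `summary`
#'   (formatted medium-cluster mean +/- sd), `unit`.
#' @export
cluster_widths <- function(widths, k = 3L, exclude_junctions = TRUE) {
  stopifnot(inherits(widths, "width_map"))
  use_nm <- !is.null(attr(widths, "pixel_size"))
  vals <- if (use_nm) widths$width_nm else widths$width_px
  unit <- if (use_nm) "nm" else "px"
  fit_vals <- if (exclude_junctions && any(!widths$junction)) vals[!widths$junction] else vals
  if (length(unique(fit_vals)) < k)
    stop("cannot form ", k, " clusters: only ", length(unique(fit_vals)),
         " distinct width values available")
  centers <- quantile(fit_vals, probs = (2 * seq_len(k) - 1) / (2 * k),
                      names = FALSE, type = 7)
  if (anyDuplicated(centers)) {
    u <- sort(unique(fit_vals))
    centers <- u[round(seq(1, length(u), length.out = k))]
  }
  km <- kmeans(fit_vals, centers = matrix(sort(centers), ncol = 1),
               iter.max = 100, algorithm = "Lloyd")
  ord <- order(km$centers[, 1])
  centers_sorted <- km$centers[ord, 1]
  # assign every entry (junctions included) to the nearest center
  lab_idx <- max.col(-abs(outer(vals, centers_sorted, "-")), ties.method = "first")
  cl_names <- if (k == 3L) c("thin", "medium", "thick")
              else paste0("cluster_", seq_len(k))
  stats <- do.call(rbind, lapply(seq_len(k), function(i) {
    member <- lab_idx == i & (!exclude_junctions | !widths$junction)
    v <- vals[member]
    data.frame(name = cl_names[i],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else 0,
               count = sum(lab_idx == i))
  }))
  if (any(diff(stats$mean) <= 0, na.rm = TRUE))
    warning("cluster means are not strictly increasing; data may have fewer than ",
            k, " genuine width modes")
  mids <- (head(centers_sorted, -1) + tail(centers_sorted, -1)) / 2
  stats$lower <- c(-Inf, mids); stats$upper <- c(mids, Inf)
  medium_i <- if (k == 3L) 2L else which.max(stats$count)
  structure(list(k = k, centers = centers_sorted,
                 labels = factor(cl_names[lab_idx], levels = cl_names),
                 stats = stats,
                 summary = format_mean_sd(stats$mean[medium_i],
                                          stats$sd[medium_i], unit),
                 unit = unit,
                 exclude_junctions = exclude_junctions),
            class = "width_clusters")
}

#' @export
print.width_clusters <- function(x, ...) {
  cat("width clusters (k =", x$k, "):\n")
  print(x$stats, row.names = FALSE)
  cat("headline (medium):", x$summary, "\n")
  invisible(x)
}

#' Histogram of local widths
#'
#' @param widths a `width_map`.
#' @param bin_width bin width in the map's unit (nm when a pixel size is
#'   attached, px otherwise); must be positive.
#' @return data frame with `bin_lo`, `bin_hi`, `mid`, `count`.
#' @export
width_histogram <- function(widths, bin_width = 2) {
  stopifnot(inherits(widths, "width_map"))
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be positive")
  if (nrow(widths) == 0) stop("width map is empty")
  use_nm <- !is.null(attr(widths, "pixel_size"))
  v <- if (use_nm) widths$width_nm else widths$width_px
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  cnt <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
  data.frame(bin_lo = head(breaks, -1), bin_hi = tail(breaks, -1),
             mid = (head(breaks, -1) + tail(breaks, -1)) / 2, count = cnt)
}

#' Render a local-width color overlay
#'
#' Paints each centerline pixel on top of the grayscale image. Without
#' clusters, widths map to a continuous palette clipped at the 1st-99th
#' percentile; with clusters, each thin/medium/thick category gets one
#' discrete color. The returned array carries the palette legend (breaks
#' and colors) as attributes; [write_overlay()] embeds it graphically.
#'
#' @param image the source [grayscale_image].
#' @param widths a `width_map` measured on it.
#' @param clusters optional `width_clusters` for the discrete 3-color map.
#' @param palette continuous palette function input (passed to
#'   [grDevices::hcl.colors]) or a vector of k colors in discrete mode.
#' @param dot_radius paint each entry as a (2r+1)-square dot (default 1).
#' @return H x W x 3 RGB array (class `overlay`) with attributes `legend`
#'   (data frame value/color) and `limits`.
#' @export
render_width_colormap <- function(image, widths, clusters = NULL,
                                  palette = NULL, dot_radius = 1L) {
  stopifnot(inherits(widths, "width_map"))
  if (nrow(widths) == 0) stop("width map is empty")
  px <- unclass(image); attributes(px) <- list(dim = dim(px))
  nr <- nrow(px); nc <- ncol(px)
  rgb_arr <- array(rep(px, 3L), dim = c(nr, nc, 3L))
  use_nm <- !is.null(attr(widths, "pixel_size"))
  v <- if (use_nm) widths$width_nm else widths$width_px
  if (is.null(clusters)) {
    lims <- quantile(v, c(0.01, 0.99), names = FALSE)
    if (diff(lims) <= 0) lims <- lims + c(-0.5, 0.5)
    vv <- clamp((v - lims[1]) / (lims[2] - lims[1]))
    pal <- grDevices::colorRamp(grDevices::hcl.colors(64, palette %||% "viridis"))
    cols <- pal(vv) / 255
    legend_vals <- seq(lims[1], lims[2], length.out = 6)
    legend_cols <- grDevices::rgb(pal(seq(0, 1, length.out = 6)) / 255)
  } else {
    k <- clusters$k
    cols_k <- palette %||% grDevices::hcl.colors(k, "Zissou 1")
    ci <- as.integer(clusters$labels)
    cols <- t(grDevices::col2rgb(cols_k[ci])) / 255
    lims <- range(v)
    legend_vals <- clusters$stats$mean
    legend_cols <- cols_k
  }
  rad <- as.integer(dot_radius)
  for (dd in seq_len(3)) {
    plane <- rgb_arr[, , dd]
    for (di in -rad:rad) for (dj in -rad:rad) {
      rr <- widths$row + 1L + di; cc <- widths$col + 1L + dj
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      plane[cbind(rr[ok], cc[ok])] <- cols[ok, dd]
    }
    rgb_arr[, , dd] <- plane
  }
  structure(rgb_arr,
            legend = data.frame(value = legend_vals, color = legend_cols),
            limits = lims,
            unit = if (use_nm) "nm" else "px",
            class = c("overlay", "array"))
}

#' Write an overlay to PNG with an embedded legend
#'
#' @param overlay an `overlay` array from [render_width_colormap()] or
#'   [render_class_map()].
#' @param path output PNG path.
#' @param legend embed the color legend (default TRUE; falls back to the
#'   bare raster if no PNG graphics device is available).
#' @return `path`, invisibly.
#' @export
write_overlay <- function(overlay, path, legend = TRUE) {
  leg <- attr(overlay, "legend")
  if (legend && !is.null(leg) && isTRUE(capabilities("png"))) {
    nr <- dim(overlay)[1]; nc <- dim(overlay)[2]
    grDevices::png(path, width = nc + 150, height = nr, res = 96)
    op <- graphics::par(mar = c(0, 0, 0, 0))
    on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, nc + 150), ylim = c(0, nr),
                          xaxs = "i", yaxs = "i", asp = 1)
    graphics::rasterImage(overlay, 0, 0, nc, nr, interpolate = FALSE)
    ys <- seq(nr * 0.1, nr * 0.9, length.out = nrow(leg))
    graphics::points(rep(nc + 30, nrow(leg)), ys, pch = 15, cex = 2,
                     col = leg$color)
    vals <- if (is.numeric(leg$value)) signif(leg$value, 3) else leg$value
    graphics::text(rep(nc + 45, nrow(leg)), ys,
                   labels = paste(vals, attr(overlay, "unit") %||% ""),
                   adj = 0, cex = 0.9)
  } else {
    arr <- unclass(overlay); attributes(arr) <- list(dim = dim(arr))
    png::writePNG(clamp(arr), target = path)
  }
  invisible(path)
}
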