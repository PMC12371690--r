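#' Crop an image into sliding-window patches
#'
#' Tiles the image with `patch_size` x `patch_size` windows whose top-left
#' corners lie at multiples of `stride` (0-based); only fully contained
#' windows are kept, giving `floor((H-P)/s)+1` by `floor((W-P)/s)+1`
#' patches.
#'
#' @param image a [grayscale_image] or numeric matrix.
#' @param patch_size window side in px (default 224).
#' @param stride window spacing in px (default `patch_size`,
#'   non-overlapping).
#' @param label optional class label applied to every patch.
#' @param image_id identifier recorded with each patch.
#' @return a `patch_set`: list with `pixels` (patch_size x patch_size x n
#'   array), `info` (data frame: `image_id`, `row`, `col`, `label`),
#'   `patch_size`, `stride`.
#' @export
crop_sliding_window <- function(image, patch_size = 224L, stride = patch_size,
                                label = NA_character_, image_id = "img") {
  px <- unclass(image); attributes(px) <- list(dim = dim(px))
  nr <- nrow(px); nc <- ncol(px)
  patch_size <- as.integer(patch_size); stride <- as.integer(stride)
  if (nr < patch_size || nc < patch_size)
    stop("image (", nr, " x ", nc, ") is smaller than patch_size (",
         patch_size, ")")
  if (stride < 1L) stop("stride must be >= 1")
  r0 <- seq.int(0L, nr - patch_size, by = stride)
  c0 <- seq.int(0L, nc - patch_size, by = stride)
  grid <- expand.grid(row = r0, col = c0)
  n <- nrow(grid)
  pixels <- array(0, dim = c(patch_size, patch_size, n))
  for (i in seq_len(n)) {
    pixels[, , i] <- px[grid$row[i] + seq_len(patch_size),
                        grid$col[i] + seq_len(patch_size)]
  }
  structure(list(pixels = pixels,
                 info = data.frame(image_id = image_id, row = grid$row,
                                   col = grid$col, label = label,
                                   stringsAsFactors = FALSE),
                 patch_size = patch_size, stride = stride),
            class = "patch_set")
}

#' Combine patch sets into one labeled collection
#'
#' @param ... `patch_set` objects sharing one `patch_size`.
#' @return a single `patch_set`.
#' @export
combine_patch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "patch_set"))
    sets <- sets[[1]]
  ps <- unique(vapply(sets, function(s) s$patch_size, integer(1)))
  if (length(ps) != 1L) stop("all patch sets must share patch_size")
  n <- sum(vapply(sets, function(s) nrow(s$info), integer(1)))
  pixels <- array(0, dim = c(ps, ps, n))
  at <- 0L
  for (s in sets) {
    k <- nrow(s$info)
    if (k) pixels[, , at + seq_len(k)] <- s$pixels
    at <- at + k
  }
  structure(list(pixels = pixels,
                 info = do.call(rbind, lapply(sets, `[[`, "info")),
                 patch_size = ps, stride = sets[[1]]$stride),
            class = "patch_set")
}

#' Crop every image of a labeled dataset into patches
#'
#' @param dataset a `fiber_dataset` from [generate_class_dataset()].
#' @param patch_size,stride see [crop_sliding_window()].
#' @return a labeled `patch_set` over all images.
#' @export
patches_from_dataset <- function(dataset, patch_size = 224L,
                                 stride = patch_size) {
  sets <- lapply(seq_along(dataset$images), function(i) {
    crop_sliding_window(dataset$images[[i]], patch_size, stride,
                        label = dataset$labels[i],
                        image_id = sprintf("%s_%03d", dataset$labels[i], i))
  })
  combine_patch_sets(sets)
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set: %d patches of %d x %d px", nrow(x$info),
              x$patch_size, x$patch_size))
  if (!all(is.na(x$info$label)))
    cat(" |", paste(sprintf("%s: %d", names(table(x$info$label)),
                            table(x$info$label)), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Split labeled patches into train and validation sets
#'
#' Stratified by class. By default whole source images are assigned to one
#' side (`by_image = TRUE`), so overlapping or adjacent crops from one
#' micrograph never straddle the split — the leakage that inflates
#' validation accuracy when near-duplicate crops land on both sides.
#' `by_image = FALSE` gives the plain patch-level stratified split, in which
#' `|train| = round(fraction * n)` per class.
#'
#' @param patches a labeled `patch_set`.
#' @param fraction train share in (0, 1\] (default 0.8).
#' @param seed RNG seed; same seed reproduces the same split.
#' @param by_image group patches by source image (default TRUE).
#' @return a `split_index`: list `train_ids`, `val_ids` (integer indices
#'   into the patch set), `fraction`, `seed`, `by_image`.
#' @export
split_dataset <- function(patches, fraction = 0.8, seed = 1L, by_image = TRUE) {
  info <- patches$info
  if (all(is.na(info$label))) stop("patches must be labeled to be split")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (fraction == 1) warning("fraction = 1: validation set is empty")
  set.seed(as.integer(seed))
  train_ids <- integer(0)
  for (cl in sort(unique(info$label))) {
    ids <- which(info$label == cl)
    if (length(ids) < 2L)
      stop("class '", cl, "' has fewer than 2 patches; cannot stratify")
    if (by_image) {
      imgs <- unique(info$image_id[ids])
      if (length(imgs) < 2L && fraction < 1)
        stop("class '", cl, "' has a single source image; cannot split by image ",
             "(use by_image = FALSE for a patch-level split)")
      imgs <- sample(imgs)
      # assign whole images: round(fraction * n_images) to the train side,
      # keeping at least one validation image when fraction < 1
      n_tr_img <- round(fraction * length(imgs))
      if (fraction < 1) n_tr_img <- min(n_tr_img, length(imgs) - 1L)
      n_tr_img <- max(n_tr_img, 1L)
      take_imgs <- imgs[seq_len(n_tr_img)]
      train_ids <- c(train_ids, ids[info$image_id[ids] %in% take_imgs])
    } else {
      n_tr <- round(fraction * length(ids))
      train_ids <- c(train_ids, sample(ids, n_tr))
    }
  }
  train_ids <- sort(train_ids)
  structure(list(train_ids = train_ids,
                 val_ids = setdiff(seq_len(nrow(info)), train_ids),
                 fraction = fraction, seed = as.integer(seed),
                 by_image = by_image),
            class = "split_index")
}

# subset a patch_set by indices
subset_patches <- function(patches, ids) {
  structure(list(pixels = patches$pixels[, , ids, drop = FALSE],
                 info = patches$info[ids, , drop = FALSE],
                 patch_size = patches$patch_size, stride = patches$stride),
            class = "patch_set")
}
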