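#' Train the patch classifier
#'
#' Trains the compact CNN of [small_cnn_config()] on the training side of a
#' stratified split, monitoring held-out accuracy each epoch, with early
#' stopping on a validation-accuracy plateau (the best-epoch weights are
#' kept). Training is deterministic for a fixed (data, config, seed)
#' triple.
#'
#' If the final validation accuracy is at chance level the function warns:
#' on separable synthetic classes that indicates a training failure, not a
#' property of the data.
#'
#' @param patches a labeled `patch_set`.
#' @param split a `split_index` from [split_dataset()].
#' @param config a `cnn_config`; its `n_classes` must match the labels.
#' @return a `classifier_model`: `classes`, `net` (weights), `config`,
#'   `log` (per-epoch loss/accuracy), `val_accuracy`.
#' @export
train_classifier <- function(patches, split, config) {
  info <- patches$info
  classes <- sort(unique(info$label[!is.na(info$label)]))
  if (length(classes) < 2) stop("need at least 2 classes in the training data")
  if (config$n_classes != length(classes))
    stop("config$n_classes (", config$n_classes, ") does not match the ",
         length(classes), " classes present")
  X <- prepare_cnn_inputs(patches, config)
  y <- match(info$label, classes)

  tr <- split$train_ids; va <- split$val_ids
  Xtr <- X[, tr, drop = FALSE]; ytr <- y[tr]
  Xva <- X[, va, drop = FALSE]; yva <- y[va]
  K <- length(classes)

  net <- init_cnn(config)
  params <- cnn_params(net)
  state <- adam_init(params)
  set.seed(config$seed)

  n_tr <- length(ytr)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_accuracy = numeric(0))
  best_acc <- -Inf; best_net <- net; since_best <- 0L

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n_tr)
    losses <- numeric(0)
    for (b0 in seq(1L, n_tr, by = config$batch_size)) {
      ids <- ord[b0:min(b0 + config$batch_size - 1L, n_tr)]
      Xb <- Xtr[, ids, drop = FALSE]
      onehot <- matrix(0, K, length(ids))
      onehot[cbind(ytr[ids], seq_along(ids))] <- 1
      net <- cnn_set_params(net, params)
      fwd <- cnn_forward(net, Xb, train = TRUE)
      net <- fwd$net                      # carries updated BN running stats
      losses <- c(losses, -mean(log(pmax(fwd$probs[cbind(ytr[ids], seq_along(ids))], 1e-12))))
      grads <- cnn_backward(net, fwd, Xb, onehot)
      upd <- adam_step(params, grads, state, config$lr)
      params <- upd$params; state <- upd$state
    }
    net <- cnn_set_params(net, params)
    val_acc <- if (length(yva)) {
      mean(predict_classes(net, Xva) == yva)
    } else NA_real_
    log <- rbind(log, data.frame(epoch = ep, train_loss = mean(losses),
                                 val_accuracy = val_acc))
    if (!is.na(val_acc)) {
      if (val_acc > best_acc + 1e-9) {
        best_acc <- val_acc; best_net <- net; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
      if (val_acc >= 1) break
    }
  }
  if (is.finite(best_acc)) net <- best_net

  model <- structure(list(classes = classes, net = net, config = config,
                          log = log,
                          val_accuracy = if (is.finite(best_acc)) best_acc else NA_real_),
                     class = "classifier_model")
  if (length(yva) && is.finite(best_acc)) {
    chance <- 1 / K
    band <- 2 * sqrt(chance * (1 - chance) / length(yva))
    if (best_acc <= chance + band)
      warning(sprintf(
        "validation accuracy %.1f%% is at chance level (%.1f%%): training failed to find class structure",
        100 * best_acc, 100 * chance))
  }
  model
}

predict_classes <- function(net, X, batch = 64L) {
  n <- ncol(X)
  out <- integer(n)
  for (b0 in seq(1L, n, by = batch)) {
    ids <- b0:min(b0 + batch - 1L, n)
    p <- cnn_forward(net, X[, ids, drop = FALSE])$probs
    out[ids] <- max.col(t(p), ties.method = "first")
  }
  out
}

predict_scores <- function(net, X, batch = 64L) {
  n <- ncol(X)
  K <- length(net$bd)
  out <- matrix(0, K, n)
  for (b0 in seq(1L, n, by = batch)) {
    ids <- b0:min(b0 + batch - 1L, n)
    out[, ids] <- cnn_forward(net, X[, ids, drop = FALSE])$probs
  }
  out
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("classifier_model (%s): %d classes [%s]\n",
              x$config$architecture, length(x$classes),
              paste(x$classes, collapse = ", ")))
  if (is.finite(x$val_accuracy))
    cat(sprintf("validation accuracy: %.1f%% (%d epochs trained)\n",
                100 * x$val_accuracy, nrow(x$log)))
  invisible(x)
}

#' Evaluate a classifier on labeled patches
#'
#' @param model a `classifier_model`.
#' @param patches a labeled `patch_set`.
#' @param ids optional indices restricting evaluation (e.g. a split's
#'   `val_ids`); default all patches.
#' @return a `confusion_matrix`: K x K table of counts (rows = true class,
#'   cols = predicted) with attributes `accuracy` and `per_class_accuracy`.
#' @export
evaluate_classifier <- function(model, patches, ids = NULL) {
  if (!is.null(ids)) patches <- subset_patches(patches, ids)
  labs <- patches$info$label
  if (any(is.na(labs))) stop("all evaluated patches must be labeled")
  unseen <- setdiff(unique(labs), model$classes)
  if (length(unseen))
    stop("labels not known to the model: ", paste(unseen, collapse = ", "))
  X <- prepare_cnn_inputs(patches, model$config)
  pred <- model$classes[predict_classes(model$net, X)]
  cm <- table(true = factor(labs, levels = model$classes),
              predicted = factor(pred, levels = model$classes))
  structure(cm,
            accuracy = sum(diag(cm)) / sum(cm),
            per_class_accuracy = diag(cm) / rowSums(cm),
            class = c("confusion_matrix", class(cm)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x))
  cat(sprintf("overall accuracy: %.1f%%\n", 100 * attr(x, "accuracy")))
  invisible(x)
}

#' Classify every sliding-window crop of an image
#'
#' Each crop is scored independently; the normalized score vector and its
#' argmax label are recorded per crop. The default stride of half a patch
#' gives overlapping crops for smoother maps.
#'
#' @param model a `classifier_model`.
#' @param image a [grayscale_image] at least `patch_size` on each side.
#' @param patch_size crop side in px (default 224).
#' @param stride crop spacing (default `patch_size / 2`).
#' @return a `class_map`: data frame with 0-based `row`, `col`, one score
#'   column per class, `label`, `max_score`; attributes `classes`,
#'   `patch_size`, `stride`, `image_shape`.
#' @export
classify_image <- function(model, image, patch_size = 224L,
                           stride = patch_size %/% 2L) {
  ps <- crop_sliding_window(image, patch_size = patch_size, stride = stride)
  X <- prepare_cnn_inputs(ps, model$config)
  scores <- predict_scores(model$net, X)       # K x n
  lab_i <- max.col(t(scores), ties.method = "first")
  df <- cbind(ps$info[, c("row", "col")],
              as.data.frame(t(scores), col.names = model$classes))
  names(df)[2 + seq_along(model$classes)] <- model$classes
  df$label <- model$classes[lab_i]
  df$max_score <- scores[cbind(lab_i, seq_along(lab_i))]
  structure(df, classes = model$classes, patch_size = patch_size,
            stride = stride, image_shape = dim(image),
            class = c("class_map", "data.frame"))
}

#' Default palette: polysaccharide classes blue, amyloid-fiber classes magenta
#'
#' Classes whose name contains "phy" (case-insensitive) are colored blue,
#' all others magenta, matching the blue/magenta composition-map convention.
#'
#' @param classes character vector of class names.
#' @return named vector of hex colors.
#' @export
default_class_palette <- function(classes) {
  cols <- ifelse(grepl("phy", classes, ignore.case = TRUE),
                 "#2C4FD8", "#E038C8")
  # distinguish multiple AF classes by magenta shades
  af <- which(cols == "#E038C8")
  if (length(af) > 1) {
    shades <- grDevices::hcl.colors(length(af) + 1, "Magenta")[seq_along(af)]
    cols[af] <- shades
  }
  setNames(cols, classes)
}

#' Render a color-coded composition map with class fractions
#'
#' Colors each pixel by the label of the crop whose center is nearest
#' (for a regular crop grid this is a tile map), alpha-blended over the
#' grayscale image, and tabulates the fraction of crops per class.
#'
#' @param image the classified [grayscale_image].
#' @param class_map a `class_map` from [classify_image()].
#' @param palette named class -> color vector; defaults to
#'   [default_class_palette()]. Classes missing from a supplied palette get
#'   a deterministic gray fallback with a warning.
#' @param alpha blend weight of the class color (default 0.55).
#' @return list with `overlay` (H x W x 3 array, class `overlay`) and
#'   `fractions` (named numeric vector over classes, summing to 1).
#' @export
render_class_map <- function(image, class_map, palette = NULL, alpha = 0.55) {
  if (nrow(class_map) == 0) stop("class map is empty")
  classes <- attr(class_map, "classes")
  if (is.null(palette)) {
    palette <- default_class_palette(classes)
  } else {
    missing <- setdiff(classes, names(palette))
    if (length(missing)) {
      warning("no palette color for class(es) ", paste(missing, collapse = ", "),
              "; using gray fallback")
      palette <- c(palette, setNames(rep("#808080", length(missing)), missing))
    }
  }
  px <- unclass(image); attributes(px) <- list(dim = dim(px))
  nr <- nrow(px); nc <- ncol(px)
  ph <- attr(class_map, "patch_size")
  # nearest crop center along each axis
  centers_r <- sort(unique(class_map$row)) + ph / 2
  centers_c <- sort(unique(class_map$col)) + ph / 2
  near_r <- vapply(seq_len(nr) - 0.5, function(y) which.min(abs(centers_r - y)), integer(1))
  near_c <- vapply(seq_len(nc) - 0.5, function(x) which.min(abs(centers_c - x)), integer(1))
  rows_u <- sort(unique(class_map$row)); cols_u <- sort(unique(class_map$col))
  L <- matrix(NA_integer_, length(rows_u), length(cols_u))
  L[cbind(match(class_map$row, rows_u), match(class_map$col, cols_u))] <-
    match(class_map$label, classes)
  lab_pix <- L[near_r, near_c]                   # class index per pixel
  rgbm <- grDevices::col2rgb(palette[classes]) / 255
  rgb_arr <- array(0, dim = c(nr, nc, 3))
  for (d in 1:3) {
    colplane <- matrix(rgbm[d, lab_pix], nr, nc)
    rgb_arr[, , d] <- (1 - alpha) * px + alpha * colplane
  }
  fr <- table(factor(class_map$label, levels = classes))
  fractions <- as.numeric(fr) / sum(fr)
  names(fractions) <- classes
  overlay <- structure(rgb_arr,
                       legend = data.frame(value = classes,
                                           color = unname(palette[classes])),
                       unit = "",
                       class = c("overlay", "array"))
  list(overlay = overlay, fractions = fractions)
}

#' Save / load a trained classifier
#'
#' The weights are written with [saveRDS()]; a JSON sidecar
#' (`<path>.json`) records the architecture, class list, configuration and
#' seed for audit.
#'
#' @param model a `classifier_model`.
#' @param path destination `.rds` path.
#' @return `path`, invisibly.
#' @export
save_classifier <- function(model, path) {
  saveRDS(model, path)
  side <- list(architecture = model$config$architecture,
               classes = model$classes,
               config = model$config[setdiff(names(model$config), "architecture")],
               val_accuracy = model$val_accuracy)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "classifier_model"))
  model
}
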