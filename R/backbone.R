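#' Rectified linear unit
#'
#' @param x Numeric vector/matrix/array.
#' @return `max(0, x)` elementwise.
#' @export
relu <- function(x) {
  if (any(!is.finite(x))) abort_validation("relu input must be finite")
  pmax(x, 0)
}

#' Specify a small convolutional backbone
#'
#' A backbone is an ordered list of conv / pool / dense layers with a named
#' feature-extraction layer: the forward pass is run up to that layer and its
#' flattened activations are the per-image feature vector. The default
#' [tiny_cnn_backbone()] is the desk-scale stand-in for large pretrained
#' networks, whose named-layer contract is mirrored by
#' [pretrained_backbone_info()].
#'
#' @param layers List of layer descriptors. Conv layers:
#'   `list(kind = "conv", name, filters, size, activation)`; pool layers:
#'   `list(kind = "pool", name, size)`; dense layers:
#'   `list(kind = "dense", name, units, activation)`. Activations are
#'   `"relu"`, `"sigmoid"` or `"none"`.
#' @param input_size Input image side length in pixels.
#' @param feature_layer Name of the layer whose flattened activations form
#'   the feature vector.
#' @param seed Seed for He-style weight initialization.
#' @return A `qlung_backbone` with initialized weights.
#' @export
backbone_spec <- function(layers, input_size = 64L, feature_layer = "features",
                          seed = 1L) {
  names_ <- map_chr(layers, "name")
  if (anyDuplicated(names_)) abort_validation("layer names must be unique")
  if (sum(names_ == feature_layer) != 1L) {
    abort_validation(sprintf("feature_layer '%s' must name exactly one layer",
                             feature_layer))
  }
  shapes <- infer_shapes(layers, input_size)
  weights <- with_seed(seed, init_weights(layers, shapes))
  fshape <- shapes[[which(names_ == feature_layer) + 1L]]
  structure(
    list(layers = layers, weights = weights, input_size = as.integer(input_size),
         feature_layer = feature_layer, feature_dim = as.integer(prod(fshape)),
         shapes = shapes, seed = as.integer(seed)),
    class = "qlung_backbone"
  )
}

#' Default two-block CNN backbone
#'
#' Two conv+pool blocks followed by a 64-unit dense feature layer and a
#' 3-logit head, for 64x64 grayscale inputs.
#'
#' @param seed Weight initialization seed.
#' @param input_size Input side length (default 64).
#' @return A `qlung_backbone`.
#' @export
tiny_cnn_backbone <- function(seed = 1L, input_size = 64L) {
  backbone_spec(
    layers = list(
      list(kind = "conv", name = "conv1", filters = 4L, size = 3L, activation = "relu"),
      list(kind = "pool", name = "pool1", size = 2L),
      list(kind = "conv", name = "conv2", filters = 8L, size = 3L, activation = "relu"),
      list(kind = "pool", name = "pool2", size = 2L),
      list(kind = "dense", name = "features", units = 64L, activation = "relu"),
      list(kind = "dense", name = "logits", units = 3L, activation = "none")
    ),
    input_size = input_size, feature_layer = "features", seed = seed
  )
}

#' @export
print.qlung_backbone <- function(x, ...) {
  cat(sprintf("<qlung_backbone> input %dx%d, feature layer '%s' (dim %d)\n",
              x$input_size, x$input_size, x$feature_layer, x$feature_dim))
  invisible(x)
}

# Shape inference: list of c(h, w, channels) before each layer plus the final
# output. Dense layers flatten; their output shape is c(1, 1, units).
infer_shapes <- function(layers, input_size) {
  shapes <- list(c(input_size, input_size, 1L))
  cur <- shapes[[1]]
  for (ly in layers) {
    cur <- switch(ly$kind,
      conv = {
        if (cur[1] < ly$size) abort_validation("conv kernel larger than input")
        c(cur[1] - ly$size + 1L, cur[2] - ly$size + 1L, ly$filters)
      },
      pool = c(cur[1] %/% ly$size, cur[2] %/% ly$size, cur[3]),
      dense = c(1L, 1L, ly$units),
      abort_validation(sprintf("unknown layer kind '%s'", ly$kind))
    )
    shapes <- c(shapes, list(as.integer(cur)))
  }
  shapes
}

init_weights <- function(layers, shapes) {
  w <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    inshape <- shapes[[i]]
    if (ly$kind == "conv") {
      fan_in <- ly$size^2 * inshape[3]
      w[[ly$name]] <- list(
        W = matrix(rnorm(fan_in * ly$filters, sd = sqrt(2 / fan_in)),
                   nrow = fan_in, ncol = ly$filters),
        b = rep(0, ly$filters)
      )
    } else if (ly$kind == "dense") {
      fan_in <- prod(inshape)
      w[[ly$name]] <- list(
        W = matrix(rnorm(fan_in * ly$units, sd = sqrt(2 / fan_in)),
                   nrow = fan_in, ncol = ly$units),
        b = rep(0, ly$units)
      )
    }
  }
  w
}

# im2col for a [h, w, c] array and k x k kernel: rows are output positions
# (column-major over the output grid), columns are (di, dj, channel) patch
# offsets, matching the conv weight matrix layout.
im2col <- function(x, k) {
  h <- dim(x)[1]; w <- dim(x)[2]; ch <- dim(x)[3]
  oh <- h - k + 1L; ow <- w - k + 1L
  out <- matrix(0, nrow = oh * ow, ncol = k * k * ch)
  col <- 1L
  for (c_ in seq_len(ch)) {
    for (dj in seq_len(k)) {
      for (di in seq_len(k)) {
        out[, col] <- as.vector(x[di:(di + oh - 1L), dj:(dj + ow - 1L), c_])
        col <- col + 1L
      }
    }
  }
  out
}

apply_activation <- function(x, activation) {
  switch(activation,
         relu = pmax(x, 0),
         sigmoid = 1 / (1 + exp(-x)),
         none = x,
         abort_validation(sprintf("unknown activation '%s'", activation)))
}

maxpool2d <- function(x, k) {
  h <- dim(x)[1]; w <- dim(x)[2]; ch <- dim(x)[3]
  oh <- h %/% k; ow <- w %/% k
  out <- array(-Inf, c(oh, ow, ch))
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      ii <- seq(di, by = k, length.out = oh)
      jj <- seq(dj, by = k, length.out = ow)
      out <- pmax(out, x[ii, jj, , drop = FALSE])
    }
  }
  out
}

# Forward pass through the backbone; returns the activation of layer `upto`
# (a [h, w, c] array) or, when upto is NULL, of the final layer.
backbone_forward <- function(backbone, pixels, upto = NULL) {
  x <- array(pixels / 255, c(nrow(pixels), ncol(pixels), 1L))
  for (ly in backbone$layers) {
    x <- switch(ly$kind,
      conv = {
        wb <- backbone$weights[[ly$name]]
        z <- sweep(im2col(x, ly$size) %*% wb$W, 2L, wb$b, "+")
        oh <- dim(x)[1] - ly$size + 1L
        apply_activation(array(z, c(oh, dim(x)[2] - ly$size + 1L, ly$filters)),
                         ly$activation)
      },
      pool = maxpool2d(x, ly$size),
      dense = {
        wb <- backbone$weights[[ly$name]]
        z <- as.vector(x) %*% wb$W + wb$b
        apply_activation(array(z, c(1L, 1L, ly$units)), ly$activation)
      }
    )
    if (!is.null(upto) && ly$name == upto) return(x)
  }
  x
}

#' Extract the per-image feature vector
#'
#' Runs the deterministic forward pass up to the backbone's feature layer and
#' returns the flattened activations.
#'
#' @param backbone A `qlung_backbone`.
#' @param image An `image_sample` whose size matches the backbone input.
#' @return Numeric vector of length `backbone$feature_dim`, with attributes
#'   `modality` and `subject_id` copied from the image.
#' @export
forward_features <- function(backbone, image) {
  stopifnot(inherits(backbone, "qlung_backbone"), inherits(image, "image_sample"))
  if (image$height != backbone$input_size || image$width != backbone$input_size) {
    abort_validation(sprintf(
      "image size %dx%d does not match backbone input %dx%d",
      image$height, image$width, backbone$input_size, backbone$input_size))
  }
  v <- as.vector(backbone_forward(backbone, image$pixels,
                                  upto = backbone$feature_layer))
  if (any(!is.finite(v))) abort_validation("non-finite feature values")
  structure(v, modality = image$modality, subject_id = image$subject_id)
}

softmax <- function(z) {
  if (is.vector(z)) z <- matrix(z, nrow = 1L)
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fine-tune the classification head of a backbone
#'
#' Replaces training of the full network by the cheap regime used throughout:
#' the convolutional body stays frozen, features are computed once, and only
#' the final logits layer is trained by softmax cross-entropy with Adam.
#'
#' @param backbone A `qlung_backbone` whose last layer is the `"logits"` dense
#'   head.
#' @param images List of `image_sample`s.
#' @param labels Character labels (at least two distinct classes).
#' @param epochs,lr Training schedule; `epochs = 0` or `lr = 0` are exact
#'   no-ops.
#' @param seed RNG seed for minibatch shuffling.
#' @param batch_size Minibatch size.
#' @return The backbone with an updated head and a `history` attribute
#'   (tibble: epoch, accuracy_pct, loss_pct).
#' @export
finetune_head <- function(backbone, images, labels, epochs = 20L, lr = 1e-2,
                          seed = 1L, batch_size = 16L) {
  stopifnot(inherits(backbone, "qlung_backbone"))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    abort_validation("fine-tuning requires at least two classes")
  }
  lv <- lesion_classes()[lesion_classes() %in% unique(labels)]
  y <- match(labels, lv)
  feats <- t(vapply(images, function(im) forward_features(backbone, im),
                    numeric(backbone$feature_dim)))
  head_name <- backbone$layers[[length(backbone$layers)]]$name
  wb <- backbone$weights[[head_name]]
  if (ncol(wb$W) < length(lv)) abort_validation("head narrower than class count")
  history <- tibble(epoch = integer(), accuracy_pct = double(), loss_pct = double())
  if (epochs > 0L) {
    opt <- adam_init(list(W = wb$W, b = wb$b))
    with_seed(seed, {
      for (ep in seq_len(epochs)) {
        idx <- sample.int(nrow(feats))
        for (batch in split(idx, ceiling(seq_along(idx) / batch_size))) {
          z <- sweep(feats[batch, , drop = FALSE] %*% wb$W, 2L, wb$b, "+")
          p <- softmax(z)
          d <- p
          d[cbind(seq_along(batch), y[batch])] <-
            d[cbind(seq_along(batch), y[batch])] - 1
          d <- d / length(batch)
          grads <- list(W = t(feats[batch, , drop = FALSE]) %*% d, b = colSums(d))
          upd <- adam_step(opt, list(W = wb$W, b = wb$b), grads, lr)
          opt <- upd$state; wb$W <- upd$params$W; wb$b <- upd$params$b
        }
        z <- sweep(feats %*% wb$W, 2L, wb$b, "+")
        p <- softmax(z)
        ce <- -mean(log(pmax(p[cbind(seq_along(y), y)], 1e-12)))
        acc <- mean(max.col(p) == y)
        history <- bind_rows(history, tibble(
          epoch = ep, accuracy_pct = 100 * acc,
          loss_pct = 100 * ce / log(length(lv))))
      }
    })
  }
  backbone$weights[[head_name]] <- wb
  attr(backbone, "history") <- history
  attr(backbone, "classes") <- lv
  backbone
}

#' Extract features for a whole manifest
#'
#' Loads every image in the manifest, resizes to the backbone input if needed
#' and computes its feature vector, keeping CXR and CT tables separate.
#'
#' @param backbones Either one `qlung_backbone` used for both modalities or a
#'   named list `list(CXR = ..., CT = ...)`.
#' @param manifest Tibble with columns subject_id, modality, label, path.
#' @return A named list of two tibbles (`CXR`, `CT`), each with columns
#'   `subject_id`, `modality`, `label` then `f1 ... fD`.
#' @export
extract_dataset_features <- function(backbones, manifest) {
  if (inherits(backbones, "qlung_backbone")) {
    backbones <- list(CXR = backbones, CT = backbones)
  }
  stopifnot(all(c("subject_id", "modality", "label", "path") %in% names(manifest)))
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    if (!file.exists(r$path)) {
      abort_io(sprintf("manifest row %d: file '%s' not found", i, r$path))
    }
    bb <- backbones[[r$modality]]
    img <- load_grayscale(r$path, modality = r$modality,
                          subject_id = r$subject_id, label = r$label)
    if (img$height != bb$input_size) img <- resize_image(img, bb$input_size)
    rows[[i]] <- c(forward_features(bb, img))
  }
  out <- list()
  for (mod in c("CXR", "CT")) {
    sel <- which(manifest$modality == mod)
    if (length(sel) == 0L) next
    fm <- do.call(rbind, rows[sel])
    colnames(fm) <- paste0("f", seq_len(ncol(fm)))
    out[[mod]] <- bind_cols(
      manifest[sel, c("subject_id", "modality", "label")],
      as_tibble(fm)
    )
  }
  out
}

#' Feature matrix of a feature table
#'
#' @param tbl A feature tibble with `f1 ... fD` columns.
#' @return Numeric matrix (subjects x dims) with subject_id rownames.
#' @export
feature_matrix <- function(tbl) {
  fcols <- grep("^f[0-9]+$", names(tbl), value = TRUE)
  m <- as.matrix(tbl[, fcols])
  rownames(m) <- tbl$subject_id
  m
}

#' Named-layer contract of the large pretrained backbones
#'
#' Declared feature-extraction layers and dimensions of the six standard
#' pretrained networks the pipeline can sit on through an adapter; the
#' networks' weights are external artifacts and are not shipped.
#'
#' @return Tibble with columns model, feature_layer, feature_dim, fused_dim.
#' @export
pretrained_backbone_info <- function() {
  tibble(
    model = c("VGG16", "VGG19", "InceptionV3", "Xception", "ResNet50", "RepVGG"),
    feature_layer = c("Block5_conv3", "Block5_conv4", "mixed10",
                      "block14_sepconv2_act", "conv5_block3_out", "repvgg_block5"),
    feature_dim = c(512L, 512L, 2048L, 2048L, 2048L, 2048L),
    fused_dim = c(1024L, 1024L, 4096L, 4096L, 4096L, 4096L)
  )
}

#' Adapter for an externally computed feature extractor
#'
#' Wraps a user-supplied extractor function (e.g. calling out to a deep
#' learning framework) in the backbone contract: a declared feature layer
#' name and dimension plus a `forward_features`-compatible callable.
#'
#' @param model One of the [pretrained_backbone_info()] model names.
#' @param extractor Function `(image_sample) -> numeric(feature_dim)`, or
#'   `NULL` to declare dimensions only.
#' @return A `qlung_backbone_adapter`.
#' @export
pretrained_adapter <- function(model, extractor = NULL) {
  info <- pretrained_backbone_info()
  row <- info[info$model == model, ]
  if (nrow(row) != 1L) {
    abort_validation(sprintf("unknown pretrained model '%s'", model))
  }
  structure(
    list(model = model, feature_layer = row$feature_layer,
         feature_dim = row$feature_dim, extractor = extractor),
    class = "qlung_backbone_adapter"
  )
}
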