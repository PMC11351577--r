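#' Image sample container
#'
#' A minimal container for one grayscale chest image: an integer pixel matrix
#' with values in 1--255 plus its modality (`"CXR"` or `"CT"`), subject id and
#' class label.
#'
#' @param pixels Numeric matrix of gray levels; values are rounded and clamped
#'   into `[1, 255]`.
#' @param modality `"CXR"`, `"CT"` or `NA`.
#' @param subject_id Subject identifier string.
#' @param label One of `"normal"`, `"benign"`, `"malignant"` or `NA` when
#'   unknown.
#' @return An object of class `image_sample`.
#' @export
image_sample <- function(pixels, modality = NA_character_,
                         subject_id = NA_character_, label = NA_character_) {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    abort_validation("`pixels` must be a non-empty matrix.")
  }
  if (!is.na(modality) && !modality %in% c("CXR", "CT")) {
    abort_validation(sprintf("unknown modality '%s' (expected CXR or CT)", modality))
  }
  if (!is.na(label) && !label %in% lesion_classes()) {
    abort_validation(sprintf("unknown label '%s'", label))
  }
  px <- pmin(pmax(round(pixels), 1), 255)
  storage.mode(px) <- "integer"
  structure(
    list(pixels = px, width = ncol(px), height = nrow(px),
         modality = modality, subject_id = subject_id, label = label),
    class = "image_sample"
  )
}

#' @export
print.image_sample <- function(x, ...) {
  cat(sprintf("<image_sample> %dx%d %s subject=%s label=%s\n",
              x$height, x$width, x$modality, x$subject_id, x$label))
  invisible(x)
}

#' Class labels in canonical order
#' @return Character vector `c("normal", "benign", "malignant")`.
#' @export
lesion_classes <- function() c("normal", "benign", "malignant")

#' Load an image as clamped 8-bit grayscale
#'
#' Reads a PNG, collapses RGB to luminance (Rec. 601 weights), rescales to
#' 8-bit gray levels and clamps into the working range `[1, 255]` (a stored 0
#' becomes 1; in-range values are preserved exactly).
#'
#' @param path Path to a PNG file.
#' @inheritParams image_sample
#' @return An `image_sample`.
#' @export
load_grayscale <- function(path, modality = NA_character_,
                           subject_id = NA_character_, label = NA_character_) {
  if (!file.exists(path)) {
    abort_io(sprintf("cannot read image: file '%s' does not exist", path))
  }
  arr <- tryCatch(png::readPNG(path),
                  error = function(e) {
                    abort_io(sprintf("cannot decode '%s' as PNG: %s", path,
                                     conditionMessage(e)))
                  })
  if (length(arr) == 0L) abort_validation(sprintf("zero-sized image: '%s'", path))
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  image_sample(pmax(round(arr * 255), 1), modality = modality,
               subject_id = subject_id, label = label)
}

#' Write an image sample as an 8-bit grayscale PNG
#'
#' @param image An `image_sample`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grayscale <- function(image, path) {
  stopifnot(inherits(image, "image_sample"))
  ok <- tryCatch({
    png::writePNG(image$pixels / 255, target = path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_io(sprintf("cannot write image to '%s'", path))
  invisible(path)
}

#' Resize an image to a square target
#'
#' Bilinear resampling to `target` x `target` pixels, then re-clamped to the
#' `[1, 255]` gray range. The default target of 1024 pixels per side is the
#' pipeline's standard preprocessing resolution.
#'
#' @param image An `image_sample`.
#' @param target Pixels per side (>= 8), default 1024.
#' @return A resized `image_sample`.
#' @export
resize_image <- function(image, target = 1024L) {
  stopifnot(inherits(image, "image_sample"))
  target <- as.integer(target)
  if (is.na(target) || target < 8L) {
    abort_validation(sprintf("resize target must be >= 8 pixels, got %s", target))
  }
  if (image$height == target && image$width == target) return(image)
  px <- EBImage::resize(EBImage::Image(image$pixels / 255),
                        w = target, h = target)
  image_sample(pmin(pmax(round(EBImage::imageData(px) * 255), 1), 255),
               modality = image$modality, subject_id = image$subject_id,
               label = image$label)
}

#' Configuration for the paired-modality lung phantom generator
#'
#' The phantom emulates the statistical structure of a paired CXR/CT lesion
#' dataset: per subject one lesion latent (positions, radii, intensities) is
#' drawn and rendered twice -- once as a sharp-edged CT slice on a quiet
#' background, once as a projection-like CXR with Gaussian-softened lesions
#' over a rib-stripe background. Class structure is ordered: normal subjects
#' carry no lesions; malignant lesions are drawn larger, brighter and more
#' numerous than benign ones.
#'
#' @param n_subjects Number of subjects (each yields one CXR + one CT image).
#' @param image_size Pixels per side of the generated (square) images.
#' @param class_proportions Named nonnegative proportions for
#'   normal/benign/malignant; must sum to 1. Default mirrors a 500/500/1000
#'   split: `c(normal = 0.25, benign = 0.25, malignant = 0.5)`.
#' @param lesion_params Per-class list with `count` (integer range),
#'   `radius` (pixel range) and `intensity` (gray-level offset range).
#' @param noise_sd Gaussian pixel noise, gray levels.
#' @param seed Integer seed controlling the whole dataset draw.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_subjects = 300L,
                           image_size = 64L,
                           class_proportions = c(normal = 0.25, benign = 0.25,
                                                 malignant = 0.5),
                           lesion_params = list(
                             normal = list(count = c(0L, 0L), radius = c(0, 0),
                                           intensity = c(0, 0)),
                             benign = list(count = c(1L, 3L), radius = c(3, 5),
                                           intensity = c(40, 70)),
                             malignant = list(count = c(2L, 5L), radius = c(8, 12),
                                              intensity = c(80, 120))
                           ),
                           noise_sd = 8,
                           seed = 1L) {
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    abort_validation("class_proportions must sum to 1")
  }
  if (any(class_proportions < 0)) abort_validation("class_proportions must be nonnegative")
  if (!setequal(names(class_proportions), lesion_classes())) {
    abort_validation("class_proportions must be named normal/benign/malignant")
  }
  if (any(lesion_params$normal$count != 0L)) {
    abort_validation("normal class lesion count must be 0")
  }
  if (n_subjects < 1L) abort_validation("n_subjects must be >= 1")
  structure(
    list(n_subjects = as.integer(n_subjects), image_size = as.integer(image_size),
         class_proportions = class_proportions[lesion_classes()],
         lesion_params = lesion_params, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Draw a per-subject lesion latent
#'
#' The latent is the cross-modality ground truth shared by the CXR and CT
#' renderings of one subject: lesion centres, radii and intensity offsets.
#'
#' @param label Class label.
#' @param config A [phantom_config()].
#' @return A tibble with columns `x`, `y`, `radius`, `intensity` (possibly
#'   zero rows for the normal class).
#' @export
draw_lesion_latent <- function(label, config) {
  stopifnot(inherits(config, "phantom_config"))
  p <- config$lesion_params[[label]]
  n <- if (p$count[2] > p$count[1]) sample(p$count[1]:p$count[2], 1L) else p$count[1]
  if (n == 0L) {
    return(tibble(x = double(), y = double(), radius = double(),
                  intensity = double()))
  }
  sz <- config$image_size
  margin <- max(p$radius[2], 2)
  tibble(
    x = runif(n, margin + 1, sz - margin),
    y = runif(n, margin + 1, sz - margin),
    radius = runif(n, p$radius[1], p$radius[2]),
    intensity = runif(n, p$intensity[1], p$intensity[2])
  )
}

# Render one modality from a lesion latent. CT: sharp disks on a quiet dark
# background. CXR: the same lesions as Gaussian-softened blobs (projection
# blur) over a brighter rib-stripe background.
render_phantom <- function(latent, config, modality, subject_id, label) {
  sz <- config$image_size
  xs <- matrix(rep(seq_len(sz), each = sz), nrow = sz)   # column index
  ys <- matrix(rep(seq_len(sz), times = sz), nrow = sz)  # row index
  if (modality == "CT") {
    base <- matrix(40, sz, sz)
    noise_sd <- config$noise_sd / 2
  } else {
    base <- 90 + 18 * sin(2 * pi * ys / 9)  # rib stripes
    noise_sd <- config$noise_sd
  }
  img <- base
  if (nrow(latent) > 0) {
    for (i in seq_len(nrow(latent))) {
      d2 <- (xs - latent$x[i])^2 + (ys - latent$y[i])^2
      if (modality == "CT") {
        img <- img + latent$intensity[i] * (d2 <= latent$radius[i]^2)
      } else {
        s2 <- (latent$radius[i] / 1.3)^2
        img <- img + 0.8 * latent$intensity[i] * exp(-d2 / (2 * s2))
      }
    }
  }
  img <- img + rnorm(sz * sz, sd = noise_sd)
  image_sample(img, modality = modality, subject_id = subject_id, label = label)
}

#' Generate one paired CXR/CT phantom
#'
#' Both images are rendered from the same lesion latent so the cross-modality
#' pairing downstream fusion relies on is true by construction.
#'
#' @param latent Lesion latent from [draw_lesion_latent()].
#' @param config A [phantom_config()].
#' @param subject_id,label Metadata stamped on both images.
#' @return A list with elements `cxr` and `ct` (both `image_sample`).
#' @export
generate_phantom_pair <- function(latent, config, subject_id = "S1",
                                  label = "normal") {
  stopifnot(inherits(config, "phantom_config"))
  list(
    cxr = render_phantom(latent, config, "CXR", subject_id, label),
    ct  = render_phantom(latent, config, "CT", subject_id, label)
  )
}

# Deterministic largest-remainder apportionment of n subjects to classes.
class_counts <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a paired phantom dataset on disk
#'
#' Writes `2 * n_subjects` grayscale PNGs, a CSV manifest (one row per image:
#' `subject_id`, `modality`, `label`, `path`) and a JSON latent record holding
#' every subject's lesion ground truth. The whole draw is governed by
#' `config$seed` and is bit-reproducible.
#'
#' @param config A [phantom_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest tibble, invisibly carrying attribute `latents`.
#' @export
generate_phantom_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "phantom_config"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2) != 0) {
    abort_io(sprintf("output directory '%s' is not writable", out_dir))
  }
  counts <- class_counts(config$n_subjects, config$class_proportions)
  labels <- rep(lesion_classes(), counts)
  rows <- vector("list", config$n_subjects)
  latents <- list()
  with_seed(config$seed, {
    for (i in seq_len(config$n_subjects)) {
      sid <- sprintf("S%04d", i)
      latent <- draw_lesion_latent(labels[i], config)
      pair <- generate_phantom_pair(latent, config, subject_id = sid,
                                    label = labels[i])
      p_cxr <- file.path(out_dir, sprintf("%s_cxr.png", sid))
      p_ct <- file.path(out_dir, sprintf("%s_ct.png", sid))
      write_grayscale(pair$cxr, p_cxr)
      write_grayscale(pair$ct, p_ct)
      rows[[i]] <- tibble(
        subject_id = sid, modality = c("CXR", "CT"),
        label = labels[i], path = c(p_cxr, p_ct)
      )
      latents[[sid]] <- as.list(latent)
    }
  })
  manifest <- bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(latents, file.path(out_dir, "latents.json"),
                       digits = NA, auto_unbox = FALSE)
  attr(manifest, "latents") <- latents
  invisible(manifest)
}

#' Read a phantom dataset manifest
#'
#' @param path Path to `manifest.csv` or to the dataset directory.
#' @return Manifest tibble with columns subject_id, modality, label, path.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  if (!file.exists(path)) abort_io(sprintf("manifest '%s' not found", path))
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
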