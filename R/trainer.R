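#' Training configuration
#'
#' @param epochs Training epochs (default 30; `0` is an exact no-op).
#' @param batch_size Minibatch size (default 16).
#' @param learning_rate Adam learning rate (default 1e-3; `0` freezes all
#'   weights).
#' @param seed Root seed; every stage (split, initialization, shuffling)
#'   derives its own stream from it.
#' @param fractions Named train/val/test fractions, positive, summing to 1.
#' @param patience Optional early-stopping patience on training loss
#'   (`NULL` = off).
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 16L, learning_rate = 1e-3,
                         seed = 1L,
                         fractions = c(train = 0.7, val = 0.15, test = 0.15),
                         patience = NULL) {
  if (abs(sum(fractions) - 1) > 1e-9) abort_validation("fractions must sum to 1")
  if (any(fractions <= 0)) abort_validation("fractions must be positive")
  if (!setequal(names(fractions), c("train", "val", "test"))) {
    abort_validation("fractions must be named train/val/test")
  }
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = as.integer(seed),
         fractions = fractions[c("train", "val", "test")],
         optimizer = list(name = "adam", beta1 = 0.9, beta2 = 0.999, eps = 1e-8),
         patience = patience),
    class = "train_config"
  )
}

#' Stratified subject-level split
#'
#' @param subject_ids Subject identifiers (unique).
#' @param labels Class label per subject.
#' @param fractions Named train/val/test fractions.
#' @param seed Split seed.
#' @return Named list of subject-id character vectors (`train`, `val`,
#'   `test`).
#' @export
split_subjects <- function(subject_ids, labels, fractions, seed = 1L) {
  if (anyDuplicated(subject_ids)) abort_validation("subject_ids must be unique")
  out <- list(train = character(), val = character(), test = character())
  with_seed(seed, {
    for (cl in unique(labels)) {
      ids <- sample(subject_ids[labels == cl])
      n <- length(ids)
      n_val <- round(n * fractions[["val"]])
      n_test <- round(n * fractions[["test"]])
      n_train <- n - n_val - n_test
      out$train <- c(out$train, ids[seq_len(n_train)])
      out$val <- c(out$val, ids[n_train + seq_len(n_val)])
      out$test <- c(out$test, ids[n_train + n_val + seq_len(n_test)])
    }
  })
  out
}

# Shared pipeline for hybrid and traditional training; the two differ only in
# the `stage` ("quantum" vs "identity") between the scaled features and the
# dense head.
train_pipeline <- function(cxr, ct, config, stage) {
  stopifnot(inherits(config, "train_config"))
  fused <- merge_dataset(cxr, ct)
  y_all <- match(fused$label, lesion_classes())
  if (any(is.na(y_all))) abort_validation("unknown labels in feature tables")
  split <- split_subjects(fused$subject_id, fused$label, config$fractions,
                          seed = stage_seed(config$seed, "split"))
  tr <- fused$subject_id %in% split$train
  if (length(unique(fused$label[tr])) < 2L) {
    abort_validation("training split is degenerate: fewer than 2 classes")
  }
  fm <- feature_matrix(fused)
  projector <- fit_svd_projector(fm[tr, , drop = FALSE], n_components = 5L)
  qfeat <- sweep(fm, 2L, projector$mean, "-") %*% projector$basis
  scaler <- fit_scaler(qfeat[tr, , drop = FALSE])
  angles <- scale_angles(scaler, qfeat)

  n_layers <- if (stage == "quantum") 2L else 0L
  spec <- circuit_spec(n_qubits = 5L, n_var_layers = n_layers, scaler = scaler)
  theta <- if (stage == "quantum") {
    with_seed(stage_seed(config$seed, "circuit"),
              runif(length(spec$params), -0.1, 0.1))
  } else {
    numeric(0)
  }
  head <- dense_head(input_dim = 5L, seed = stage_seed(config$seed, "head"))

  stage_fwd <- function(a, th) {
    if (stage == "quantum") qforward_angles(spec, a, th) else a
  }

  a_tr <- angles[tr, , drop = FALSE]
  y_tr <- y_all[tr]
  history <- tibble(epoch = integer(), accuracy_pct = double(),
                    loss_pct = double())
  if (config$epochs > 0L && nrow(a_tr) > 0L) {
    flat <- flatten_params(head, theta)
    opt <- adam_init(flat, beta1 = config$optimizer$beta1,
                     beta2 = config$optimizer$beta2, eps = config$optimizer$eps)
    best_loss <- Inf; bad <- 0L
    with_seed(stage_seed(config$seed, "train"), {
      for (ep in seq_len(config$epochs)) {
        idx <- sample.int(nrow(a_tr))
        for (batch in split(idx, ceiling(seq_along(idx) / config$batch_size))) {
          ab <- a_tr[batch, , drop = FALSE]
          zb <- stage_fwd(ab, theta)
          hl <- head_loss_and_grads(head, zb, y_tr[batch])
          g <- list(theta = numeric(length(theta)))
          if (length(theta) > 0L) {
            gt <- numeric(length(theta))
            for (j in seq_along(theta)) {
              up <- theta; up[j] <- up[j] + pi / 2
              dn <- theta; dn[j] <- dn[j] - pi / 2
              jac <- (qforward_angles(spec, ab, up) -
                        qforward_angles(spec, ab, dn)) / 2
              gt[j] <- sum(hl$input_grad * jac)
            }
            g$theta <- gt
          }
          for (i in seq_along(head$W)) {
            g[[paste0("W", i)]] <- hl$grads$W[[i]]
            g[[paste0("b", i)]] <- hl$grads$b[[i]]
          }
          flat <- flatten_params(head, theta)
          upd <- adam_step(opt, flat, g, config$learning_rate)
          opt <- upd$state
          restored <- unflatten_params(upd$params, head)
          head <- restored$head; theta <- restored$theta
        }
        z_full <- stage_fwd(a_tr, theta)
        p_full <- head_forward(head, z_full)
        ce <- -mean(log(pmax(p_full[cbind(seq_along(y_tr), y_tr)], 1e-300)))
        acc <- mean(max.col(p_full) == y_tr)
        history <- bind_rows(history, tibble(
          epoch = ep, accuracy_pct = 100 * acc,
          loss_pct = 100 * ce / log(3)))
        if (!is.null(config$patience)) {
          if (ce < best_loss - 1e-9) { best_loss <- ce; bad <- 0L }
          else { bad <- bad + 1L; if (bad >= config$patience) break }
        }
      }
    })
  }
  spec$params <- theta
  structure(
    list(stage = stage, projector = projector, spec = spec, head = head,
         label_levels = lesion_classes(),
         n_quantum_params = length(theta),
         split = split, config = config, history = history,
         feature_dim = ncol(fm)),
    class = "qlung_model"
  )
}

flatten_params <- function(head, theta) {
  out <- list(theta = theta)
  for (i in seq_along(head$W)) {
    out[[paste0("W", i)]] <- head$W[[i]]
    out[[paste0("b", i)]] <- head$b[[i]]
  }
  out
}

unflatten_params <- function(flat, head) {
  for (i in seq_along(head$W)) {
    head$W[[i]] <- flat[[paste0("W", i)]]
    head$b[[i]] <- flat[[paste0("b", i)]]
  }
  list(head = head, theta = flat$theta)
}

#' Train the hybrid quantum-classical classifier
#'
#' Full pipeline fit in order: subject-level stratified split; CXR/CT fusion;
#' SVD projector and angle scaler fitted on the training split only;
#' minibatch Adam updates of the variational circuit parameters (by the
#' parameter-shift rule, chained through the head's input gradient) jointly
#' with the dense-head weights.
#'
#' @param cxr,ct Per-modality feature tibbles from
#'   [extract_dataset_features()].
#' @param config A [train_config()].
#' @return A `qlung_model`; its `$history` tibble has one row per epoch
#'   (`epoch`, `accuracy_pct`, `loss_pct`, both percentages; loss is
#'   cross-entropy normalized by `log(3)`).
#' @export
train_hybrid <- function(cxr, ct, config = train_config()) {
  train_pipeline(cxr, ct, config, stage = "quantum")
}

#' Train the no-quantum ablation baseline
#'
#' Identical pipeline, but the quantum stage is an identity pass-through of
#' the five scaled features into the same dense head; the model reports zero
#' quantum parameters.
#'
#' @inheritParams train_hybrid
#' @return A `qlung_model` with `stage == "identity"`.
#' @export
train_traditional <- function(cxr, ct, config = train_config()) {
  train_pipeline(cxr, ct, config, stage = "identity")
}

#' @export
print.qlung_model <- function(x, ...) {
  cat(sprintf("<qlung_model> stage=%s, %d fused dims -> 5 quantum features -> 3 classes\n",
              x$stage, x$projector$input_dim))
  cat(sprintf("quantum parameters: %d; epochs trained: %d\n",
              x$n_quantum_params, nrow(x$history)))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("final training accuracy %.2f%%, loss %.2f%%\n",
                last$accuracy_pct, last$loss_pct))
  }
  invisible(x)
}

#' Predict class probabilities for paired feature tables
#'
#' @param object A `qlung_model`.
#' @param cxr,ct Per-modality feature tibbles covering the same subjects.
#' @param ... Unused.
#' @return Tibble: `subject_id`, `label` (if present in the inputs),
#'   `p_normal`, `p_benign`, `p_malignant`, `pred`.
#' @export
predict.qlung_model <- function(object, cxr, ct, ...) {
  if (missing(ct)) abort_validation("both CXR and CT feature tables are required")
  fused <- merge_dataset(cxr, ct)
  fm <- feature_matrix(fused)
  qf <- sweep(fm, 2L, object$projector$mean, "-") %*% object$projector$basis
  angles <- scale_angles(object$spec$scaler, qf)
  z <- if (object$stage == "quantum") {
    qforward_angles(object$spec, angles, object$spec$params)
  } else {
    angles
  }
  p <- head_forward(object$head, z)
  colnames(p) <- paste0("p_", object$label_levels)
  out <- bind_cols(
    fused[, intersect(c("subject_id", "label"), names(fused))],
    as_tibble(p)
  )
  out$pred <- object$label_levels[max.col(p)]
  out
}

#' Save / load a trained model bundle
#'
#' The bundle is a single JSON manifest holding the projector, scaler,
#' circuit parameters and head weights at full double precision, so a
#' reloaded model reproduces predictions exactly.
#'
#' @param model A `qlung_model`.
#' @param dir Bundle directory (created if missing).
#' @return `save_model` returns `dir` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  j <- list(
    type = "qlung_model", stage = model$stage,
    n_quantum_params = model$n_quantum_params,
    label_levels = model$label_levels,
    feature_dim = model$feature_dim,
    projector = list(mean = model$projector$mean,
                     basis = as.numeric(model$projector$basis),
                     singular_values = model$projector$singular_values,
                     n_components = model$projector$n_components,
                     centered = model$projector$centered,
                     input_dim = model$projector$input_dim),
    scaler = list(min = model$spec$scaler$min, max = model$spec$scaler$max),
    circuit = list(n_qubits = model$spec$n_qubits,
                   n_var_layers = model$spec$n_var_layers,
                   embedding = model$spec$embedding,
                   entangler = model$spec$entangler,
                   params = model$spec$params),
    head = list(layer_sizes = model$head$layer_sizes,
                input_dim = model$head$input_dim,
                W = map(model$head$W, as.numeric),
                b = model$head$b,
                W_dims = map(model$head$W, dim)),
    split = model$split,
    config = list(epochs = model$config$epochs,
                  batch_size = model$config$batch_size,
                  learning_rate = model$config$learning_rate,
                  seed = model$config$seed,
                  fractions = as.list(model$config$fractions))
  )
  jsonlite::write_json(j, file.path(dir, "model.json"), digits = I(17),
                       auto_unbox = TRUE, null = "null")
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "model.json") else dir
  if (!file.exists(path)) abort_io(sprintf("model bundle '%s' not found", dir))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  projector <- structure(
    list(mean = as.numeric(j$projector$mean),
         basis = matrix(as.numeric(j$projector$basis),
                        ncol = j$projector$n_components),
         singular_values = as.numeric(j$projector$singular_values),
         n_components = as.integer(j$projector$n_components),
         centered = isTRUE(j$projector$centered),
         input_dim = as.integer(j$projector$input_dim)),
    class = "svd_projector")
  scaler <- structure(list(min = as.numeric(j$scaler$min),
                           max = as.numeric(j$scaler$max)),
                      class = "angle_scaler")
  spec <- circuit_spec(n_qubits = j$circuit$n_qubits,
                       n_var_layers = j$circuit$n_var_layers,
                       embedding = j$circuit$embedding,
                       entangler = j$circuit$entangler,
                       params = as.numeric(j$circuit$params),
                       scaler = scaler)
  wd <- j$head$W_dims
  if (is.matrix(wd)) wd <- lapply(seq_len(nrow(wd)), function(i) wd[i, ])
  j$head$W_dims <- wd
  head <- structure(
    list(W = map2(j$head$W, j$head$W_dims,
                  ~ matrix(as.numeric(.x), nrow = .y[1], ncol = .y[2])),
         b = map(j$head$b, as.numeric),
         layer_sizes = as.integer(j$head$layer_sizes),
         input_dim = as.integer(j$head$input_dim)),
    class = "dense_head")
  history_path <- file.path(dirname(path), "history.csv")
  history <- if (file.exists(history_path)) {
    as_tibble(utils::read.csv(history_path))
  } else {
    tibble(epoch = integer(), accuracy_pct = double(), loss_pct = double())
  }
  structure(
    list(stage = j$stage, projector = projector, spec = spec, head = head,
         label_levels = as.character(j$label_levels),
         n_quantum_params = as.integer(j$n_quantum_params),
         split = j$split,
         config = train_config(epochs = j$config$epochs,
                               batch_size = j$config$batch_size,
                               learning_rate = j$config$learning_rate,
                               seed = j$config$seed,
                               fractions = unlist(j$config$fractions)),
         history = history, feature_dim = as.integer(j$feature_dim)),
    class = "qlung_model"
  )
}
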