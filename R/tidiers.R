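#' Tidy the variational parameters of a trained model
#'
#' @param x A `qlung_model`.
#' @param ... Unused.
#' @return Tibble with one row per variational angle (`layer`, `qubit`,
#'   `angle`); zero rows for the identity-stage baseline.
#' @method tidy qlung_model
#' @export
tidy.qlung_model <- function(x, ...) {
  n_q <- x$spec$n_qubits
  n_l <- x$spec$n_var_layers
  if (n_l == 0L) {
    return(tibble(layer = integer(), qubit = integer(), angle = double()))
  }
  tibble(
    layer = rep(seq_len(n_l), each = n_q),
    qubit = rep(0:(n_q - 1L), times = n_l),
    angle = x$spec$params
  )
}

#' One-row model summary
#'
#' @param x A `qlung_model`.
#' @param ... Unused.
#' @return Tibble: stage, fused feature dim, quantum parameter count, epochs
#'   trained, final training accuracy and loss (percent).
#' @method glance qlung_model
#' @export
glance.qlung_model <- function(x, ...) {
  last <- if (nrow(x$history)) x$history[nrow(x$history), ] else
    tibble(accuracy_pct = NA_real_, loss_pct = NA_real_)
  tibble(
    stage = x$stage,
    feature_dim = x$feature_dim,
    n_quantum_params = x$n_quantum_params,
    epochs_trained = nrow(x$history),
    final_accuracy_pct = last$accuracy_pct,
    final_loss_pct = last$loss_pct
  )
}

#' Tidy an evaluation report
#'
#' @param x A `qlung_eval`.
#' @param ... Unused.
#' @return Long tibble (`metric`, `value`).
#' @method tidy qlung_eval
#' @export
tidy.qlung_eval <- function(x, ...) {
  m <- x$metrics
  tibble(
    metric = c("accuracy", "sensitivity", "specificity", "precision", "f1",
               "mcc", "auc"),
    value = c(m$accuracy, m$sensitivity, m$specificity, m$precision, m$f1,
              m$mcc, if (is.null(x$roc)) NA_real_ else x$roc$auc)
  )
}

#' @rdname tidy.qlung_eval
#' @method glance qlung_eval
#' @export
glance.qlung_eval <- function(x, ...) {
  bind_cols(x$metrics,
            tibble(auc = if (is.null(x$roc)) NA_real_ else x$roc$auc,
                   positive_class = x$positive_class))
}

#' Tidy an SVD projector's spectrum
#'
#' @param x An `svd_projector`.
#' @param ... Unused.
#' @return Tibble (`component`, `singular_value`, `energy_fraction`).
#' @method tidy svd_projector
#' @export
tidy.svd_projector <- function(x, ...) {
  s2 <- x$singular_values^2
  tibble(component = seq_along(x$singular_values),
         singular_value = x$singular_values,
         energy_fraction = if (sum(s2) > 0) s2 / sum(s2) else 0 * s2)
}

#' Plot a training history
#'
#' @param object A `qlung_model` (its history is plotted).
#' @param ... Unused.
#' @return A ggplot: accuracy and loss (percent) against epoch.
#' @method autoplot qlung_model
#' @export
autoplot.qlung_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("accuracy_pct", "loss_pct"),
                           names_to = "series", values_to = "percent")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$percent,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "%", colour = NULL,
                  title = sprintf("Training history (%s stage)", object$stage)) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object A `qlung_roc`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve with its AUC in the subtitle.
#' @method autoplot qlung_roc
#' @export
autoplot.qlung_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate (1 - specificity)",
                  y = "true positive rate (sensitivity)",
                  subtitle = sprintf("AUC = %.4f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation's confusion matrix
#'
#' @param object A `qlung_eval`.
#' @param ... Unused.
#' @return A ggplot tile map of the 3x3 confusion matrix.
#' @method autoplot qlung_eval
#' @export
autoplot.qlung_eval <- function(object, ...) {
  d <- as.data.frame(as.table(object$confusion))
  names(d) <- c("true", "predicted", "n")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$true,
                                  fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = "Confusion matrix (rows = true class)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
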