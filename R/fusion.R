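#' Fuse one subject's CXR and CT feature vectors
#'
#' Cross-modality fusion is order-preserving concatenation with the CXR block
#' first; the split index is recorded so the fusion is losslessly invertible.
#'
#' @param fx CXR feature vector (as returned by [forward_features()], or any
#'   numeric vector with attributes `modality` and `subject_id`).
#' @param fct CT feature vector for the same subject.
#' @return Numeric vector of length `length(fx) + length(fct)` with attributes
#'   `subject_id` and `split_index`.
#' @export
merge_features <- function(fx, fct) {
  mx <- attr(fx, "modality") %||% "CXR"
  mct <- attr(fct, "modality") %||% "CT"
  if (!identical(mx, "CXR") || !identical(mct, "CT")) {
    abort_validation(sprintf(
      "modality mismatch: expected (CXR, CT), got (%s, %s)", mx, mct))
  }
  sx <- attr(fx, "subject_id"); sct <- attr(fct, "subject_id")
  if (!is.null(sx) && !is.null(sct) && !is.na(sx) && !is.na(sct) &&
      !identical(sx, sct)) {
    abort_validation(sprintf(
      "subject mismatch: CXR vector is '%s', CT vector is '%s'", sx, sct))
  }
  structure(c(as.numeric(fx), as.numeric(fct)),
            subject_id = sx %||% sct, split_index = length(fx))
}

#' Fuse the CXR and CT feature tables of a dataset
#'
#' Pairs rows by `subject_id` and concatenates the feature blocks, CXR first.
#' Subjects missing from either table are reported by id, never dropped
#' silently.
#'
#' @param cxr,ct Feature tibbles from [extract_dataset_features()] (columns
#'   `subject_id`, `label`, `f1 ... fD`).
#' @return A fused tibble (`subject_id`, `label`, `f1 ... f(Dx+Dct)`), rows in
#'   canonical (sorted) subject order, with attribute `split_index`.
#' @export
merge_dataset <- function(cxr, ct) {
  missing_ct <- setdiff(cxr$subject_id, ct$subject_id)
  missing_cxr <- setdiff(ct$subject_id, cxr$subject_id)
  if (length(missing_ct) || length(missing_cxr)) {
    abort_validation(paste0(
      "unpaired subjects: ",
      if (length(missing_ct)) paste0("missing CT for [",
        paste(missing_ct, collapse = ", "), "] ") else "",
      if (length(missing_cxr)) paste0("missing CXR for [",
        paste(missing_cxr, collapse = ", "), "]") else ""))
  }
  if (anyDuplicated(cxr$subject_id) || anyDuplicated(ct$subject_id)) {
    abort_validation("duplicate subject_id rows in a feature table")
  }
  ord <- order(cxr$subject_id)
  cxr <- cxr[ord, ]
  ct <- ct[match(cxr$subject_id, ct$subject_id), ]
  mx <- feature_matrix(cxr)
  mct <- feature_matrix(ct)
  fused <- cbind(mx, mct)
  colnames(fused) <- paste0("f", seq_len(ncol(fused)))
  out <- bind_cols(cxr[, c("subject_id", "label")], as_tibble(fused))
  attr(out, "split_index") <- ncol(mx)
  out
}

#' Undo a fusion at its recorded split index
#'
#' @param fused A fused vector from [merge_features()] or tibble from
#'   [merge_dataset()].
#' @return A list with elements `cxr` and `ct`.
#' @export
unmerge <- function(fused) {
  k <- attr(fused, "split_index")
  if (is.null(k)) abort_validation("input carries no split_index attribute")
  if (is.data.frame(fused)) {
    m <- feature_matrix(fused)
    list(cxr = m[, seq_len(k), drop = FALSE],
         ct = m[, (k + 1):ncol(m), drop = FALSE])
  } else {
    list(cxr = as.numeric(fused[seq_len(k)]),
         ct = as.numeric(fused[(k + 1):length(fused)]))
  }
}
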