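#' Reconstruct a stimulus image from a voxel response vector
#'
#' End-to-end inference: mask the response vector to the selected voxels,
#' predict the two class capsules with the mapper, take the longer capsule
#' (ties resolve to the lower class label and are flagged), and decode it
#' with the capsule network's reconstruction decoder.
#'
#' @param voxel_vector full-length voxel response vector (length V).
#' @param selection a [select_top_k()] selection over the V voxels.
#' @param mapper a trained [train_mapper()] model.
#' @param capsnet a trained [train_capsnet()] model (frozen decoder).
#' @param true_capsule optional 16-vector of the item's true capsule
#'   features; when given, the "theoretical" reconstruction (decode of the
#'   true capsule, the method's upper limit) is included.
#' @return An object of class `"reconstruction"`: `predicted_capsules`
#'   (`2 x 16`), `chosen_class`, `tie` flag, `image` (side^2 pixel vector in
#'   `(0,1)`), and optionally `theoretical` (pixel vector).
#' @export
reconstruct_from_fmri <- function(voxel_vector, selection, mapper, capsnet,
                                  true_capsule = NULL) {
  if (length(voxel_vector) < max(selection$selected))
    stop("voxel vector (length ", length(voxel_vector),
         ") is shorter than the selection's voxel space (stage: selection)")
  x <- voxel_vector[selection$selected]
  if (length(x) != nrow(mapper$params$W1))
    stop("selection keeps ", length(x), " voxels but the mapper expects ",
         nrow(mapper$params$W1), " (stage: mapper)")
  if (ncol(mapper$params$W3) != capsnet$config$n_classes * capsnet$config$digit_dim)
    stop("mapper output (", ncol(mapper$params$W3), ") does not match ",
         capsnet$config$n_classes, " x ", capsnet$config$digit_dim,
         " capsules (stage: decoder)")
  caps <- predict_capsules(mapper, x)
  norms <- sqrt(rowSums(caps^2))
  j <- which.max(norms)            # first index wins exact ties
  tie <- length(unique(norms)) < length(norms)
  img <- decode_capsule(capsnet, caps[j, ])
  out <- list(predicted_capsules = caps,
              chosen_class = capsnet$config$classes[j], tie = tie,
              image = img)
  if (!is.null(true_capsule))
    out$theoretical <- decode_capsule(capsnet, as.numeric(true_capsule))
  structure(out, class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("<reconstruction> chosen class %s%s; capsule norms %s\n",
              x$chosen_class, if (x$tie) " (tie)" else "",
              paste(sprintf("%.3f", sqrt(rowSums(x$predicted_capsules^2))),
                    collapse = ", ")))
  invisible(x)
}

#' Cross-validated reconstruction evaluation
#'
#' The capsule network (stage 1) is trained on separate stimulus material
#' and shared across folds; per fold, the encoding fit, voxel selection and
#' mapper (stages 2-3) are refit on the training items only and the held-out
#' items are reconstructed and scored with MSE, PCC and SSIM — both for the
#' fMRI path and for the theoretical (true-capsule) path.
#'
#' @param study a `synthetic_study` (or any list with `voxels`, `images`,
#'   `labels`).
#' @param capsnet trained `capsnet_model` used for true capsules and
#'   decoding.
#' @param k number of folds (default 10).
#' @param seed seed for the fold split and mapper training.
#' @param n_select voxels to retain per fold (default 100).
#' @param mapper_cfg a [mapper_config()]; its seed is offset per fold.
#' @param global_selection refit selection on all items once (mimicking a
#'   protocol without per-fold refit) instead of per training fold.
#' @return An object of class `"metrics_report"`: `per_item` data frame
#'   (item, fold, label, chosen_class, MSE, PCC, SSIM, and theoretical
#'   counterparts), `means`, `theoretical_means`, `fold`.
#' @export
crossvalidate <- function(study, capsnet, k = 10L, seed = 1L,
                          n_select = 100L, mapper_cfg = NULL,
                          global_selection = FALSE) {
  if (is.null(study$images)) stop("study carries no images to score against")
  n <- nrow(study$voxels)
  mcfg <- mapper_cfg %||% mapper_config()
  fold <- split_folds(n, k, labels = study$labels, seed = seed)
  pr <- predict_capsnet(capsnet, study$images)
  feats <- longer_capsule_features(pr$capsules)
  rows <- vector("list", n)
  glob_sel <- if (global_selection)
    select_top_k(fit_voxel_encoding(feats, study$voxels), n_select) else NULL
  for (f in sort(unique(fold))) {
    tr <- which(fold != f); te <- which(fold == f)
    sel <- glob_sel %||%
      select_top_k(fit_voxel_encoding(feats[tr, , drop = FALSE],
                                      study$voxels[tr, , drop = FALSE]),
                   n_select)
    mcfg_f <- mcfg
    mcfg_f$seed <- mcfg$seed + f
    mapper <- train_mapper(study$voxels[tr, sel$selected, drop = FALSE],
                           pr$capsules[tr, , , drop = FALSE], mcfg_f)
    for (i in te) {
      rec <- reconstruct_from_fmri(study$voxels[i, ], sel, mapper, capsnet,
                                   true_capsule = feats[i, ])
      img <- study$images[i, ]
      rows[[i]] <- data.frame(
        item = i, fold = f, label = study$labels[i],
        chosen_class = rec$chosen_class,
        MSE = mse_metric(img, rec$image),
        PCC = pcc_metric(img, rec$image),
        SSIM = ssim_metric(img, rec$image),
        MSE_theoretical = mse_metric(img, rec$theoretical),
        PCC_theoretical = pcc_metric(img, rec$theoretical),
        SSIM_theoretical = ssim_metric(img, rec$theoretical))
    }
  }
  per_item <- do.call(rbind, rows)
  means <- colMeans(per_item[, c("MSE", "PCC", "SSIM")])
  tmeans <- colMeans(per_item[, c("MSE_theoretical", "PCC_theoretical",
                                  "SSIM_theoretical")])
  names(tmeans) <- c("MSE", "PCC", "SSIM")
  structure(list(per_item = per_item, means = means,
                 theoretical_means = tmeans, fold = fold,
                 class_accuracy = mean(per_item$chosen_class == per_item$label)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> cross-validated reconstruction\n")
  m <- rbind(`fMRI path` = x$means, theoretical = x$theoretical_means)
  print(round(m, 4))
  cat(sprintf("class recovery: %.1f%%\n", 100 * x$class_accuracy))
  invisible(x)
}
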