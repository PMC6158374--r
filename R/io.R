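# Shared on-disk conventions: a "study" is a directory of CSV matrices plus
# a JSON manifest; a model checkpoint is a JSON manifest (type, config,
# parameter names/dims, seeds) plus one flat little-endian double payload.
# (No HDF5 binding is available to R in this environment; the named-array +
# sidecar contract is kept, the serialization is CSV/JSON + raw doubles.)

.write_mat_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
}

.read_mat_csv <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' Write / read a study container
#'
#' Serializes a `synthetic_study` (or compatible list) to a directory:
#' `voxels.csv`, `images.csv`, `true_capsules.csv`, `encoding_weights.csv`
#' and a `study.json` manifest holding labels, informative indices, noise
#' scales, seeds and the container hash.
#'
#' @param study a `synthetic_study`.
#' @param dir target directory (created if needed).
#' @return `dir` (invisibly) for `write_study`; a `synthetic_study` for
#'   `read_study`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_mat_csv(study$voxels, file.path(dir, "voxels.csv"))
  if (!is.null(study$images))
    .write_mat_csv(study$images, file.path(dir, "images.csv"))
  if (!is.null(study$true_capsules))
    .write_mat_csv(study$true_capsules, file.path(dir, "true_capsules.csv"))
  if (!is.null(study$encoding_weights))
    .write_mat_csv(study$encoding_weights, file.path(dir, "encoding_weights.csv"))
  meta <- list(labels = study$labels, intercepts = study$intercepts,
               informative_idx = study$informative_idx,
               noise_sd = study$noise_sd, snr_r2 = study$snr_r2,
               seed = study$seed)
  jsonlite::write_json(meta, file.path(dir, "study.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  if (!file.exists(file.path(dir, "study.json")))
    stop("no study container at '", dir, "' (study.json missing)")
  meta <- jsonlite::read_json(file.path(dir, "study.json"), simplifyVector = TRUE)
  rd <- function(f) if (file.exists(file.path(dir, f)))
    .read_mat_csv(file.path(dir, f)) else NULL
  structure(list(voxels = rd("voxels.csv"), images = rd("images.csv"),
                 true_capsules = rd("true_capsules.csv"),
                 encoding_weights = rd("encoding_weights.csv"),
                 intercepts = meta$intercepts,
                 informative_idx = as.integer(meta$informative_idx %||% integer(0)),
                 noise_sd = meta$noise_sd, snr_r2 = meta$snr_r2,
                 seed = meta$seed, labels = meta$labels),
            class = "synthetic_study")
}

# rebuild a classed config from a plain JSON list, keeping only known formals
.config_revive <- function(lst, constructor) {
  keep <- intersect(names(lst), names(formals(constructor)))
  do.call(constructor, lst[keep])
}

#' Save / load a model checkpoint
#'
#' Writes `manifest.json` (model type, configuration, parameter names and
#' dimensions, seed, payload hash) and `weights.bin` (all parameters
#' concatenated as little-endian doubles in manifest order).  Works for both
#' `capsnet_model` and `mapper_model`; round trips are exact.
#'
#' @param model a `capsnet_model` or `mapper_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir` (invisibly) for `save_checkpoint`; the model for
#'   `load_checkpoint`.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  type <- class(model)[1]
  stopifnot(type %in% c("capsnet_model", "mapper_model"))
  theta <- unlist(model$params, use.names = FALSE)
  if (type == "mapper_model")  # doubles belong in the binary payload
    theta <- c(theta, model$center, model$scale)
  manifest <- list(
    type = type,
    params = lapply(model$params, function(p) as.integer(dim(p) %||% length(p))),
    config = unclass(model$config),
    extra = switch(type,
      capsnet_model = list(seed = model$seed, trace = model$trace),
      mapper_model = list(n_inputs = length(model$center),
                          digit_dim = model$digit_dim)),
    n_values = length(theta),
    checksum = fnv1a_hash(paste(format(sum(theta), digits = 17),
                                format(sum(abs(theta)), digits = 17))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(dir, "weights.bin"), "wb")
  on.exit(close(con))
  writeBin(theta, con, size = 8L, endian = "little")
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path))
    stop("no checkpoint at '", dir, "' (manifest.json missing)")
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  con <- file(file.path(dir, "weights.bin"), "rb")
  on.exit(close(con))
  theta <- readBin(con, "double", n = mf$n_values, size = 8L,
                   endian = "little")
  if (length(theta) != mf$n_values)
    stop("checkpoint payload truncated: expected ", mf$n_values, " doubles")
  skel <- lapply(mf$params, function(d) as.integer(d))
  n_par <- sum(vapply(skel, prod, numeric(1)))
  params <- .unflatten_params(theta[seq_len(n_par)], skel)
  if (mf$type == "capsnet_model") {
    cfg <- .config_revive(mf$config, capsnet_config)
    structure(list(config = cfg, params = params,
                   trace = mf$extra$trace, seed = mf$extra$seed),
              class = "capsnet_model")
  } else {
    cfg <- .config_revive(mf$config, mapper_config)
    n_in <- as.integer(mf$extra$n_inputs)
    structure(list(params = params, config = cfg,
                   center = theta[n_par + seq_len(n_in)],
                   scale = theta[n_par + n_in + seq_len(n_in)],
                   digit_dim = as.integer(mf$extra$digit_dim),
                   trace = NULL),
              class = "mapper_model")
  }
}

#' Export images as a PNG grid
#'
#' Lays out image rows (e.g. stimulus / theoretical / fMRI-path
#' reconstructions) as a grid of grayscale panels.  Requires a PNG-capable
#' graphics device; errors with guidance otherwise.
#'
#' @param rows a list of image matrices (`n x side^2` each); one grid row
#'   per element.
#' @param path output `.png` path.
#' @param scale pixel magnification per image.
#' @return `path`, invisibly.
#' @export
export_png_grid <- function(rows, path, scale = 4L) {
  if (!capabilities("png"))
    stop("this R build has no PNG device; export the pixel CSVs instead")
  n <- nrow(rows[[1]])
  side <- as.integer(sqrt(ncol(rows[[1]])))
  grDevices::png(path, width = n * side * scale,
                 height = length(rows) * side * scale)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(rows), n), mar = rep(0.05, 4))
  for (r in rows) for (i in seq_len(n)) {
    m <- matrix(r[i, ], side, side)
    graphics::image(t(m[side:1, ]), col = grDevices::gray(seq(0, 1, length = 256)),
                    axes = FALSE, useRaster = TRUE, zlim = c(0, 1))
  }
  invisible(path)
}
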