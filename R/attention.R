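# Attention-map export: per-layer temporal attention (raw and masked,
# averaged over heads and channels), the learned mask, and the spatial
# inter-channel map, written as an array bundle plus PNG heatmaps.

heatmap_png <- function(m, path, main) {
  grDevices::png(path, width = 480, height = 440)
  on.exit(grDevices::dev.off())
  graphics::image(t(m)[, nrow(m):1, drop = FALSE], axes = FALSE, main = main,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
  graphics::box()
}

#' Export attention maps for selected epochs
#'
#' Runs a forward pass with attention collection on the selected epochs and
#' writes, per layer, the head- and channel-averaged raw and masked
#' temporal attention (P x P), the learned mask, and the epoch-averaged
#' spatial attention map (C x C), as an array bundle (`attention.json` /
#' `attention.bin`) plus one PNG heatmap per matrix.
#'
#' @param model a trained `eeg_transformer`.
#' @param epochs an [eeg_epochs()]; all selected epochs are processed in
#'   one forward batch.
#' @param out_dir output directory (created if missing).
#' @param select integer epoch indices (default: first epoch).
#' @return Named list of the exported matrices, invisibly.
#' @export
export_attention <- function(model, epochs, out_dir, select = 1L) {
  stopifnot(inherits(model, "eeg_transformer"))
  if (length(select) == 0L) stop("empty epoch selection", call. = FALSE)
  d <- dim(epochs$epochs)
  if (any(select < 1L | select > d[1L]))
    stop("epoch selection out of range", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sub <- epochs[select]
  pr <- predict_model(model, sub, batch_size = length(select),
                      collect_attention = TRUE)
  at <- pr$attention
  mats <- list()
  for (l in seq_along(at$temporal)) {
    # average over heads and sequences (epochs x channels)
    mats[[sprintf("layer%02d_temporal_raw", l)]] <-
      apply(at$temporal[[l]]$raw, c(1L, 2L), mean)
    mats[[sprintf("layer%02d_temporal_masked", l)]] <-
      apply(at$temporal[[l]]$masked, c(1L, 2L), mean)
    mats[[sprintf("layer%02d_mask", l)]] <- at$temporal[[l]]$mask
  }
  mats[["spatial"]] <- apply(at$spatial, c(1L, 2L), mean)
  write_array_bundle(mats, file.path(out_dir, "attention"),
                     meta = list(epochs = select, classes = model$classes))
  for (nm in names(mats))
    heatmap_png(mats[[nm]], file.path(out_dir, paste0(nm, ".png")), nm)
  invisible(mats)
}
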