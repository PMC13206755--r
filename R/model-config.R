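#' Architecture configuration
#'
#' Collects every architecture hyperparameter of the segmentation network.
#' The `"canonical"` preset reproduces the published geometry: a ViT-large
#' encoder (24 blocks, embedding 1024, 16 heads, 16x16 patches on a 224
#' canvas), bottleneck adapters with 128 middle channels in every block, a
#' 2-block mask-transformer decoder (dim 1024, 16 heads), skip taps after
#' encoder blocks 6/12/18/24 projected to 64 channels, and a 4-stage
#' progressive-upsampling post-adapter. The `"tiny"` preset keeps the same
#' 224/16 geometry but shrinks widths (embedding 64, 4 blocks, 4 heads,
#' adapter mid 16, decoder dim 64, skip and pre-adapter widths 8) so the
#' whole network runs forward and backward in seconds on one CPU; it exists
#' for tests and experimentation, not for accuracy claims.
#'
#' @param preset `"canonical"` or `"tiny"`.
#' @param ... named overrides of individual fields (e.g. `num_classes = 2`,
#'   `unfreeze_last_n = 2`, `use_skips = FALSE`).
#' @return an object of class `fundseg_config` (a validated named list).
#' @details Fields: `patch_size`, `canvas_size`, `embed_dim`, `depth`,
#'   `num_heads`, `adapter_mid`, `decoder_depth`, `decoder_dim`,
#'   `decoder_heads`, `skip_taps` (4 strictly increasing encoder layer
#'   indices), `skip_channels`, `pre_adapter_mid`, `num_classes` (2 for
#'   OD-only, 3 for joint OD/OC), `input_size`, `norm_kind`
#'   (`"batch"`/`"group"`), toggles `use_pre_adapter`, `use_post_adapter`,
#'   `use_skips`, `use_block_adapters`, and `unfreeze_last_n`.
#' @export
#' @examples
#' cfg <- model_config("tiny", num_classes = 3)
#' cfg$grid_size
model_config <- function(preset = c("canonical", "tiny"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    patch_size = 16L, canvas_size = 224L,
    embed_dim = 1024L, depth = 24L, num_heads = 16L, adapter_mid = 128L,
    decoder_depth = 2L, decoder_dim = 1024L, decoder_heads = 16L,
    skip_taps = c(6L, 12L, 18L, 24L), skip_channels = 64L,
    pre_adapter_mid = 64L,
    num_classes = 3L, input_size = 256L, norm_kind = "batch",
    use_pre_adapter = TRUE, use_post_adapter = TRUE, use_skips = TRUE,
    use_block_adapters = TRUE, unfreeze_last_n = 0L)
  if (preset == "tiny") {
    cfg[c("embed_dim", "depth", "num_heads", "adapter_mid", "decoder_dim",
          "decoder_heads", "skip_channels", "pre_adapter_mid", "input_size")] <-
      list(64L, 4L, 4L, 16L, 64L, 4L, 8L, 8L, 128L)
    cfg$skip_taps <- c(1L, 2L, 3L, 4L)
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stopf("unknown model_config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$preset <- preset
  validate_config(cfg)
}

validate_config <- function(cfg) {
  int_fields <- c("patch_size", "canvas_size", "embed_dim", "depth",
                  "num_heads", "adapter_mid", "decoder_depth", "decoder_dim",
                  "decoder_heads", "skip_channels", "pre_adapter_mid",
                  "num_classes", "input_size", "unfreeze_last_n")
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  cfg$skip_taps <- as.integer(cfg$skip_taps)
  if (cfg$canvas_size %% cfg$patch_size != 0)
    stopf("canvas_size (%d) must be divisible by patch_size (%d)",
          cfg$canvas_size, cfg$patch_size)
  cfg$grid_size <- cfg$canvas_size %/% cfg$patch_size
  stages <- log2(cfg$canvas_size / cfg$grid_size)
  if (abs(stages - round(stages)) > 1e-9 || stages < 1)
    stopf(paste0("configuration error: log2(canvas_size / grid_size) = %.3f ",
                 "must be a positive integer (number of post-adapter ",
                 "doubling stages)"), stages)
  cfg$n_stages <- as.integer(round(stages))
  if (!cfg$num_classes %in% c(2L, 3L))
    stopf("num_classes must be 2 (OD-only) or 3 (joint OD/OC), got %d",
          cfg$num_classes)
  if (length(cfg$skip_taps) != 4L)
    stopf("skip_taps must list exactly 4 encoder layers")
  if (any(diff(cfg$skip_taps) <= 0))
    stopf("skip_taps must be strictly increasing")
  if (max(cfg$skip_taps) > cfg$depth)
    stopf("skip_taps max (%d) exceeds encoder depth (%d)",
          max(cfg$skip_taps), cfg$depth)
  if (!cfg$norm_kind %in% c("batch", "group"))
    stopf("norm_kind must be 'batch' or 'group'")
  if (cfg$embed_dim %% cfg$num_heads != 0)
    stopf("embed_dim must be divisible by num_heads")
  if (cfg$decoder_dim %% cfg$decoder_heads != 0)
    stopf("decoder_dim must be divisible by decoder_heads")
  if (cfg$unfreeze_last_n < 0 || cfg$unfreeze_last_n > cfg$depth)
    stopf("unfreeze_last_n must be in [0, depth]")
  structure(cfg, class = "fundseg_config")
}

#' @method print fundseg_config
#' @export
print.fundseg_config <- function(x, ...) {
  cat(sprintf("<fundseg_config> %s: ViT %dx%d/%d, depth %d, K=%d, input %d\n",
              x$preset %||% "custom", x$embed_dim, x$num_heads, x$patch_size,
              x$depth, x$num_classes, x$input_size))
  invisible(x)
}
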