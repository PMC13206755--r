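# Saving/loading model weights and importing pretrained encoder checkpoints
# with MAE/ViT-large style parameter names.

#' Save model weights
#'
#' Writes all parameter values (an `.rds` of a named list) plus a JSON
#' sidecar holding the full architecture configuration and the
#' tunable-parameter count.
#'
#' @param model a `fundseg_model`.
#' @param path weights file path (`.rds`); the sidecar is `<path>.json`.
#' @return invisibly, `path`.
#' @export
norm_layers <- function(model) {
  Filter(function(l) identical(l$type, "norm2d"),
         collect_layers(model$layers))
}

save_weights <- function(model, path) {
  vals <- lapply(model$params, function(p) p$value)
  running <- lapply(norm_layers(model), function(l)
    list(mean = l$run_mean, var = l$run_var))
  saveRDS(list(values = vals, running = running), path)
  cfg <- model$config
  class(cfg) <- NULL
  jsonlite::write_json(
    list(config = cfg,
         tunable_parameters = count_tunable_parameters(model)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load weights into a model
#'
#' @param model a `fundseg_model` with matching geometry.
#' @param path weights file written by [save_weights()].
#' @return the model (parameters are updated in place).
#' @export
load_weights <- function(model, path) {
  stored <- readRDS(path)
  vals <- stored$values
  miss <- setdiff(names(model$params), names(vals))
  if (length(miss)) stopf("weights file lacks parameter(s): %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    v <- vals[[nm]]
    if (length(v) != length(p$value))
      stopf("parameter '%s': stored size %d does not match model size %d",
            nm, length(v), length(p$value))
    p$value <- v
  }
  nl <- norm_layers(model)
  for (nm in intersect(names(nl), names(stored$running))) {
    nl[[nm]]$run_mean <- stored$running[[nm]]$mean
    nl[[nm]]$run_var <- stored$running[[nm]]$var
  }
  model
}

#' Restore a saved model
#'
#' Rebuilds the architecture from the JSON sidecar and loads the weights.
#'
#' @param path weights file path written by [save_weights()].
#' @return a `fundseg_model`.
#' @export
load_model <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- side$config
  cfg$skip_taps <- as.integer(cfg$skip_taps)
  pres <- cfg$preset
  cfg$preset <- NULL; cfg$grid_size <- NULL; cfg$n_stages <- NULL
  m <- build_model(do.call(model_config,
                           c(list(preset = pres %||% "canonical"), cfg)))
  load_weights(m, path)
}

# convert a torch-layout conv kernel [out, in, kh, kw] to our patch matrix
torch_patch_to_matrix <- function(w) {
  d <- dim(w)
  Dm <- d[1]; C <- d[2]; k <- d[3]
  out <- matrix(0, k * k * C, Dm)
  for (dd in seq_len(Dm))
    out[, dd] <- as.vector(aperm(array(w[dd, , , ], c(C, k, k)), c(2, 3, 1)))
  out
}

#' Import pretrained encoder weights
#'
#' Accepts an `.rds` checkpoint holding a named list with MAE/ViT-large
#' style names (`patch_embed.proj.weight`, `pos_embed`, `blocks.<i>.*`,
#' `norm.*`; torch layouts: linear weights `[out, in]`, patch-embedding
#' kernel `[out, in, k, k]`, `pos_embed` `[1, 1+T, D]` with a class token
#' that is dropped). Positional embeddings for a non-canonical grid are
#' bicubically interpolated at load time. Adapter/decoder weights absent
#' from the checkpoint stay at their initialization; a report of matched
#' and unmatched names is attached and messaged.
#'
#' @param model a `fundseg_model`.
#' @param checkpoint path to the `.rds` checkpoint (or the list itself).
#' @return the model, with attribute `"import_report"`.
#' @export
import_encoder_weights <- function(model, checkpoint) {
  ck <- if (is.character(checkpoint)) readRDS(checkpoint) else checkpoint
  cfg <- model$config
  matched <- character(0); unmatched <- character(0)
  grab <- function(nm) { matched <<- c(matched, nm); ck[[nm]] }
  set_val <- function(p, v, what) {
    if (length(v) != length(p$value))
      stopf("checkpoint geometry mismatch for %s: got %s, expected %s", what,
            paste(dim(v) %||% length(v), collapse = "x"),
            paste(dim(p$value) %||% length(p$value), collapse = "x"))
    p$value <- v
  }
  for (nm in names(ck)) {
    v <- ck[[nm]]
    if (nm == "patch_embed.proj.weight") {
      w <- if (length(dim(v)) == 4) torch_patch_to_matrix(v) else v
      if (!all(dim(w) == dim(model$params[["patch.weight"]]$value)))
        stopf("checkpoint geometry mismatch for patch embedding: %s vs %s",
              paste(dim(w), collapse = "x"),
              paste(dim(model$params[["patch.weight"]]$value), collapse = "x"))
      model$params[["patch.weight"]]$value <- w
      matched <- c(matched, nm)
    } else if (nm == "patch_embed.proj.bias") {
      set_val(model$params[["patch.bias"]], as.numeric(v), nm)
      matched <- c(matched, nm)
    } else if (nm == "pos_embed") {
      pe <- v
      if (length(dim(pe)) == 3) pe <- pe[1, , ]
      D <- ncol(pe)
      Tt <- nrow(pe)
      g <- cfg$grid_size
      g0 <- sqrt(Tt)
      if (g0 %% 1 != 0) { pe <- pe[-1, , drop = FALSE]; g0 <- sqrt(nrow(pe)) }
      if (g0 %% 1 != 0) stopf("pos_embed token count %d is not a square grid",
                              nrow(pe))
      if (D != cfg$embed_dim)
        stopf("checkpoint geometry mismatch for pos_embed width: %d vs %d",
              D, cfg$embed_dim)
      if (g0 != g) {
        arr <- array(pe, c(g0, g0, D))
        arr <- resample_image(arr, g, g, "bicubic")
        pe <- matrix(arr, g * g, D)
      }
      model$params[["patch.pos"]]$value <- pe
      matched <- c(matched, nm)
    } else if (grepl("^blocks\\.\\d+\\.", nm)) {
      i <- as.integer(sub("^blocks\\.(\\d+)\\..*", "\\1", nm)) + 1L
      if (i > cfg$depth) { unmatched <- c(unmatched, nm); next }
      field <- sub("^blocks\\.\\d+\\.", "", nm)
      tgt <- switch(field,
                    "norm1.weight" = sprintf("blocks.%d.norm1.gamma", i),
                    "norm1.bias" = sprintf("blocks.%d.norm1.beta", i),
                    "norm2.weight" = sprintf("blocks.%d.norm2.gamma", i),
                    "norm2.bias" = sprintf("blocks.%d.norm2.beta", i),
                    "attn.qkv.weight" = sprintf("blocks.%d.attn.qkv_w", i),
                    "attn.qkv.bias" = sprintf("blocks.%d.attn.qkv_b", i),
                    "attn.proj.weight" = sprintf("blocks.%d.attn.proj_w", i),
                    "attn.proj.bias" = sprintf("blocks.%d.attn.proj_b", i),
                    "mlp.fc1.weight" = sprintf("blocks.%d.mlp_fc1.weight", i),
                    "mlp.fc1.bias" = sprintf("blocks.%d.mlp_fc1.bias", i),
                    "mlp.fc2.weight" = sprintf("blocks.%d.mlp_fc2.weight", i),
                    "mlp.fc2.bias" = sprintf("blocks.%d.mlp_fc2.bias", i),
                    NULL)
      if (is.null(tgt)) { unmatched <- c(unmatched, nm); next }
      if (grepl("weight$", field) && length(dim(v)) == 2) v <- t(v)
      set_val(model$params[[tgt]], v, nm)
      matched <- c(matched, nm)
    } else if (nm == "norm.weight") {
      set_val(model$params[["enc_norm.gamma"]], as.numeric(v), nm)
      matched <- c(matched, nm)
    } else if (nm == "norm.bias") {
      set_val(model$params[["enc_norm.beta"]], as.numeric(v), nm)
      matched <- c(matched, nm)
    } else {
      unmatched <- c(unmatched, nm)
    }
  }
  report <- list(matched = matched, unmatched = unmatched)
  message(sprintf("encoder import: %d matched, %d unmatched tensor(s)%s",
                  length(matched), length(unmatched),
                  if (length(unmatched))
                    paste0(" (", paste(utils::head(unmatched, 4),
                                       collapse = ", "),
                           if (length(unmatched) > 4) ", ..." else "", ")")
                  else ""))
  attr(model, "import_report") <- report
  model
}
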