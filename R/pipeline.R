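# End-to-end pipeline: preprocessing, stage-1 vertebra/aorta segmentation,
# stage-2 calcification segmentation on the aorta crop, and Kauppila
# scoring, with every intermediate kept for audit.

#' Default pipeline configuration
#'
#' Nested configuration consumed by [run_pipeline()]; [read_config()] merges
#' a YAML file over these defaults. Blocks: `preprocess` (enabled +
#' [preprocess_config()] fields), `scoring` (wall-label trust, minimum
#' plaque component size, lenient mode), `labels`, `seed`.
#'
#' @return Named list.
#' @export
aac_config <- function() {
  list(
    preprocess = c(list(enabled = FALSE), unclass(preprocess_config())),
    scoring = list(trust_wall_labels = FALSE, min_calc_component_px = 0L,
                   lenient = FALSE),
    labels = as.list(aac_labels()),
    seed = 1L)
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file; keys merge over [aac_config()] defaults.
#' @return Named list with attribute `hash` (provenance digest of the merged
#'   configuration).
#' @export
read_config <- function(path = NULL) {
  cfg <- aac_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, user)
  }
  lab <- unlist(cfg$labels)
  if (anyDuplicated(lab)) abort("label integers must be unique")
  attr(cfg, "hash") <- rlang::hash(cfg)
  cfg
}

resolve_checkpoint <- function(ckpt, stage) {
  if (is.null(ckpt))
    abort(sprintf("missing %s checkpoint", stage))
  if (is.character(ckpt)) {
    if (!file.exists(ckpt))
      abort(sprintf("missing %s checkpoint: %s", stage, ckpt))
    return(load_unet(ckpt))
  }
  ckpt
}

#' Run the full scoring pipeline on one radiograph
#'
#' Stage 1 segments vertebrae and aorta, stage 2 segments calcification
#' within the aorta crop (mapped back through the crop offset), and the
#' scoring engine converts the combined mask into a Kauppila result. Each
#' checkpoint may be a trained `unet_model`, a checkpoint path, or a plain
#' function `image_matrix -> integer mask` (an oracle stub, useful to test
#' the scoring chain in isolation from learning variance).
#'
#' @param image A [radiograph()] or matrix.
#' @param checkpoints List with elements `stage1` and `stage2`.
#' @param config Configuration list from [aac_config()]/[read_config()].
#' @return List of class `aac_pipeline_result`: `result` (the
#'   `kauppila_result`), `mask` (combined multi-class mask), `stage1_mask`,
#'   `calc_mask`, `preprocessed`, `aorta_crop`, `config_hash`, `warnings`.
#' @export
run_pipeline <- function(image, checkpoints, config = aac_config()) {
  image <- as_radiograph(image)
  warnings <- character(0)
  lb <- unlist(config$labels)

  if (isTRUE(config$preprocess$enabled)) {
    pcfg <- do.call(preprocess_config,
                    config$preprocess[setdiff(names(config$preprocess),
                                              "enabled")])
    image <- preprocess_image(image, pcfg)
    margin <- pcfg$aorta_margin_px
  } else {
    margin <- config$preprocess$aorta_margin_px %||% 5L
  }

  s1 <- resolve_checkpoint(checkpoints$stage1, "stage1")
  stage1_mask <- if (is.function(s1)) s1(image$pixels) else
    predict_stage1(s1, image$pixels)

  aorta <- matrix(stage1_mask == lb[["aorta"]], nrow(stage1_mask))
  calc_mask <- matrix(0L, nrow(stage1_mask), ncol(stage1_mask))
  crop <- NULL
  if (!any(aorta)) {
    warnings <- c(warnings, "stage1 predicted no aorta; stage 2 skipped")
    warn(warnings[length(warnings)])
  } else {
    s2 <- resolve_checkpoint(checkpoints$stage2, "stage2")
    crop <- crop_to_aorta(image, aorta, margin_px = margin)
    calc_mask <- if (is.function(s2)) s2(image$pixels) else
      predict_stage2(s2, crop$image, crop$offset, dim(stage1_mask))
  }

  combined <- stage1_mask
  combined[calc_mask != 0L] <- calc_mask[calc_mask != 0L]
  storage.mode(combined) <- "integer"

  result <- score_case(combined, labels = lb,
                       trust_wall_labels =
                         isTRUE(config$scoring$trust_wall_labels),
                       min_calc_component_px =
                         config$scoring$min_calc_component_px %||% 0L,
                       lenient = isTRUE(config$scoring$lenient))
  structure(
    list(result = result, mask = combined, stage1_mask = stage1_mask,
         calc_mask = calc_mask, preprocessed = image, aorta_crop = crop,
         config_hash = attr(config, "hash") %||% rlang::hash(config),
         warnings = c(warnings, result$warnings)),
    class = "aac_pipeline_result")
}

#' @export
print.aac_pipeline_result <- function(x, ...) {
  cat(sprintf("<aac_pipeline_result> total %d (%s), config %s\n",
              x$result$total, x$result$severity,
              substr(x$config_hash, 1, 8)))
  invisible(x)
}

#' Oracle segmentation stubs from a phantom case
#'
#' Builds `stage1`/`stage2` checkpoint functions that return the phantom's
#' ground-truth masks regardless of the input image, isolating the scoring
#' chain from segmentation quality.
#'
#' @param case A `phantom_case`.
#' @return List with `stage1` and `stage2` functions for [run_pipeline()].
#' @export
oracle_checkpoints <- function(case) {
  lb <- aac_labels()
  m <- case$mask
  stage1 <- function(image) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[m == lb[["vertebra"]]] <- lb[["vertebra"]]
    out[m %in% c(lb[["aorta"]], lb[["calc_anterior"]],
                 lb[["calc_posterior"]], lb[["calc"]])] <- lb[["aorta"]]
    out
  }
  stage2 <- function(image) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[m == lb[["calc_anterior"]]] <- lb[["calc_anterior"]]
    out[m == lb[["calc_posterior"]]] <- lb[["calc_posterior"]]
    out
  }
  list(stage1 = stage1, stage2 = stage2)
}
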