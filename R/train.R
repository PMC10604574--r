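# Training loop (Adam + soft-Dice), stage-wise prediction helpers and
# checkpoint IO for the compact U-Net.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# pad an integer target to the model's internal grid (background fill)
pad_target <- function(target, mult) {
  d <- dim(target)
  H <- as.integer(ceiling(d[1L] / mult) * mult)
  W <- as.integer(ceiling(d[2L] / mult) * mult)
  if (H == d[1L] && W == d[2L]) return(target)
  tp <- matrix(0L, H, W)
  tp[seq_len(d[1L]), seq_len(d[2L])] <- target
  tp
}

#' Train a U-Net with Adam and soft-Dice loss
#'
#' Runs mini-batch Adam on the given cases, monitoring the per-epoch mean
#' loss and stopping early once the loss reduction halts: when the epoch
#' mean fails to improve by at least `early_stop_tol` for `patience`
#' consecutive epochs, capped at `epochs`. Fully seeded: shuffling,
#' augmentation draws and initialization derive from `seed`, so identical
#' calls give identical traces on CPU.
#'
#' @param model A `unet_model` from [build_unet()].
#' @param cases List of training cases, each a list with `x` (numeric image
#'   matrix, ideally normalized to `[0, 1]`) and `y` (integer class matrix,
#'   values `0..n_classes-1`).
#' @param seed RNG seed for shuffling and augmentation.
#' @param augment_cfg Optional [preprocess_config()]; when the model config's
#'   `augment_factor > 1`, each epoch additionally trains on that many
#'   randomly augmented copies per case drawn on the fly.
#' @return List with `model` (trained) and `trace`, a tibble with columns
#'   `epoch`, `step`, `loss` (per optimizer step) plus the per-epoch mean
#'   loss in `attr(trace, "epoch_mean")`.
#' @export
train_unet <- function(model, cases, seed = 1L,
                       augment_cfg = preprocess_config()) {
  cfg <- model$cfg
  if (length(cases) < 1L) abort("no training cases")
  if (cfg$epochs == 0L)
    return(list(model = model,
                trace = tibble::tibble(epoch = integer(0), step = integer(0),
                                       loss = numeric(0))))
  L <- length(cfg$encoder_filters)
  mult <- 2L^(L - 1L)
  state <- adam_init(model$params)
  trace <- list()
  epoch_mean <- numeric(0)
  stall <- 0L
  step <- 0L
  with_seed(seed, {
    for (ep in seq_len(cfg$epochs)) {
      pool <- cases
      if (cfg$augment_factor > 1L) {
        extra <- unlist(lapply(seq_len(cfg$augment_factor - 1L), function(k) {
          lapply(cases, function(cs) {
            a <- augment(cs$x, cs$y, augment_cfg,
                         seed = sample.int(.Machine$integer.max, 1L))
            list(x = a$image$pixels, y = a$mask)
          })
        }), recursive = FALSE)
        pool <- c(pool, extra)
      }
      pool <- pool[sample.int(length(pool))]
      nb <- ceiling(length(pool) / cfg$batch_size)
      ep_losses <- numeric(0)
      for (b in seq_len(nb)) {
        idx <- ((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size,
                                                    length(pool))
        gsum <- NULL
        lsum <- 0
        for (i in idx) {
          fwd <- unet_forward(model, pool[[i]]$x, with_cache = TRUE)
          tp <- pad_target(pool[[i]]$y, mult)
          lg <- dice_loss_grad(fwd$probs_padded, tp)
          if (!is.finite(lg$loss))
            abort(sprintf("non-finite loss at epoch %d step %d", ep, step + 1L))
          g <- unet_backward(model, fwd$caches, lg$dlogits)
          lsum <- lsum + lg$loss
          gsum <- if (is.null(gsum)) g else
            mapply(`+`, gsum, g, SIMPLIFY = FALSE)
        }
        gmean <- lapply(gsum, function(g) g / length(idx))
        upd <- adam_step(model$params, gmean, state, cfg$learning_rate)
        model$params <- upd$params
        state <- upd$state
        step <- step + 1L
        loss_b <- lsum / length(idx)
        ep_losses <- c(ep_losses, loss_b)
        trace[[length(trace) + 1L]] <- c(epoch = ep, step = step,
                                         loss = loss_b)
      }
      epoch_mean <- c(epoch_mean, mean(ep_losses))
      if (ep > 1L) {
        if (epoch_mean[ep - 1L] - epoch_mean[ep] < cfg$early_stop_tol)
          stall <- stall + 1L
        else stall <- 0L
        if (stall >= cfg$patience) break
      }
    }
  })
  tr <- tibble::as_tibble(do.call(rbind, trace))
  tr$epoch <- as.integer(tr$epoch)
  tr$step <- as.integer(tr$step)
  attr(tr, "epoch_mean") <- epoch_mean
  list(model = model, trace = tr)
}

argmax_channels <- function(probs) {
  d <- dim(probs)
  P <- matrix(probs, d[1L] * d[2L], d[3L])
  matrix(max.col(P, ties.method = "first") - 1L, d[1L], d[2L])
}

#' Stage-one prediction: vertebrae and aorta
#'
#' Argmax over the stage-one model's class probabilities, mapped to the
#' package label integers (0 background, 1 vertebra, 2 aorta).
#'
#' @param model Stage-one `unet_model` (3 classes).
#' @param image Numeric image matrix.
#' @return Integer mask matrix.
#' @export
predict_stage1 <- function(model, image) {
  if (is.list(image) && inherits(image, "radiograph")) image <- image$pixels
  cls <- argmax_channels(predict_probs(model, image))
  storage.mode(cls) <- "integer"
  cls  # class ids coincide with labels: 0 bg, 1 vertebra, 2 aorta
}

#' Stage-two prediction: calcification within the aorta crop
#'
#' Runs the stage-two model on an aorta-cropped image and maps the predicted
#' calcification pixels back to full-image coordinates through the crop
#' offset. With a 2-class model the output uses the generic calcification
#' label (5); a 3-class model yields anterior (3) / posterior (4) labels
#' directly.
#'
#' @param model Stage-two `unet_model`.
#' @param crop Cropped image matrix (or `radiograph`), as produced by
#'   [crop_to_aorta()].
#' @param offset 0-based `(row, col)` origin of the crop in the full image.
#' @param full_shape `(rows, cols)` of the full image.
#' @return Integer full-frame calcification mask.
#' @export
predict_stage2 <- function(model, crop, offset = c(0L, 0L),
                           full_shape = NULL) {
  if (is.list(crop) && inherits(crop, "radiograph")) crop <- crop$pixels
  if (is.null(full_shape)) full_shape <- dim(crop) + offset
  cls <- argmax_channels(predict_probs(model, crop))
  lb <- aac_labels()
  out <- matrix(0L, full_shape[1L], full_shape[2L])
  mapped <- matrix(0L, nrow(cls), ncol(cls))
  if (model$n_classes == 2L) {
    mapped[cls == 1L] <- lb[["calc"]]
  } else {
    mapped[cls == 1L] <- lb[["calc_anterior"]]
    mapped[cls == 2L] <- lb[["calc_posterior"]]
  }
  out[offset[1L] + seq_len(nrow(cls)), offset[2L] + seq_len(ncol(cls))] <-
    mapped
  out
}

#' Save / load a U-Net checkpoint
#'
#' The checkpoint is an RDS file holding the parameter list, with a JSON
#' sidecar (`<path>.json`) recording the configuration and class count.
#'
#' @param model A `unet_model`.
#' @param path Checkpoint path (e.g. `stage1.rds`).
#' @return `save_unet` returns `path` invisibly; `load_unet` the model.
#' @export
save_unet <- function(model, path) {
  saveRDS(model$params, path)
  meta <- list(preset = model$cfg$preset,
               encoder_filters = model$cfg$encoder_filters,
               decoder_filters = model$cfg$decoder_filters,
               learning_rate = model$cfg$learning_rate,
               batch_size = model$cfg$batch_size,
               epochs = model$cfg$epochs,
               n_classes = model$n_classes,
               seed = model$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- unet_config(preset = meta$preset,
                     encoder_filters = meta$encoder_filters,
                     decoder_filters = meta$decoder_filters,
                     learning_rate = meta$learning_rate,
                     batch_size = meta$batch_size,
                     epochs = meta$epochs)
  model <- structure(list(cfg = cfg, n_classes = as.integer(meta$n_classes),
                          params = readRDS(path),
                          seed = as.integer(meta$seed %||% 1L)),
                     class = "unet_model")
  model
}

#' Convert a phantom cohort into U-Net training cases
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param stage 1 (vertebra/aorta; calcification pixels count as aorta) or
#'   2 (binary calcification target on the aorta crop).
#' @param split Which split to take (`"training"`, `"validation"`, `"test"`
#'   or `"all"`).
#' @param margin_px Aorta-crop margin for stage 2.
#' @return List of cases with `x` and `y` as expected by [train_unet()].
#' @export
cohort_to_cases <- function(cohort, stage = 1L, split = "training",
                            margin_px = 5L) {
  rows <- if (split == "all") seq_len(nrow(cohort)) else
    which(cohort$split == split)
  lb <- aac_labels()
  lapply(cohort$case[rows], function(cs) {
    img <- normalize_intensity(cs$image)$pixels
    m <- cs$mask
    if (stage == 1L) {
      y <- matrix(0L, nrow(m), ncol(m))
      y[m == lb[["vertebra"]]] <- 1L
      y[m %in% c(lb[["aorta"]], lb[["calc_anterior"]],
                 lb[["calc_posterior"]], lb[["calc"]])] <- 2L
      list(x = img, y = y)
    } else {
      aorta <- matrix(m %in% c(lb[["aorta"]], lb[["calc_anterior"]],
                               lb[["calc_posterior"]], lb[["calc"]]),
                      nrow(m))
      cr <- crop_to_aorta(img, aorta, margin_px)
      y_full <- matrix(0L, nrow(m), ncol(m))
      y_full[m %in% c(lb[["calc_anterior"]], lb[["calc_posterior"]],
                      lb[["calc"]])] <- 1L
      bb <- cr$bbox
      y <- y_full[(bb$rows[1L] + 1L):bb$rows[2L],
                  (bb$cols[1L] + 1L):bb$cols[2L], drop = FALSE]
      list(x = cr$image$pixels, y = y, offset = cr$offset)
    }
  })
}
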