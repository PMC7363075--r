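# Stage 2: slice-wise stroke region proposals.
#
# A 2D encoder-decoder (5x5 kernels, sigmoid output) trained with the Dice
# loss, computed per batch sample and averaged over the batch so small and
# large lesions are penalised alike, followed by removal of connected
# components below a physical volume bound.

#' Region-proposal model configuration
#'
#' Defaults follow the reference setup (256x256 input, 5x5 kernels, Adam at
#' lr 1e-4, 30 epochs, training restricted to lesion-bearing slices).  The
#' desk preset reduces the input grid, filter widths and epochs to CPU
#' scale.
#'
#' @param input_size Slice input grid `(rows, cols)`, divisible by 4.
#' @param filters Per-level filter widths (3 levels).
#' @param lr Learning rate.
#' @param epochs Training epochs (> 0).
#' @param stroke_slices_only Train only on slices whose ground truth
#'   contains lesion voxels.
#' @param augment Rotation/shift/zoom augmentation during training.
#' @param desk Use the reduced desk-scale preset.
#' @return An object of class `proposal_config`.
#' @export
proposal_config <- function(input_size = NULL, filters = NULL, lr = 1e-4,
                            epochs = NULL, stroke_slices_only = TRUE,
                            augment = NULL, desk = FALSE) {
  if (is.null(input_size)) input_size <- if (desk) c(64, 64) else c(256, 256)
  if (is.null(filters)) filters <- if (desk) c(6, 12, 24) else c(8, 16, 32)
  if (is.null(epochs)) epochs <- if (desk) 12L else 30L
  if (desk && missing(lr)) lr <- 3e-3
  if (is.null(augment)) augment <- !desk
  if (epochs <= 0) stop("epochs must be > 0")
  if (any(input_size %% 4 != 0))
    stop("input size must be divisible by the pooling factors (4)")
  structure(list(input_size = as.integer(input_size), kernel = 5L,
                 filters = as.integer(filters), lr = lr,
                 epochs = as.integer(epochs),
                 stroke_slices_only = isTRUE(stroke_slices_only),
                 augment = isTRUE(augment)),
            class = "proposal_config")
}

#' Smoothed Dice coefficient
#'
#' `(2 * sum(S*y) + eps) / (sum(S^2 + y^2) + eps)`.  On binary masks the
#' squares are idempotent and this reduces to `2|S∩y| / (|S| + |y|)`.
#' Accepts probability maps for `S`.
#'
#' @param S Prediction (binary mask or probability map).
#' @param y Ground-truth binary mask, same shape.
#' @param eps Smoothing constant.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(S, y, eps = 1e-6) {
  S <- as.numeric(unclass_mask(S)); y <- as.numeric(unclass_mask(y))
  if (length(S) != length(y)) stop("S and y must have the same shape")
  (2 * sum(S * y) + eps) / (sum(S^2 + y^2) + eps)
}

unclass_mask <- function(x) if (is.list(x) && !is.null(x$voxels)) x$voxels else x

#' Mean Dice loss over a batch
#'
#' `mean(1 - dice_coefficient)` over paired predictions and truths, i.e.
#' the Dice loss computed per batch sample and averaged on batch level.
#'
#' @param predictions,truths Equal-length lists of same-shaped arrays.
#' @param eps Smoothing constant.
#' @return Scalar loss.
#' @export
dice_loss_batch <- function(predictions, truths, eps = 1e-6) {
  if (length(predictions) == 0) stop("empty batch")
  if (length(predictions) != length(truths)) stop("unequal batch sizes")
  mean(mapply(function(p, y) 1 - dice_coefficient(p, y, eps),
              predictions, truths))
}

# loss + gradient w.r.t. pre-sigmoid logits for one sample
dice_grad <- function(p, y, eps = 1e-6) {
  num <- 2 * sum(p * y) + eps
  den <- sum(p^2 + y^2) + eps
  loss <- 1 - num / den
  ddice_dp <- (2 * y * den - num * 2 * p) / den^2
  dz <- -ddice_dp * p * (1 - p)   # chain through the sigmoid
  list(loss = loss, dz = dz)
}

#' Build a trainable region-proposal model
#'
#' @param config A `proposal_config`.
#' @param seed Integer seed for glorot-uniform initialisation.
#' @return An object of class `proposal_model`.
#' @export
build_proposal_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "proposal_config"))
  par <- with_seed(seed, unet_init(config$filters, config$kernel, 1L, 2L))
  structure(list(config = config, params = par, history = NULL),
            class = "proposal_model")
}

proposal_slices <- function(sample, input_size, stroke_only = TRUE) {
  v <- clip_normalize(sample$volume)
  les <- sample$lesions$voxels
  nz <- dim(v$voxels)[1]
  keep <- if (stroke_only)
    which(apply(les, 1, sum) > 0) else seq_len(nz)
  lapply(keep, function(z) {
    x <- cpp_resize2d(v$voxels[z, , ], input_size[1], input_size[2], 1L)
    y <- cpp_resize2d(les[z, , ] + 0, input_size[1], input_size[2], 0L)
    list(x = array(x, c(input_size, 1)), y = y)
  })
}

#' Train the region-proposal model
#'
#' Training uses only slices whose ground truth contains lesion voxels
#' (when `stroke_slices_only` is set), Dice loss per sample averaged over
#' the batch, and returns the weights from the epoch with the best
#' validation loss.
#'
#' @param model A `proposal_model`.
#' @param train,val Lists of samples with `volume` and `lesions` elements;
#'   the training set must contribute at least one lesion-bearing slice.
#' @param seed Integer seed.
#' @return The trained model with a `history` data.frame.
#' @export
train_region_proposal <- function(model, train, val, seed = 1L) {
  cfg <- model$config
  items <- unlist(lapply(train, proposal_slices, input_size = cfg$input_size,
                         stroke_only = cfg$stroke_slices_only),
                  recursive = FALSE)
  vitems <- unlist(lapply(val, proposal_slices, input_size = cfg$input_size,
                          stroke_only = cfg$stroke_slices_only),
                   recursive = FALSE)
  if (length(items) == 0) stop("no lesion-bearing slices in the training set")
  if (length(vitems) == 0) vitems <- items[1]
  res <- train_segmenter(model$params, cfg$kernel, 2L, items, vitems,
                         cfg$lr, cfg$epochs, seed, dice_grad,
                         augment = cfg$augment)
  model$params <- res$params
  model$history <- res$history
  model
}

#' Generate stroke region proposals for a volume
#'
#' Slice-wise inference at the configured resolution; probabilities are
#' thresholded at 0.5, resampled back to the volume grid (nearest
#' neighbour) and stacked to a 3D mask.  Proposals are deliberately
#' sensitive; false positives are removed by the stage-3 classifier.
#'
#' @param model A trained `proposal_model`.
#' @param volume A `normalized_volume`.
#' @param threshold Probability threshold.
#' @return A `seg_mask` on the volume grid.
#' @export
propose_regions <- function(model, volume, threshold = 0.5) {
  cfg <- model$config
  d <- dim(volume$voxels)
  out <- array(0L, d)
  for (z in seq_len(d[1])) {
    x <- cpp_resize2d(volume$voxels[z, , ], cfg$input_size[1],
                      cfg$input_size[2], 1L)
    p <- unet2d_forward(model$params, array(x, c(cfg$input_size, 1)),
                        cfg$kernel)$out
    out[z, , ] <- as.integer(cpp_resize2d(matrix(as.numeric(p >= threshold),
                                                 cfg$input_size[1]),
                                          d[2], d[3], 0L) != 0)
  }
  seg_mask(out, volume$spacing, volume$z_thickness)
}

# physical volume (cm^3) of a voxel set given spacing / per-slice thickness
component_volume_cm3 <- function(idx_z, spacing, z_thickness) {
  area_mm2 <- spacing[2] * spacing[3]
  sum(area_mm2 * z_thickness[idx_z]) / 1000
}

#' Remove small connected components
#'
#' Labels the mask with 26-connectivity and removes every component whose
#' physical volume is strictly below `min_cm3`; remaining components are
#' untouched.  Mixed slice thicknesses are honoured (per-voxel volume is
#' in-plane area times the slice's thickness).
#'
#' @param mask A `seg_mask` with known spacing.
#' @param min_cm3 Volume bound in cm^3.
#' @return The filtered `seg_mask`.
#' @export
filter_small_components <- function(mask, min_cm3 = 0.2) {
  if (is.null(mask$spacing) || any(!is.finite(mask$spacing)))
    stop("mask spacing is unknown")
  d <- dim(mask$voxels)
  lab <- array(cpp_label3d(as.integer(mask$voxels), d[1], d[2], d[3]), d)
  if (max(lab) == 0) return(mask)
  keep <- array(0L, d)
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l, arr.ind = TRUE)
    vol <- component_volume_cm3(idx[, 1], mask$spacing, mask$z_thickness)
    if (vol >= min_cm3) keep[lab == l] <- 1L
  }
  mask$voxels <- keep
  mask
}
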