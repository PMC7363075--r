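# Stage 1: cranial-cavity segmentation.
#
# Encoder-decoder segmenters (a slice-wise 2D variant with 5x5 kernels and a
# volumetric 3D variant with 3x3x3 kernels) trained with unweighted binary
# cross-entropy, plus the boundary-refinement step that repairs upsampling
# blur around the mask border.

#' Cavity model configuration
#'
#' Defaults follow the reference training setup (Adam, lr 1e-4; 30 epochs
#' for the 2D variant, 320 for the 3D variant; 512x512 slice input for 2D,
#' 40x64x64 volume input for 3D).  The `desk` presets used throughout the
#' synthetic test-bench shrink input sizes, filter widths and epochs to CPU
#' scale; see the methods vignette.
#'
#' @param variant "2d" or "3d".
#' @param input_size Network input grid: `(rows, cols)` for 2D,
#'   `(slices, rows, cols)` for 3D.  Each in-plane size must be divisible
#'   by 4 (two pooling levels), and the 3D slice count by 4 as well.
#' @param filters Per-level filter widths (3 levels).
#' @param lr Learning rate (> 0).
#' @param epochs Training epochs (> 0).
#' @param augment Use rotation/shift/zoom augmentation during training.
#' @param desk Use the reduced desk-scale preset for `input_size`,
#'   `filters` and `epochs` (any explicitly supplied value still wins).
#' @return An object of class `cavity_config`.
#' @export
cavity_config <- function(variant = c("3d", "2d"), input_size = NULL,
                          filters = NULL, lr = 1e-4, epochs = NULL,
                          augment = NULL, desk = FALSE) {
  variant <- match.arg(variant)
  if (is.null(input_size))
    input_size <- if (variant == "3d") {
      if (desk) c(12, 32, 32) else c(40, 64, 64)
    } else {
      if (desk) c(64, 64) else c(512, 512)
    }
  if (is.null(filters)) filters <- if (desk) c(4, 8, 16) else c(8, 16, 32)
  if (is.null(epochs)) epochs <- if (desk) {
    if (variant == "3d") 24L else 4L
  } else {
    if (variant == "3d") 320L else 30L
  }
  if (desk && missing(lr)) lr <- 3e-3
  if (is.null(augment)) augment <- !desk
  if (lr <= 0) stop("learning rate must be > 0")
  if (epochs <= 0) stop("epochs must be > 0")
  k <- if (variant == "3d") 3L else 5L
  if (any(utils::tail(input_size, 2) %% 4 != 0) ||
      (variant == "3d" && input_size[1] %% 4 != 0))
    stop("input size must be divisible by the pooling factors (4)")
  structure(list(variant = variant, input_size = as.integer(input_size),
                 kernel = k, filters = as.integer(filters), lr = lr,
                 epochs = as.integer(epochs), augment = isTRUE(augment)),
            class = "cavity_config")
}

#' Build a trainable cavity segmentation model
#'
#' Encoder-decoder with two pooling levels and skip connections, ReLU
#' activations, a sigmoid single-channel output and unweighted binary
#' cross-entropy loss.  Weights are glorot-uniform, biases zero; the
#' initial weights are fully determined by `seed`.
#'
#' @param config A `cavity_config`.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `cavity_model`.
#' @export
build_cavity_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cavity_config"))
  nd <- if (config$variant == "3d") 3L else 2L
  par <- with_seed(seed, unet_init(config$filters, config$kernel, 1L, nd))
  structure(list(config = config, params = par, history = NULL),
            class = "cavity_model")
}

# one sample -> list(x = input array (+channel dim), y = target array)
cavity_prepare_3d <- function(sample, input_size) {
  v <- clip_normalize(sample$volume)
  x <- resize_volume(v$voxels, input_size, bilinear = TRUE)
  y <- resize_volume(sample$cavity$voxels, input_size, bilinear = FALSE)
  list(x = array(x, c(input_size, 1)), y = y)
}

cavity_prepare_2d <- function(sample, input_size) {
  v <- clip_normalize(sample$volume)
  nz <- dim(v$voxels)[1]
  lapply(seq_len(nz), function(z) {
    x <- cpp_resize2d(v$voxels[z, , ], input_size[1], input_size[2], 1L)
    y <- cpp_resize2d(sample$cavity$voxels[z, , ] + 0, input_size[1],
                      input_size[2], 0L)
    list(x = array(x, c(input_size, 1)), y = y)
  })
}

bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Shared training loop for sigmoid segmenters (stage 1 and stage 2).
# items: list of list(x, y); loss_grad returns list(loss, dz) given (p, y).
train_segmenter <- function(par, k, nd, items, val_items, lr, epochs, seed,
                            loss_fn, augment = FALSE) {
  fwd <- if (nd == 3L) unet3d_forward else unet2d_forward
  bwd <- if (nd == 3L) unet3d_backward else unet2d_backward
  opt <- adam_init(par)
  eval_loss <- function(p_list, its) {
    mean(vapply(its, function(it) loss_fn(fwd(p_list, it$x, k)$out, it$y)$loss,
                numeric(1)))
  }
  best_par <- par
  best_val <- Inf
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(items))
      tr_loss <- 0
      for (i in ord) {
        it <- items[[i]]
        if (augment) {
          aug <- draw_augment()
          it <- augment_item(it, aug, nd)
        }
        f <- fwd(par, it$x, k)
        lg <- loss_fn(f$out, it$y)
        tr_loss <- tr_loss + lg$loss
        g <- bwd(par, f$cache, lg$dz, k)[names(par)]
        st <- adam_step(par, g, opt, lr)
        par <- st$params
        opt <- st$state
      }
      vl <- eval_loss(par, val_items)
      hist <- rbind(hist, data.frame(epoch = ep,
                                     train_loss = tr_loss / length(items),
                                     val_loss = vl))
      if (vl < best_val) { best_val <- vl; best_par <- par }
    }
  })
  list(params = best_par, history = hist)
}

augment_item <- function(it, aug, nd) {
  if (nd == 2L) {
    x <- apply_augment2d(it$x[, , 1], aug, bilinear = TRUE)
    y <- apply_augment2d(it$y, aug, bilinear = FALSE)
    list(x = array(x, dim(it$x)), y = y)
  } else {
    x <- it$x; y <- it$y
    for (z in seq_len(dim(x)[1])) {
      x[z, , , 1] <- apply_augment2d(it$x[z, , , 1], aug, bilinear = TRUE)
      y[z, , ] <- apply_augment2d(it$y[z, , ], aug, bilinear = FALSE)
    }
    list(x = x, y = y)
  }
}

bce_grad <- function(p, y) {
  # gradient w.r.t. pre-sigmoid logits of mean BCE: (p - y) / n
  list(loss = bce_loss(p, y), dz = (p - y) / length(p))
}

#' Train a cavity segmentation model
#'
#' Runs Adam over the training samples (batch size one), logging training
#' and validation loss per epoch, and returns the weights from the epoch
#' with the lowest validation loss.
#'
#' @param model A `cavity_model` from `build_cavity_model()`.
#' @param train,val Non-empty lists of `phantom_sample`-like objects
#'   (elements `volume` and `cavity`).
#' @param seed Integer seed controlling shuffling and augmentation.
#' @return The model with trained `params` and a `history` data.frame.
#' @export
train_cavity <- function(model, train, val, seed = 1L) {
  if (length(train) < 1 || length(val) < 1)
    stop("need at least one training and one validation sample")
  cfg <- model$config
  if (cfg$variant == "3d") {
    items <- lapply(train, cavity_prepare_3d, input_size = cfg$input_size)
    vitems <- lapply(val, cavity_prepare_3d, input_size = cfg$input_size)
    nd <- 3L
  } else {
    items <- unlist(lapply(train, cavity_prepare_2d,
                           input_size = cfg$input_size), recursive = FALSE)
    vitems <- unlist(lapply(val, cavity_prepare_2d,
                            input_size = cfg$input_size), recursive = FALSE)
    nd <- 2L
  }
  res <- train_segmenter(model$params, cfg$kernel, nd, items, vitems,
                         cfg$lr, cfg$epochs, seed, bce_grad,
                         augment = cfg$augment)
  model$params <- res$params
  model$history <- res$history
  model
}

#' Segment the cranial cavity
#'
#' Downsamples the normalized volume to the network input grid, runs the
#' model, thresholds the probability map at 0.5 and resamples the binary
#' mask back to the original grid (nearest neighbour).
#'
#' @param model A trained `cavity_model`.
#' @param volume A `normalized_volume` (values in `[0, 1]`).
#' @param threshold Probability threshold for binarisation.
#' @return A `seg_mask` on the volume's grid.
#' @export
segment_cavity <- function(model, volume, threshold = 0.5) {
  cfg <- model$config
  d <- dim(volume$voxels)
  if (cfg$variant == "3d") {
    x <- resize_volume(volume$voxels, cfg$input_size, bilinear = TRUE)
    p <- unet3d_forward(model$params, array(x, c(cfg$input_size, 1)),
                        cfg$kernel)$out
    m <- resize_volume(array(as.numeric(p >= threshold), cfg$input_size), d,
                       bilinear = FALSE)
  } else {
    m <- array(0, d)
    for (z in seq_len(d[1])) {
      x <- cpp_resize2d(volume$voxels[z, , ], cfg$input_size[1],
                        cfg$input_size[2], 1L)
      p <- unet2d_forward(model$params, array(x, c(cfg$input_size, 1)),
                          cfg$kernel)$out
      m[z, , ] <- cpp_resize2d(matrix(as.numeric(p >= threshold),
                                      cfg$input_size[1]),
                               d[2], d[3], 0L)
    }
  }
  seg_mask(m, volume$spacing, volume$z_thickness)
}

#' Refine a cavity mask boundary with an HU band criterion
#'
#' Voxels strictly inside the mask and farther (in-plane) than `band_px`
#' from the mask boundary are kept unconditionally; voxels within `band_px`
#' of the boundary -- on either side -- are kept iff their HU value is below
#' `hu_max`; all other voxels are removed.  Distances are Euclidean,
#' computed per slice.
#'
#' @param mask A `seg_mask` (e.g. the upsampled network output).
#' @param volume The aligned `ct_volume` in HU.
#' @param band_px Band half-width in pixels (>= 0).
#' @param hu_max HU bound (strict `<`) applied inside the band.
#' @return The refined `seg_mask`.
#' @export
refine_boundary <- function(mask, volume, band_px = 11, hu_max = 50) {
  if (band_px < 0) stop("band_px must be >= 0")
  if (!identical(dim(mask$voxels), dim(volume$voxels)))
    stop("mask and volume must share a grid")
  d <- dim(mask$voxels)
  out <- array(0L, d)
  for (z in seq_len(d[1])) {
    m <- mask$voxels[z, , ]
    if (sum(m) == 0) next
    b <- boundary_pixels(m)
    dist <- if (sum(b) > 0) cpp_edt2d(b) else
      matrix(Inf, d[2], d[3])
    hu <- volume$voxels[z, , ]
    keep <- (m == 1 & dist > band_px) |
      (dist <= band_px & hu < hu_max)
    out[z, , ] <- as.integer(keep)
  }
  seg_mask(out, mask$spacing, mask$z_thickness)
}

# Mask pixels with a 4-neighbour outside the mask (grid edges count as
# outside): the in-plane boundary of a binary slice.
boundary_pixels <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(0L, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- m
  nb <- pad[1:ny, 2:(nx + 1)] + pad[3:(ny + 2), 2:(nx + 1)] +
    pad[2:(ny + 1), 1:nx] + pad[2:(ny + 1), 3:(nx + 2)]
  matrix(as.integer(m == 1 & nb < 4), ny, nx)
}
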