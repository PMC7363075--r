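# Stage 3: dual-resolution border patches and the densely connected
# dual-pathway patch classifier.
#
# Lesions are connected components (26-connectivity); the border is the set
# of lesion voxels where the per-slice Sobel magnitude of the binary mask is
# non-zero; 70 random border positions per lesion seed dual-resolution
# patches (3x32x32 fine, 3x64x64 downsampled to 3x32x32 coarse).  Negatives
# are mined from stage-2 false positives on healthy volumes; the minority
# class is oversampled to parity.

# Lesions ----------------------------------------------------------------

#' Label connected lesions in a binary mask
#'
#' One lesion per 26-connected component; physical volumes from spacing
#' (per-slice thickness honoured).
#'
#' @param mask A `seg_mask`.
#' @param subject_id Source subject recorded on each lesion.
#' @return List of `lesion` objects: `id`, `coords` (n x 3 matrix of 1-based
#'   `(z, y, x)`), `volume_cm3`, `subject_id`.
#' @export
label_lesions <- function(mask, subject_id = "subject") {
  d <- dim(mask$voxels)
  lab <- array(cpp_label3d(as.integer(mask$voxels), d[1], d[2], d[3]), d)
  n <- max(lab)
  if (n == 0) return(list())
  lapply(seq_len(n), function(l) {
    coords <- which(lab == l, arr.ind = TRUE)
    colnames(coords) <- c("z", "y", "x")
    structure(list(id = l, coords = coords,
                   volume_cm3 = component_volume_cm3(coords[, 1],
                                                     mask$spacing,
                                                     mask$z_thickness),
                   subject_id = subject_id),
              class = "lesion")
  })
}

sobel_magnitude2d <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(0, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- m
  sh <- function(dy, dx) pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
    (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Extract the border of one lesion
#'
#' Border voxels are the lesion's voxels where the per-slice Sobel gradient
#' magnitude of the binary lesion mask is non-zero, so the border is a
#' subset of the lesion (patch centres sit on lesion tissue).
#'
#' @param lesion A `lesion` from `label_lesions()`.
#' @param shape Grid shape `(nz, ny, nx)` of the source mask.
#' @return Matrix (n x 3) of 1-based `(z, y, x)` border coordinates.
#' @export
lesion_border <- function(lesion, shape) {
  if (nrow(lesion$coords) == 0) stop("empty lesion mask")
  m <- array(0, shape)
  m[lesion$coords] <- 1
  border <- NULL
  for (z in unique(lesion$coords[, "z"])) {
    mag <- sobel_magnitude2d(m[z, , ])
    sel <- which(m[z, , ] == 1 & mag > 0, arr.ind = TRUE)
    if (nrow(sel) > 0)
      border <- rbind(border, cbind(z = z, y = sel[, 1], x = sel[, 2]))
  }
  if (is.null(border)) {
    # degenerate lesions (single voxels) have a symmetric, zero Sobel
    # response at the voxel itself; the whole lesion is then its border
    border <- lesion$coords
    colnames(border) <- c("z", "y", "x")
  }
  border
}

#' Sample random positions on a lesion border
#'
#' Exactly `n` coordinates from the border set: without replacement when
#' the border has at least `n` points, with replacement otherwise.
#'
#' @param border Matrix of border coordinates (rows are positions).
#' @param n Number of positions (default 70).
#' @param seed Integer seed.
#' @return Matrix (n x 3) of coordinates, each a row of `border`.
#' @export
sample_border_positions <- function(border, n = 70, seed = 1L) {
  if (is.null(border) || nrow(border) == 0) stop("empty border")
  with_seed(seed, {
    idx <- sample(nrow(border), n, replace = nrow(border) < n)
    border[idx, , drop = FALSE]
  })
}

# Patches ----------------------------------------------------------------

extract_window2d <- function(sl, cy, cx, half_lo, half_hi) {
  ny <- nrow(sl); nx <- ncol(sl)
  out <- matrix(0, half_lo + half_hi + 1, half_lo + half_hi + 1)
  ys <- (cy - half_lo):(cy + half_hi)
  xs <- (cx - half_lo):(cx + half_hi)
  ok_y <- ys >= 1 & ys <= ny; ok_x <- xs >= 1 & xs <= nx
  out[which(ok_y), which(ok_x)] <- sl[ys[ok_y], xs[ok_x]]
  out
}

avg_pool2x2 <- function(m) {
  ny <- nrow(m) / 2; nx <- ncol(m) / 2
  0.25 * (m[2 * (1:ny) - 1, 2 * (1:nx) - 1] + m[2 * (1:ny), 2 * (1:nx) - 1] +
            m[2 * (1:ny) - 1, 2 * (1:nx)] + m[2 * (1:ny), 2 * (1:nx)])
}

#' Extract a dual-resolution patch
#'
#' Fine pathway: a 3-slice 32x32 window centred on `center`.  Coarse
#' pathway: the 3-slice 64x64 window, downsampled in-plane to 32x32 by
#' 2x2 average pooling.  Windows reaching beyond the volume are zero
#' padded (air after normalization).
#'
#' @param volume A `normalized_volume`.
#' @param center 1-based `(z, y, x)` coordinate inside the volume.
#' @param label Optional label ("stroke", "non-stroke", "unlabeled").
#' @return A `dual_patch`: `fine` and `coarse` 3x32x32 arrays, `center`,
#'   `label`.
#' @export
extract_dual_patch <- function(volume, center, label = "unlabeled") {
  d <- dim(volume$voxels)
  center <- as.integer(center)
  if (any(center < 1) || any(center > d))
    stop("patch center outside the volume")
  fine <- array(0, c(3, 32, 32))
  coarse <- array(0, c(3, 32, 32))
  for (i in -1:1) {
    z <- center[1] + i
    sl <- if (z >= 1 && z <= d[1]) volume$voxels[z, , ] else
      matrix(0, d[2], d[3])
    fine[i + 2, , ] <- extract_window2d(sl, center[2], center[3], 15L, 16L)
    coarse[i + 2, , ] <- avg_pool2x2(
      extract_window2d(sl, center[2], center[3], 31L, 32L))
  }
  structure(list(fine = fine, coarse = coarse, center = center,
                 label = label), class = "dual_patch")
}

# Stack a list of dual patches into batched matrices (sample-major rows).
patches_to_matrices <- function(patches) {
  n <- length(patches)
  Xf <- matrix(0, n * 3 * 32 * 32, 1)
  Xc <- matrix(0, n * 3 * 32 * 32, 1)
  for (i in seq_len(n)) {
    rows <- (i - 1) * 3072 + 1:3072
    Xf[rows, 1] <- as.vector(patches[[i]]$fine)
    Xc[rows, 1] <- as.vector(patches[[i]]$coarse)
  }
  list(fine = Xf, coarse = Xc)
}

#' Mine hard negatives from healthy volumes
#'
#' Runs the stage-2 proposal model (plus small-component filtering) on
#' healthy volumes; every surviving proposal component is a false positive,
#' and `n_per_lesion` dual patches are extracted from its border, labelled
#' non-stroke.
#'
#' @param healthy List of samples with a `volume` element (`ct_volume`).
#' @param proposal_model Trained `proposal_model`.
#' @param n_per_lesion Patches per false-positive component.
#' @param min_cm3 Component-volume bound applied before mining.
#' @param seed Integer seed.
#' @param cavity_masks Optional list of cavity `seg_mask`s used to restrict
#'   proposals to the cranial cavity (same order as `healthy`).
#' @return List of `dual_patch` objects labelled "non-stroke".
#' @export
mine_hard_negatives <- function(healthy, proposal_model, n_per_lesion = 70,
                                min_cm3 = 0.2, seed = 1L,
                                cavity_masks = NULL) {
  out <- list()
  for (i in seq_along(healthy)) {
    s <- healthy[[i]]
    nv <- clip_normalize(s$volume)
    prop <- propose_regions(proposal_model, nv)
    if (!is.null(cavity_masks))
      prop$voxels <- prop$voxels * cavity_masks[[i]]$voxels
    prop <- filter_small_components(prop, min_cm3)
    lesions <- label_lesions(prop, subject_id = s$volume$subject_id)
    for (les in lesions) {
      border <- lesion_border(les, dim(prop$voxels))
      if (is.null(border)) next
      pos <- sample_border_positions(border, n_per_lesion,
                                     seed = sub_seed(seed, paste0(
                                       s$volume$subject_id, "_", les$id)))
      for (j in seq_len(nrow(pos)))
        out[[length(out) + 1]] <- extract_dual_patch(nv, pos[j, ],
                                                     label = "non-stroke")
    }
  }
  out
}

#' Extract positive patches from ground-truth lesions
#'
#' @param stroke List of samples with `volume` and `lesions` elements.
#' @param n_per_lesion Patches per lesion.
#' @param seed Integer seed.
#' @return List of `dual_patch` objects labelled "stroke".
#' @export
extract_positive_patches <- function(stroke, n_per_lesion = 70, seed = 1L) {
  out <- list()
  for (s in stroke) {
    nv <- clip_normalize(s$volume)
    lesions <- label_lesions(s$lesions, subject_id = s$volume$subject_id)
    for (les in lesions) {
      border <- lesion_border(les, dim(s$lesions$voxels))
      if (is.null(border)) next
      pos <- sample_border_positions(border, n_per_lesion,
                                     seed = sub_seed(seed, paste0(
                                       s$volume$subject_id, "_", les$id)))
      for (j in seq_len(nrow(pos)))
        out[[length(out) + 1]] <- extract_dual_patch(nv, pos[j, ],
                                                     label = "stroke")
    }
  }
  out
}

#' Build a balanced labelled patch dataset
#'
#' Combines stroke (ground-truth lesion border) and non-stroke (hard
#' negative) patches and oversamples the minority class with replacement
#' until both labels are exactly equiprobable.
#'
#' @param positives,negatives Non-empty lists of `dual_patch` objects.
#' @param seed Integer seed for the oversampling draw.
#' @return List with `patches` (list) and `label` (integer vector, 1 =
#'   stroke).
#' @export
build_patch_dataset <- function(positives, negatives, seed = 1L) {
  if (length(positives) == 0 || length(negatives) == 0)
    stop("both classes must be non-empty")
  with_seed(seed, {
    np <- length(positives); nn <- length(negatives)
    if (np < nn) {
      extra <- sample(np, nn - np, replace = TRUE)
      positives <- c(positives, positives[extra])
    } else if (nn < np) {
      extra <- sample(nn, np - nn, replace = TRUE)
      negatives <- c(negatives, negatives[extra])
    }
    patches <- c(positives, negatives)
    label <- c(rep(1L, length(positives)), rep(0L, length(negatives)))
    ord <- sample(length(patches))
    list(patches = patches[ord], label = label[ord])
  })
}

# Classifier -------------------------------------------------------------

#' Patch-classifier configuration
#'
#' A dual-pathway densely connected network: each pathway is a 3x3x3 stem
#' convolution followed by dense blocks (layers concatenate all previous
#' outputs in the block, adding `growth` channels each) interleaved with
#' transition blocks (1x1x1 compression convolution + 1x2x2 max-pooling);
#' pathway features are globally average pooled, merged, passed through a
#' dropout and fully connected layers, and a 2-unit softmax.  Batch
#' normalisation uses momentum 0.99 and epsilon 1e-3.
#'
#' @param blocks Integer vector: layers per dense block (one entry per
#'   block).
#' @param growth Growth rate (channels added per dense layer).
#' @param stem Stem convolution filters.
#' @param compression Transition compression factor in (0, 1].
#' @param dropout Dropout rate in `[0, 1)` before the dense layers.
#' @param fc Hidden units of the merged fully connected layer.
#' @param lr Learning rate (reference default 1e-5).
#' @param epochs Training epochs (reference default 5).
#' @param batch Mini-batch size.
#' @param desk Use the desk-scale preset (smaller net, larger lr).
#' @return An object of class `patch_config`.
#' @export
patch_config <- function(blocks = c(2, 2), growth = 4, stem = 4,
                         compression = 0.5, dropout = 0.2, fc = 16,
                         lr = NULL, epochs = NULL, batch = 16,
                         desk = FALSE) {
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (is.null(lr)) lr <- if (desk) 1e-3 else 1e-5
  if (is.null(epochs)) epochs <- if (desk) 6L else 5L
  if (any(blocks < 1)) stop("each dense block needs >= 1 layer")
  structure(list(blocks = as.integer(blocks), growth = as.integer(growth),
                 stem = as.integer(stem), compression = compression,
                 dropout = dropout, fc = as.integer(fc), lr = lr,
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 bn_momentum = 0.99, bn_eps = 1e-3),
            class = "patch_config")
}

pathway_init <- function(cfg, prefix) {
  par <- list()
  st <- list()
  add <- function(name, p) par[[paste0(prefix, "_", name)]] <<- p
  addbn <- function(name, C) {
    par[[paste0(prefix, "_", name, "_bn")]] <<- bn_par_init(C)
    st[[paste0(prefix, "_", name, "_bn")]] <<- bn_state_init(C)
  }
  add("stem", conv_init(27L, 1L, cfg$stem)); addbn("stem", cfg$stem)
  C <- cfg$stem
  for (b in seq_along(cfg$blocks)) {
    for (l in seq_len(cfg$blocks[b])) {
      nm <- sprintf("b%d_l%d", b, l)
      add(nm, conv_init(27L, C, cfg$growth)); addbn(nm, cfg$growth)
      C <- C + cfg$growth
    }
    Ct <- max(1L, as.integer(ceiling(C * cfg$compression)))
    nm <- sprintf("t%d", b)
    add(nm, conv_init(1L, C, Ct)); addbn(nm, Ct)
    C <- Ct
  }
  list(par = par, state = st, out_channels = C)
}

#' Build a trainable dual-pathway patch classifier
#'
#' @param config A `patch_config`.
#' @param seed Integer seed for glorot-uniform initialisation.
#' @return An object of class `patch_model`.
#' @export
build_patch_classifier <- function(config, seed = 1L) {
  stopifnot(inherits(config, "patch_config"))
  with_seed(seed, {
    f <- pathway_init(config, "f")
    c_ <- pathway_init(config, "c")
    par <- c(f$par, c_$par)
    merged <- f$out_channels + c_$out_channels
    par$fc1 <- dense_init(merged, config$fc)
    par$fc2 <- dense_init(config$fc, 2L)
    structure(list(config = config, params = par,
                   bn_state = c(f$state, c_$state), history = NULL),
              class = "patch_model")
  })
}

pathway_forward <- function(par, bn_state, prefix, X, cfg, train) {
  sp <- c(3L, 32L, 32L)
  caches <- list()
  nm <- function(s) paste0(prefix, "_", s)
  # stem
  cv <- bconv3_f(X, par[[nm("stem")]]$W, par[[nm("stem")]]$b, sp, 3L)
  bno <- bn_f(cv$y, par[[nm("stem_bn")]], bn_state[[nm("stem_bn")]], train,
              cfg$bn_momentum, cfg$bn_eps)
  bn_state[[nm("stem_bn")]] <- bno$state
  rl <- relu_f(bno$y)
  spool <- bpool_f(rl$y, sp, c(1L, 2L, 2L))
  caches$stem <- list(cv = cv, bn = bno$cache, rl = rl, cin = 1L, sp = sp,
                      pool = spool)
  sp <- sp %/% c(1L, 2L, 2L)
  cur <- spool$y
  for (b in seq_along(cfg$blocks)) {
    feats <- list(cur)
    widths <- ncol(cur)
    lay_caches <- list()
    for (l in seq_len(cfg$blocks[b])) {
      lname <- sprintf("b%d_l%d", b, l)
      inp <- do.call(cbind, feats)
      cv <- bconv3_f(inp, par[[nm(lname)]]$W, par[[nm(lname)]]$b, sp, 3L)
      bno <- bn_f(cv$y, par[[nm(paste0(lname, "_bn"))]],
                  bn_state[[nm(paste0(lname, "_bn"))]], train,
                  cfg$bn_momentum, cfg$bn_eps)
      bn_state[[nm(paste0(lname, "_bn"))]] <- bno$state
      rl <- relu_f(bno$y)
      lay_caches[[l]] <- list(cv = cv, bn = bno$cache, rl = rl,
                              cin = ncol(inp))
      feats[[l + 1]] <- rl$y
      widths <- c(widths, cfg$growth)
    }
    blk_out <- do.call(cbind, feats)
    # transition
    tname <- sprintf("t%d", b)
    cv <- bconv3_f(blk_out, par[[nm(tname)]]$W, par[[nm(tname)]]$b, sp, 1L)
    bno <- bn_f(cv$y, par[[nm(paste0(tname, "_bn"))]],
                bn_state[[nm(paste0(tname, "_bn"))]], train,
                cfg$bn_momentum, cfg$bn_eps)
    bn_state[[nm(paste0(tname, "_bn"))]] <- bno$state
    rl <- relu_f(bno$y)
    pool <- bpool_f(rl$y, sp, c(1L, 2L, 2L))
    caches[[paste0("block", b)]] <- list(lay = lay_caches, widths = widths,
                                         tcv = cv, tbn = bno$cache, trl = rl,
                                         pool = pool, tcin = ncol(blk_out),
                                         sp = sp)
    sp <- sp %/% c(1L, 2L, 2L)
    cur <- pool$y
  }
  # global average pooling
  n <- nrow(cur) / prod(sp)
  grp <- rep(seq_len(n), each = prod(sp))
  gap <- rowsum(cur, grp) / prod(sp)
  caches$gap <- list(grp = grp, npix = prod(sp), dims = dim(cur))
  list(out = gap, caches = caches, bn_state = bn_state)
}

pathway_backward <- function(par, caches, prefix, dgap, cfg, train = TRUE) {
  g <- list()
  nm <- function(s) paste0(prefix, "_", s)
  gc <- caches$gap
  cur <- dgap[gc$grp, , drop = FALSE] / gc$npix
  for (b in rev(seq_along(cfg$blocks))) {
    bc <- caches[[paste0("block", b)]]
    cur <- bpool_b(bc$pool, cur)
    cur <- relu_b(bc$trl, cur)
    bb <- bn_b(bc$tbn, cur, train)
    g[[nm(sprintf("t%d_bn", b))]] <- list(gamma = bb$gamma, beta = bb$beta)
    tb <- bconv3_b(bc$tcv, par[[nm(sprintf("t%d", b))]]$W, bb$dx, bc$sp, 1L,
                   bc$tcin)
    g[[nm(sprintf("t%d", b))]] <- list(W = tb$dW, b = tb$db)
    # split gradient of the block output into per-feature segments
    widths <- bc$widths
    dfeats <- list()
    off <- 0
    for (i in seq_along(widths)) {
      dfeats[[i]] <- tb$dx[, off + seq_len(widths[i]), drop = FALSE]
      off <- off + widths[i]
    }
    for (l in rev(seq_len(cfg$blocks[b]))) {
      lc <- bc$lay[[l]]
      dy <- relu_b(lc$rl, dfeats[[l + 1]])
      bb <- bn_b(lc$bn, dy, train)
      lname <- sprintf("b%d_l%d", b, l)
      g[[nm(paste0(lname, "_bn"))]] <- list(gamma = bb$gamma, beta = bb$beta)
      cb <- bconv3_b(lc$cv, par[[nm(lname)]]$W, bb$dx, bc$sp, 3L, lc$cin)
      g[[nm(lname)]] <- list(W = cb$dW, b = cb$db)
      off <- 0
      for (i in seq_len(l)) {
        dfeats[[i]] <- dfeats[[i]] +
          cb$dx[, off + seq_len(widths[i]), drop = FALSE]
        off <- off + widths[i]
      }
    }
    cur <- dfeats[[1]]
  }
  sc <- caches$stem
  cur <- bpool_b(sc$pool, cur)
  cur <- relu_b(sc$rl, cur)
  bb <- bn_b(sc$bn, cur, train)
  g[[nm("stem_bn")]] <- list(gamma = bb$gamma, beta = bb$beta)
  cb <- bconv3_b(sc$cv, par[[nm("stem")]]$W, bb$dx, sc$sp, 3L, 1L)
  g[[nm("stem")]] <- list(W = cb$dW, b = cb$db)
  g
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

patch_forward <- function(model, Xf, Xc, train = FALSE, dropout_mask = NULL) {
  cfg <- model$config
  par <- model$params
  f <- pathway_forward(par, model$bn_state, "f", Xf, cfg, train)
  c_ <- pathway_forward(par, f$bn_state, "c", Xc, cfg, train)
  merged <- cbind(f$out, c_$out)
  if (train && cfg$dropout > 0) {
    if (is.null(dropout_mask))
      dropout_mask <- matrix(stats::runif(length(merged)) >= cfg$dropout,
                             nrow(merged))
    dropped <- merged * dropout_mask / (1 - cfg$dropout)
  } else {
    dropout_mask <- NULL
    dropped <- merged
  }
  h1 <- addcol(dropped %*% par$fc1$W, par$fc1$b)
  r1 <- relu_f(h1)
  z <- addcol(r1$y %*% par$fc2$W, par$fc2$b)
  p <- softmax_rows(z)
  list(prob = p,
       cache = list(f = f$caches, c = c_$caches, merged = merged,
                    dropout_mask = dropout_mask, dropped = dropped, r1 = r1),
       bn_state = c_$bn_state)
}

patch_backward <- function(model, cache, dz, train = TRUE) {
  cfg <- model$config
  par <- model$params
  g <- list()
  dW2 <- crossprod(cache$r1$y, dz)
  g$fc2 <- list(W = dW2, b = colSums(dz))
  dr1 <- dz %*% t(par$fc2$W)
  dh1 <- relu_b(cache$r1, dr1)
  g$fc1 <- list(W = crossprod(cache$dropped, dh1), b = colSums(dh1))
  dmerged <- dh1 %*% t(par$fc1$W)
  if (!is.null(cache$dropout_mask))
    dmerged <- dmerged * cache$dropout_mask / (1 - cfg$dropout)
  nf <- ncol(cache$merged) / 2
  gf <- pathway_backward(par, cache$f, "f",
                         dmerged[, seq_len(nf), drop = FALSE], cfg, train)
  gc_ <- pathway_backward(par, cache$c, "c",
                          dmerged[, nf + seq_len(nf), drop = FALSE], cfg,
                          train)
  c(g, gf, gc_)
}

#' Train the patch classifier
#'
#' Mini-batch Adam with categorical cross-entropy on one-hot labels;
#' returns the weights (and batch-norm statistics) from the epoch with the
#' best validation accuracy.
#'
#' @param model A `patch_model`.
#' @param dataset Balanced dataset from `build_patch_dataset()`.
#' @param val_dataset Validation dataset of the same form.
#' @param seed Integer seed (shuffling, dropout).
#' @return The trained model with a `history` data.frame.
#' @export
train_patch_classifier <- function(model, dataset, val_dataset, seed = 1L) {
  if (length(dataset$patches) == 0) stop("empty patch dataset")
  cfg <- model$config
  mats <- patches_to_matrices(dataset$patches)
  vmats <- patches_to_matrices(val_dataset$patches)
  n <- length(dataset$patches)
  rows_of <- function(idx) as.vector(outer(1:3072, (idx - 1) * 3072, "+"))
  opt <- adam_init(model$params)
  # align the Adam state with a gradient ordering, fixed once
  best <- list(par = model$params, bn = model$bn_state, acc = -Inf)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_acc = numeric())
  with_seed(seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(n)
      tr_loss <- 0; nb <- 0
      for (start in seq(1, n, by = cfg$batch)) {
        idx <- ord[start:min(start + cfg$batch - 1, n)]
        rows <- rows_of(idx)
        Xf <- mats$fine[rows, , drop = FALSE]
        Xc <- mats$coarse[rows, , drop = FALSE]
        Y <- cbind(1 - dataset$label[idx], dataset$label[idx])
        fw <- patch_forward(model, Xf, Xc, train = TRUE)
        model$bn_state <- fw$bn_state
        p <- pmin(pmax(fw$prob, 1e-12), 1)
        loss <- -mean(rowSums(Y * log(p)))
        tr_loss <- tr_loss + loss; nb <- nb + 1
        dz <- (fw$prob - Y) / nrow(Y)
        g <- patch_backward(model, fw$cache, dz)
        g <- g[names(model$params)]
        st <- adam_step(model$params, g, opt, cfg$lr)
        model$params <- st$params
        opt <- st$state
      }
      vp <- classify_patches(model, NULL, mats = vmats)
      vacc <- mean((vp >= 0.5) == (val_dataset$label == 1))
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss / nb,
                                     val_acc = vacc))
      if (vacc > best$acc)
        best <- list(par = model$params, bn = model$bn_state, acc = vacc)
    }
  })
  model$params <- best$par
  model$bn_state <- best$bn
  model$history <- hist
  model
}

#' Classify patches
#'
#' Deterministic inference (dropout off, batch-norm running statistics);
#' returns the stroke-class probability per patch.
#'
#' @param model A trained `patch_model`.
#' @param patches List of `dual_patch` objects (or `NULL` when `mats` is
#'   given).
#' @param mats Optional pre-stacked matrices from `patches_to_matrices()`.
#' @param batch Inference batch size.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
classify_patches <- function(model, patches, mats = NULL, batch = 64L) {
  if (is.null(mats)) mats <- patches_to_matrices(patches)
  n <- nrow(mats$fine) / 3072
  out <- numeric(n)
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1, n)
    rows <- as.vector(outer(1:3072, (idx - 1) * 3072, "+"))
    fw <- patch_forward(model, mats$fine[rows, , drop = FALSE],
                        mats$coarse[rows, , drop = FALSE], train = FALSE)
    out[idx] <- fw$prob[, 2]
  }
  out
}
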