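# ---- training / inference / evaluation orchestration ------------------------

#' Training configuration
#'
#' Defaults follow the method's published settings: Adam, initial learning
#' rate 1e-4, batch size 1, dropout 0.5, Tversky loss with alpha = 0.3 /
#' beta = 0.7, 10-fold cross-validation.
#'
#' @param optimizer only `"adam"` is provided
#' @param learning_rate Adam initial learning rate
#' @param batch_size volumes per gradient step (gradients of a batch are
#'   accumulated sequentially; the reference setting is 1)
#' @param dropout dropout probability passed to the network
#' @param max_steps gradient steps to run
#' @param patch_size cubic training patch edge, divisible by 8
#' @param rng_seed master seed for init, patch sampling, augmentation, dropout
#' @param loss loss name: tversky, dice, gdl, bce, focal
#' @param loss_params named list of loss parameters (alpha, beta, gamma, ...)
#' @param k_folds folds for cross-validation drivers
#' @param val_fraction fraction of volumes held out for validation (>= 1
#'   volume whenever the dataset has more than one)
#' @param val_every validate (and checkpoint best-by-Dice) every so many steps
#' @param augment apply joint random flips to training patches
#' @return a `train_config` list
#' @export
train_config <- function(optimizer = "adam", learning_rate = 1e-4,
                         batch_size = 1L, dropout = 0.5, max_steps = 300L,
                         patch_size = 48L, rng_seed = 1L, loss = "tversky",
                         loss_params = list(alpha = 0.3, beta = 0.7),
                         k_folds = 10L, val_fraction = 0.1, val_every = 50L,
                         augment = TRUE) {
  if (!identical(optimizer, "adam")) stop("only the Adam optimizer is provided")
  if (patch_size %% 8L != 0L) stop("patch_size must be divisible by 8")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), dropout = dropout,
                 max_steps = as.integer(max_steps),
                 patch_size = as.integer(patch_size),
                 rng_seed = as.integer(rng_seed), loss = loss,
                 loss_params = loss_params, k_folds = as.integer(k_folds),
                 val_fraction = val_fraction,
                 val_every = as.integer(val_every), augment = isTRUE(augment)),
            class = "train_config")
}

#' Deterministic balanced k-fold split
#'
#' Shuffles the ids with the given seed and cuts them into k consecutive
#' chunks whose sizes differ by at most one.
#'
#' @param ids vector of volume identifiers
#' @param k number of folds (>= 2)
#' @param seed integer seed
#' @return list of k disjoint id vectors covering `ids`
#' @export
kfold_split <- function(ids, k, seed = 1L) {
  n <- length(ids)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k = ", k, " exceeds the number of ids (", n, ")")
  set.seed(seed)
  perm <- sample(ids)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  lapply(seq_len(k), function(i) perm[starts[i]:stops[i]])
}

# ---- Adam -------------------------------------------------------------------

.adam_init <- function(params) {
  lapply(params, function(p) list(m = array(0, dim = dim(p$value) %||%
                                              length(p$value)),
                                  v = array(0, dim = dim(p$value) %||%
                                              length(p$value))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adam_update <- function(params, state, t, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    state[[i]] <- st
  }
  state
}

# ---- helpers ----------------------------------------------------------------

.as_image_array <- function(x) {
  a <- if (inherits(x, "ct_volume")) x$voxels else x
  storage.mode(a) <- "double"
  a
}
.as_label_array <- function(x) {
  a <- if (inherits(x, "mask_volume")) x$voxels else x
  array(as.integer(a), dim = dim(a))
}

# random cubic patch (edge `ps`) cut jointly from image and label
.sample_patch <- function(img, lab, ps) {
  d <- dim(img)
  lo <- vapply(1:3, function(a) {
    if (d[a] <= ps) 1L else sample.int(d[a] - ps + 1L, 1L)
  }, integer(1))
  hi <- pmin(lo + ps - 1L, d)
  list(image = img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       label = lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
}

#' Preprocess a phantom dataset for training
#'
#' Applies the standard chain (HU clip, isotropic resampling, z-score) to
#' each image and pairs it with its resampled label. Phantoms use the whole
#' volume as ROI, so no liver-mask cropping is involved.
#'
#' @param dataset output of [make_dataset()]
#' @param config a [preprocess_config()]
#' @return list of `list(image = array, label = array)` ready for [train()]
#' @export
preprocess_dataset <- function(dataset, config = preprocess_config()) {
  lapply(dataset, function(item) {
    pp <- preprocess_volume(item$image, item$label, config)
    list(image = .as_image_array(pp$image), label = .as_label_array(pp$label))
  })
}

# ---- training ---------------------------------------------------------------

#' Train the improved V-Net on a dataset
#'
#' Runs Adam (lr from the config, batch accumulation for batch_size > 1) on
#' the deep-supervision total loss. A validation subset
#' (`max(1, val_fraction * n)` volumes when n > 1) is held out; the
#' parameters with the best validation Dice are kept as the checkpoint.
#' Fully deterministic for a fixed `rng_seed` (single-threaded; all
#' randomness flows from the R RNG).
#'
#' @param dataset list of `list(image, label)` pairs (arrays or volumes),
#'   already preprocessed
#' @param cfg a [train_config()]
#' @param network_cfg a [network_config()]; its dropout is overridden by the
#'   training config
#' @param verbose print progress lines
#' @return object of class `vnet_run`: `model`, `checkpoint`, `manifest`
#'   (config snapshot, seed, per-step loss terms, validation history)
#' @export
train <- function(dataset, cfg = train_config(),
                  network_cfg = network_config(), verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty dataset")
  network_cfg$dropout_p <- cfg$dropout
  set.seed(cfg$rng_seed)
  model <- vnet_build(network_cfg, seed = NULL)
  loss_fn <- do.call(make_loss, c(list(name = cfg$loss), cfg$loss_params))

  imgs <- lapply(dataset, function(d) .as_image_array(d$image))
  labs <- lapply(dataset, function(d) .as_label_array(d$label))
  n <- length(imgs)
  n_val <- if (n > 1L) max(1L, floor(cfg$val_fraction * n)) else 0L
  perm <- sample.int(n)
  val_ids <- sort(perm[seq_len(n_val)])
  train_ids <- setdiff(seq_len(n), val_ids)
  if (length(train_ids) == 0L) stop("no volumes left for training")

  params <- model$params
  state <- .adam_init(params)
  hist <- vector("list", cfg$max_steps)
  val_hist <- list()
  best <- list(dice = -Inf, values = NULL, step = 0L)
  ps <- cfg$patch_size

  snapshot <- function() lapply(params, function(p) p$value)
  validate <- function(step) {
    if (n_val == 0L) return(invisible(NULL))
    dices <- vapply(val_ids, function(v) {
      pr <- predict_volume(model, imgs[[v]], apply_postprocess = FALSE)
      d <- dice_overlap_crosscheck(pr$mask, labs[[v]])
      if (is.na(d)) 0 else d
    }, numeric(1))
    vd <- mean(dices)
    val_hist[[length(val_hist) + 1L]] <<- data.frame(step = step, dice = vd)
    if (vd > best$dice) best <<- list(dice = vd, values = snapshot(),
                                      step = step)
    vd
  }

  draw <- integer(0)
  for (step in seq_len(cfg$max_steps)) {
    for (p in params) p$grad <- NULL
    acc <- NULL
    terms_acc <- NULL
    for (b in seq_len(cfg$batch_size)) {
      if (length(draw) == 0L) draw <- sample(train_ids)
      vol <- draw[1L]; draw <- draw[-1L]
      pat <- .sample_patch(imgs[[vol]], labs[[vol]], ps)
      if (cfg$augment) {
        fl <- augment_flip(pat$image, pat$label)
        pat <- list(image = fl$image, label = fl$label)
      }
      out <- vnet_forward(model, pat$image, training = TRUE)
      sl <- supervision_total_loss(out, pat$label, loss_fn)
      if (!all(is.finite(sl$terms))) {
        bad <- names(sl$terms)[!is.finite(sl$terms)]
        stop("non-finite loss at step ", step, " in term(s): ",
             paste(bad, collapse = ", "))
      }
      ag_backward(sl$total, seed = 1 / cfg$batch_size)
      acc <- if (is.null(acc)) sl$total$value else acc + sl$total$value
      terms_acc <- if (is.null(terms_acc)) sl$terms else terms_acc + sl$terms
    }
    state <- .adam_update(params, state, step, cfg$learning_rate)
    hist[[step]] <- data.frame(step = step,
                               total = acc / cfg$batch_size,
                               t(terms_acc / cfg$batch_size))
    if (step %% cfg$val_every == 0L || step == cfg$max_steps) {
      vd <- validate(step)
      if (verbose)
        cat(sprintf("step %4d  loss %.4f  val dice %s\n", step,
                    acc / cfg$batch_size,
                    ifelse(is.null(vd), "-", sprintf("%.4f", vd))))
    } else if (verbose && step %% 10L == 0L) {
      cat(sprintf("step %4d  loss %.4f\n", step, acc / cfg$batch_size))
    }
  }
  if (is.null(best$values)) best <- list(dice = NA_real_, values = snapshot(),
                                         step = cfg$max_steps)
  # restore best-by-validation parameters into the model
  for (nm in names(params)) params[[nm]]$value <- best$values[[nm]]

  manifest <- list(train_config = cfg, network_config = network_cfg,
                   seed = cfg$rng_seed, n_volumes = n, val_ids = val_ids,
                   loss_history = do.call(rbind, hist),
                   val_history = if (length(val_hist))
                     do.call(rbind, val_hist) else NULL,
                   best_val_dice = best$dice, best_step = best$step)
  structure(list(model = model,
                 checkpoint = list(values = best$values,
                                   network_config = network_cfg,
                                   train_config = cfg),
                 manifest = manifest),
            class = "vnet_run")
}

#' @export
print.vnet_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("vnet_run: %d steps, loss %s, best val dice %.4f (step %d)\n",
              m$train_config$max_steps, m$train_config$loss,
              m$best_val_dice, m$best_step))
  invisible(x)
}

#' Save / load a checkpoint
#'
#' The checkpoint embeds the network configuration, so loading rebuilds the
#' model and restores its parameter values exactly.
#'
#' @param run a `vnet_run` (or a bare checkpoint list)
#' @param path file path
#' @return `checkpoint_load` returns a `vnet3d` model
#' @export
checkpoint_save <- function(run, path) {
  ckpt <- if (inherits(run, "vnet_run")) run$checkpoint else run
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname checkpoint_save
#' @export
checkpoint_load <- function(path) {
  ckpt <- readRDS(path)
  model <- vnet_build(ckpt$network_config, seed = 0L)
  for (nm in names(model$params)) {
    if (is.null(ckpt$values[[nm]]))
      stop("checkpoint/config mismatch: missing parameter ", nm)
    model$params[[nm]]$value <- ckpt$values[[nm]]
  }
  model
}

# ---- inference --------------------------------------------------------------

#' Segment a volume with a trained model
#'
#' Pads the volume symmetrically (zeros, i.e. the post-normalization mean) to
#' the next multiple of 8 per axis, runs the network in evaluation mode,
#' removes the padding, takes the per-voxel argmax and optionally applies the
#' connected-component volume filter.
#'
#' @param model a `vnet3d` model, `vnet_run`, or checkpoint path
#' @param image preprocessed [ct_volume()] or 3-D array
#' @param apply_postprocess remove components smaller than `min_volume_mm3`
#' @param min_volume_mm3 post-filter threshold (default 180)
#' @param connectivity component adjacency, 26 or 6
#' @return list: `prob` (array (nx,ny,nz,2): foreground then background
#'   probability), `mask` ([mask_volume()]), `report` (post-filter component
#'   table, if applied)
#' @export
predict_volume <- function(model, image, apply_postprocess = TRUE,
                           min_volume_mm3 = 180, connectivity = 26) {
  if (inherits(model, "vnet_run")) model <- model$model
  if (is.character(model)) model <- checkpoint_load(model)
  spacing <- if (inherits(image, "ct_volume")) image$spacing else c(1, 1, 1)
  arr <- .as_image_array(image)
  d <- dim(arr)
  target <- as.integer(ceiling(d / 8) * 8)
  pad_lo <- (target - d) %/% 2L
  padded <- array(0, dim = target)
  padded[pad_lo[1] + seq_len(d[1]), pad_lo[2] + seq_len(d[2]),
         pad_lo[3] + seq_len(d[3])] <- arr
  out <- vnet_forward(model, padded, training = FALSE)
  probs <- out$probs$value
  probs <- probs[pad_lo[1] + seq_len(d[1]), pad_lo[2] + seq_len(d[2]),
                 pad_lo[3] + seq_len(d[3]), , drop = FALSE]
  p0 <- array(probs[, , , 1], dim = d)
  mask <- mask_volume(array(as.integer(p0 >= 0.5), dim = d),
                      spacing = spacing)
  report <- NULL
  if (apply_postprocess) {
    fl <- filter_small_components(mask, min_volume_mm3 = min_volume_mm3,
                                  connectivity = connectivity)
    mask <- fl$mask
    report <- fl$report
  }
  list(prob = probs, mask = mask, report = report)
}

# ---- loss-comparison harness ------------------------------------------------

#' Train the same model under several losses and compare the metrics
#'
#' One model per loss, identical seed and configuration otherwise; each is
#' evaluated on the held-out volumes (the run's validation set by default, or
#' an explicit evaluation set) with the full metrics report.
#'
#' @param dataset preprocessed training dataset
#' @param base_cfg a [train_config()] used for every run (its `loss` and
#'   `loss_params` are overridden per row)
#' @param losses named list: loss name -> list of loss parameters, e.g.
#'   `list(tversky = list(alpha = 0.3, beta = 0.7), dice = list())`
#' @param network_cfg a [network_config()]
#' @param eval_dataset optional list of `list(image, label)` used for
#'   evaluation instead of each run's validation volumes
#' @param apply_postprocess post-filter predictions before scoring
#' @return list: `table` (one metrics row per loss) and `runs`
#' @export
compare_losses <- function(dataset, base_cfg = train_config(),
                           losses = list(tversky = list(alpha = 0.3,
                                                        beta = 0.7),
                                         dice = list()),
                           network_cfg = network_config(),
                           eval_dataset = NULL, apply_postprocess = FALSE) {
  known <- c("tversky", "dice", "gdl", "bce", "focal")
  bad <- setdiff(names(losses), known)
  if (length(bad)) stop("unknown loss name(s): ", paste(bad, collapse = ", "))
  runs <- list()
  rows <- list()
  for (nm in names(losses)) {
    cfg <- base_cfg
    cfg$loss <- nm
    cfg$loss_params <- losses[[nm]]
    run <- train(dataset, cfg, network_cfg)
    runs[[nm]] <- run
    evset <- eval_dataset %||% lapply(run$manifest$val_ids, function(v)
      dataset[[v]])
    reps <- lapply(evset, function(item) {
      pr <- predict_volume(run$model, item$image,
                           apply_postprocess = apply_postprocess)
      metrics_report(pr$mask, .as_label_array(item$label))
    })
    mr <- do.call(rbind, reps)
    rows[[nm]] <- data.frame(loss = nm, dice = mean(mr$dice),
                             accuracy = mean(mr$accuracy),
                             sensitivity = mean(mr$sensitivity),
                             specificity = mean(mr$specificity))
  }
  list(table = do.call(rbind, rows), runs = runs)
}

# ---- YAML configuration -----------------------------------------------------

#' Load a run configuration from a YAML file
#'
#' Recognized blocks: `phantom`, `preprocess`, `network`, `train`,
#' `loss` (merged into the train config), `postprocess`. Unknown keys are
#' rejected so manifests stay trustworthy.
#'
#' @param path YAML file
#' @return list of config objects (`phantom`, `preprocess`, `network`,
#'   `train`, `postprocess`)
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("phantom", "preprocess", "network", "train", "loss",
             "supervision", "postprocess")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  build <- function(ctor, args) do.call(ctor, args %||% list())
  net_args <- y$network %||% list()
  if (!is.null(y$supervision$merge))
    net_args$fusion_merge <- y$supervision$merge
  cfg <- list(
    phantom = build(phantom_config, y$phantom),
    preprocess = build(preprocess_config, y$preprocess),
    network = build(network_config, net_args),
    train = build(train_config, y$train),
    postprocess = y$postprocess %||% list(min_volume_mm3 = 180,
                                          connectivity = 26))
  if (!is.null(y$loss)) {
    cfg$train$loss <- y$loss$name %||% cfg$train$loss
    cfg$train$loss_params <- y$loss[setdiff(names(y$loss), "name")]
  }
  cfg
}
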