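# Training, evaluation and prediction drivers. SGD with Nesterov-free
# momentum, weight decay and polynomial learning-rate decay (the standard
# recipe for segmentation networks trained at base lr 0.0025); Adam is
# available as an option. All randomness (weight init, batch shuffling,
# dropout) is driven by the config seed.

#' Training configuration
#'
#' @param lr base learning rate (default 0.0025).
#' @param epochs maximum epochs (default 400).
#' @param max_iters optional hard cap on total iterations (overrides
#'   `epochs` when reached first); useful for short mechanism checks.
#' @param batch_size images per iteration (default 6).
#' @param optimizer `"sgd"` (momentum 0.9) or `"adam"`.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coefficient.
#' @param poly_power exponent of the polynomial lr decay
#'   `lr * (1 - t/T)^power`; 0 disables decay.
#' @param seed integer seed controlling init, shuffling and dropout.
#' @param eval_every compute the monitored training/validation mIoU every
#'   this many iterations (0 = only at the end).
#' @param stop_miou early-stop threshold on the monitored mIoU (NULL = run
#'   to the end).
#' @param checkpoint_path optional RDS path; the best-validation (or, with
#'   no validation split, the final) model is saved there.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 0.0025, epochs = 400L, max_iters = NULL,
                         batch_size = 6L,
                         optimizer = c("sgd", "adam"), momentum = 0.9,
                         weight_decay = 1e-4, poly_power = 0.9, seed = 1L,
                         eval_every = 0L, stop_miou = NULL,
                         checkpoint_path = NULL) {
  optimizer <- match.arg(optimizer)
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 max_iters = max_iters, batch_size = as.integer(batch_size),
                 optimizer = optimizer, momentum = momentum,
                 weight_decay = weight_decay, poly_power = poly_power,
                 seed = as.integer(seed), eval_every = as.integer(eval_every),
                 stop_miou = stop_miou, checkpoint_path = checkpoint_path),
            class = "train_config")
}

make_optimizer <- function(cfg) {
  state <- new.env(parent = emptyenv())
  state$buf <- list()
  state$t <- 0L
  if (cfg$optimizer == "sgd") {
    function(params, lr) {
      for (nm in names(params)) {
        p <- params[[nm]]
        g <- p$grad + cfg$weight_decay * p$value
        b <- state$buf[[nm]] %||% array(0, dim = dim(p$value) %||% length(p$value))
        b <- cfg$momentum * b + g
        state$buf[[nm]] <- b
        p$value <- p$value - lr * b
      }
    }
  } else {
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    function(params, lr) {
      state$t <- state$t + 1L
      for (nm in names(params)) {
        p <- params[[nm]]
        g <- p$grad + cfg$weight_decay * p$value
        m <- state$buf[[paste0(nm, ".m")]] %||% 0
        v <- state$buf[[paste0(nm, ".v")]] %||% 0
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        state$buf[[paste0(nm, ".m")]] <- m
        state$buf[[paste0(nm, ".v")]] <- v
        mh <- m / (1 - beta1^state$t); vh <- v / (1 - beta2^state$t)
        p$value <- p$value - lr * mh / (sqrt(vh) + eps)
      }
    }
  }
}

#' Train a network
#'
#' Iterates mini-batches of the training pairs, minimizing the configured
#' loss; logs per-iteration loss and periodic mIoU of the monitored split
#' (validation if provided, else training). The best monitored model is
#' kept when a checkpoint path is configured.
#'
#' @param train_pairs list of `sample_pair`s (equal sizes).
#' @param val_pairs optional validation pairs.
#' @param net_cfg a [network_config()].
#' @param loss_cfg a [loss_config()].
#' @param cfg a [train_config()].
#' @param label run label recorded in the history (defaults to
#'   "erfnet-baseline" for the all-flags-off cross-entropy config, else
#'   "epanet" with the active flags).
#' @param verbose print progress lines.
#' @return list with `net`, `history` (data frame: iter, epoch, lr, loss,
#'   miou where evaluated), `label`, `best_miou`.
#' @export
epanet_train <- function(train_pairs, val_pairs = NULL,
                         net_cfg = network_config(),
                         loss_cfg = loss_config(),
                         cfg = train_config(), label = NULL,
                         verbose = FALSE) {
  if (!length(train_pairs)) stop("no training pairs")
  label <- label %||% config_label(net_cfg, loss_cfg)
  set.seed(cfg$seed)
  net <- epanet_build(net_cfg)
  step <- make_optimizer(cfg)
  n <- length(train_pairs)
  batches_per_epoch <- ceiling(n / cfg$batch_size)
  total <- cfg$max_iters %||% (cfg$epochs * batches_per_epoch)
  monitored <- val_pairs %||% train_pairs
  history <- list()
  best <- -Inf
  it <- 0L
  done <- FALSE
  for (epoch in seq_len(cfg$epochs)) {
    if (done) break
    ord <- sample.int(n)
    for (bi in seq_len(batches_per_epoch)) {
      idx <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, n)]
      batch <- pairs_to_batch(train_pairs[idx])
      lr_t <- if (cfg$poly_power > 0)
        cfg$lr * (1 - it / total)^cfg$poly_power else cfg$lr
      loss_val <- tryCatch(
        with_tape({
          logits <- ag_epanet_forward(net, ag_node(batch$x), training = TRUE)
          loss <- ag_total_loss(logits, batch$y, loss_cfg)
          ag_backward(loss)
          loss$value
        }),
        error = function(e) {
          if (grepl("non-finite", conditionMessage(e)))
            stop("training diverged at iteration ", it + 1L, " (",
                 conditionMessage(e), "); lower the learning rate",
                 call. = FALSE)
          stop(e)
        })
      if (!is.finite(loss_val))
        stop("training diverged at iteration ", it + 1L,
             " (loss = ", loss_val, "); lower the learning rate")
      params <- collect_params(net)
      step(params, lr_t)
      ag_zero_grad(params)
      it <- it + 1L
      rec <- list(iter = it, epoch = epoch, lr = lr_t, loss = loss_val,
                  miou = NA_real_)
      if (cfg$eval_every > 0 && it %% cfg$eval_every == 0L) {
        rep <- epanet_evaluate(net, monitored, batch_size = cfg$batch_size,
                               ignore_index = loss_cfg$ignore_index)
        rec$miou <- rep$miou / 100
        if (rec$miou > best) {
          best <- rec$miou
          if (!is.null(cfg$checkpoint_path))
            save_checkpoint(net, cfg$checkpoint_path,
                            extra = list(label = label, iter = it,
                                         miou = best))
        }
        if (verbose)
          message(sprintf("[%s] iter %d loss %.4f mIoU %.4f",
                          label, it, loss_val, rec$miou))
        if (!is.null(cfg$stop_miou) && rec$miou >= cfg$stop_miou)
          done <- TRUE
      } else if (verbose && it %% 10L == 0L) {
        message(sprintf("[%s] iter %d loss %.4f", label, it, loss_val))
      }
      history[[length(history) + 1L]] <- rec
      if (it >= total) done <- TRUE
      if (done) break
    }
  }
  if (best == -Inf) {
    rep <- epanet_evaluate(net, monitored, batch_size = cfg$batch_size,
                           ignore_index = loss_cfg$ignore_index)
    best <- rep$miou / 100
    if (!is.null(cfg$checkpoint_path))
      save_checkpoint(net, cfg$checkpoint_path,
                      extra = list(label = label, iter = it, miou = best))
  }
  list(net = net, history = do.call(rbind, lapply(history, as.data.frame)),
       label = label, best_miou = best)
}

config_label <- function(net_cfg, loss_cfg) {
  ce_only <- loss_cfg$dice_weight == 0
  if (!net_cfg$simam && !net_cfg$fdpn && !net_cfg$psa && ce_only)
    return("erfnet-baseline")
  if (net_cfg$simam && net_cfg$fdpn && net_cfg$psa && !ce_only)
    return("epanet")
  paste0("erf", if (net_cfg$psa) "+psa" else "",
         if (!ce_only) "+doubleloss" else "+ce",
         if (net_cfg$simam) "+simam" else "",
         if (net_cfg$fdpn) "+fdpn" else "")
}

#' Evaluate a network on a set of pairs
#'
#' Eval-mode forward (running batch statistics, no dropout), confusion
#' matrix accumulated across batches, full metric report.
#'
#' @param net network module.
#' @param pairs list of `sample_pair`s.
#' @param batch_size evaluation batch size.
#' @param ignore_index optional 0-based label excluded from scoring.
#' @return a `metrics_report`.
#' @export
epanet_evaluate <- function(net, pairs, batch_size = 8L,
                            ignore_index = NULL) {
  K <- net$cfg$num_classes
  cm <- confusion_matrix(K)
  n <- length(pairs)
  for (b in seq_len(ceiling(n / batch_size))) {
    idx <- ((b - 1L) * batch_size + 1L):min(b * batch_size, n)
    batch <- pairs_to_batch(pairs[idx])
    pred <- epanet_predict_mask(net, batch$x)
    cm <- cm_accumulate(cm, pred, batch$y, ignore_index)
  }
  compute_report(cm)
}

#' Segment one image and write the mask PNG
#'
#' @param net network module (or result of [load_checkpoint()]'s `net`).
#' @param image path to an RGB PNG, or an `[H, W, 3]` array in `[0, 1]`;
#'   H and W must be divisible by 8.
#' @param out output PNG path for the palette-colored mask.
#' @param palette mask palette.
#' @param overlay optional path for a 50/50 color overlay on the input.
#' @return the predicted integer mask, invisibly.
#' @export
epanet_predict <- function(net, image, out = NULL,
                           palette = default_palette(), overlay = NULL) {
  img <- if (is.character(image)) {
    if (!file.exists(image)) stop("cannot read image: ", image)
    arr <- png::readPNG(image)
    if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
    arr[, , 1:3, drop = FALSE]
  } else image
  d <- dim(img)
  if (d[1] %% 8L || d[2] %% 8L)
    stop("image size ", d[1], "x", d[2], " is not divisible by 8")
  x <- array(img, dim = c(d[1], d[2], 3, 1))
  mask <- epanet_predict_mask(net, x)[, , 1]
  if (!is.null(out)) png::writePNG(rgb_from_mask(mask, palette), out)
  if (!is.null(overlay)) {
    ov <- 0.5 * img + 0.5 * rgb_from_mask(mask, palette)
    png::writePNG(pmin(pmax(ov, 0), 1), overlay)
  }
  invisible(mask)
}
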