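# EPAnet assembly: a 24-layer encoder-decoder. Layers 1-16 form the encoder
# (three stages, each opened by a concat downsampler followed by SimAM, the
# deeper two stages stacked with Non-bottleneck-1D blocks); layers 17-24
# form the decoder (transposed-conv upsamplers and Non-bt-1D blocks, the
# PSA head at the second-to-last position, and a final transposed conv
# straight to class logits). Encoder taps at strides 2/4/8 feed the FDPN
# connector, whose fused maps are injected into the decoder at strides 4
# and 2.

#' Network configuration
#'
#' @param num_classes number of segmentation classes (>= 2; default 3:
#'   background, bean seedling, weed).
#' @param stage_widths strictly increasing channel widths of the three
#'   encoder stages; default `c(16, 64, 128)`.
#' @param dilation_schedule dilations of the eight stage-3 Non-bt-1D blocks;
#'   default `c(2, 4, 8, 16, 2, 4, 8, 16)`.
#' @param simam enable SimAM after each downsampler.
#' @param simam_lambda SimAM regularization constant.
#' @param fdpn enable the FDPN connector.
#' @param fdpn_channels fused pyramid width.
#' @param fdpn_upsample `"nearest"` or `"bilinear"` top-down upsampling.
#' @param psa enable the PSA decoder head (layer 23).
#' @param psa_reduced_channels C2 of the PSA head (default half of the
#'   finest decoder width).
#' @param psa_max_attention_size spatial cap of the PSA attention grid.
#' @param dropout_stage2,dropout_stage3 dropout probabilities of the
#'   encoder Non-bt-1D blocks (decoder blocks use none).
#' @return object of class `network_config`.
#' @export
network_config <- function(num_classes = 3L,
                           stage_widths = c(16L, 64L, 128L),
                           dilation_schedule = c(2L, 4L, 8L, 16L,
                                                 2L, 4L, 8L, 16L),
                           simam = TRUE, simam_lambda = 1e-4,
                           fdpn = TRUE, fdpn_channels = 64L,
                           fdpn_upsample = "nearest",
                           psa = TRUE, psa_reduced_channels = NULL,
                           psa_max_attention_size = 32L,
                           dropout_stage2 = 0.03, dropout_stage3 = 0.3) {
  if (num_classes < 2) stop("num_classes must be >= 2")
  if (length(stage_widths) != 3 || any(diff(stage_widths) <= 0))
    stop("stage_widths must be three strictly increasing integers")
  if (length(dilation_schedule) != 8)
    stop("dilation_schedule must list eight dilations")
  structure(list(
    num_classes = as.integer(num_classes),
    stage_widths = as.integer(stage_widths),
    dilation_schedule = as.integer(dilation_schedule),
    simam = isTRUE(simam), simam_lambda = simam_lambda,
    fdpn = isTRUE(fdpn), fdpn_channels = as.integer(fdpn_channels),
    fdpn_upsample = fdpn_upsample,
    psa = isTRUE(psa),
    psa_reduced_channels = psa_reduced_channels,
    psa_max_attention_size = as.integer(psa_max_attention_size),
    dropout_stage2 = dropout_stage2, dropout_stage3 = dropout_stage3
  ), class = "network_config")
}

#' Build the network
#'
#' Layer schedule (default config): L1 down(3->16)+SimAM; L2 down(16->64)
#' +SimAM; L3-L7 Non-bt-1D(64); L8 down(64->128)+SimAM; L9-L16
#' Non-bt-1D(128) with the dilation schedule; L17 up(128->64); L18-L19
#' Non-bt-1D(64); L20 up(64->16); L21-L22 Non-bt-1D(16); L23 PSA head(16);
#' L24 up(16->num_classes), plain logits. Disabled flags remove exactly
#' their module from the graph.
#'
#' @param cfg a [network_config()].
#' @param seed optional integer seed for weight initialization.
#' @return a network module (fields `cfg`, `layer_names`).
#' @export
epanet_build <- function(cfg = network_config(), seed = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  w <- cfg$stage_widths
  net <- new_module("epanet")
  net$cfg <- cfg
  add <- function(name, mod) net$submodules[[name]] <<- mod

  add("L01_down", downsampler(3L, w[1]))
  add("L02_down", downsampler(w[1], w[2]))
  for (k in 3:7)
    add(sprintf("L%02d_nonbt", k),
        non_bt_1d(w[2], 1L, cfg$dropout_stage2))
  add("L08_down", downsampler(w[2], w[3]))
  for (k in 9:16)
    add(sprintf("L%02d_nonbt", k),
        non_bt_1d(w[3], cfg$dilation_schedule[k - 8L], cfg$dropout_stage3))
  add("L17_up", upsampler(w[3], w[2]))
  add("L18_nonbt", non_bt_1d(w[2], 1L, 0))
  add("L19_nonbt", non_bt_1d(w[2], 1L, 0))
  add("L20_up", upsampler(w[2], w[1]))
  add("L21_nonbt", non_bt_1d(w[1], 1L, 0))
  add("L22_nonbt", non_bt_1d(w[1], 1L, 0))
  if (cfg$psa) {
    c2 <- cfg$psa_reduced_channels %||% max(1L, w[1] %/% 2L)
    add("L23_psa", psa_head(psa_head_config(w[1], c2,
                                            cfg$psa_max_attention_size)))
  }
  add("L24_up", upsampler(w[1], cfg$num_classes, bn_relu = FALSE))
  if (cfg$fdpn)
    net$submodules$fdpn <- fdpn_module(w, cfg$fdpn_channels,
                                       cfg$fdpn_upsample,
                                       decoder_widths = c(w[2], w[1]),
                                       smooth_levels = 1:2)
  net$layer_names <- grep("^L", names(net$submodules), value = TRUE)
  net$simam_cfg <- simam_config(cfg$simam_lambda)
  net$forward <- function(x, training = FALSE) {
    ag_epanet_forward(net, x, training)
  }
  net
}

ag_epanet_forward <- function(net, x, training = FALSE, trace = NULL) {
  x <- as_node(x)
  d <- dim(ag_value(x))
  if (length(d) != 4 || d[3] != 3L)
    stop("input must be [H, W, 3, N]")
  if (d[1] %% 8L || d[2] %% 8L)
    stop("input H and W must be divisible by 8, got ", d[1], "x", d[2])
  cfg <- net$cfg
  s <- net$submodules
  note <- function(name, h) {
    if (!is.null(trace)) trace[[name]] <- dim(ag_value(h))[1:3]
    h
  }
  att <- function(h) if (cfg$simam) ag_apply_simam(h, net$simam_cfg) else h

  t1 <- att(s$L01_down$forward(x, training)); note("L01_down", t1)
  t2 <- att(s$L02_down$forward(t1, training)); note("L02_down", t2)
  h <- t2
  for (k in 3:7) h <- note(sprintf("L%02d_nonbt", k),
                           s[[sprintf("L%02d_nonbt", k)]]$forward(h, training))
  t3 <- att(s$L08_down$forward(h, training)); note("L08_down", t3)
  h <- t3
  for (k in 9:16) h <- note(sprintf("L%02d_nonbt", k),
                            s[[sprintf("L%02d_nonbt", k)]]$forward(h, training))

  fused <- NULL
  if (cfg$fdpn)
    fused <- fuse_topdown(collect_pyramid(list(t1, t2, t3)), s$fdpn, training)

  h <- note("L17_up", s$L17_up$forward(h, training))
  if (cfg$fdpn) h <- inject_into_decoder(s$fdpn, fused$stride4, h, 4L)
  h <- note("L18_nonbt", s$L18_nonbt$forward(h, training))
  h <- note("L19_nonbt", s$L19_nonbt$forward(h, training))
  h <- note("L20_up", s$L20_up$forward(h, training))
  if (cfg$fdpn) h <- inject_into_decoder(s$fdpn, fused$stride2, h, 2L)
  h <- note("L21_nonbt", s$L21_nonbt$forward(h, training))
  h <- note("L22_nonbt", s$L22_nonbt$forward(h, training))
  if (cfg$psa) h <- note("L23_psa", s$L23_psa$forward(h, training))
  note("L24_up", s$L24_up$forward(h, training))
}

#' Forward pass returning logits
#'
#' @param net network from [epanet_build()].
#' @param x image batch `[H, W, 3, N]`, values typically in `[0, 1]`; H and
#'   W must be divisible by 8.
#' @param training forward in training mode (batch statistics, dropout).
#' @return logits array `[H, W, num_classes, N]`.
#' @export
epanet_forward <- function(net, x, training = FALSE) {
  ag_value(ag_epanet_forward(net, as_node(as_feature_map(x)), training))
}

#' Per-layer spatial-size trace of a forward pass
#'
#' @inheritParams epanet_forward
#' @return named list mapping layer names to `c(H, W, C)` output shapes.
#' @export
epanet_shape_trace <- function(net, x) {
  trace <- new.env(parent = emptyenv())
  ag_epanet_forward(net, as_node(as_feature_map(x)), FALSE, trace = trace)
  out <- as.list(trace)
  out[order(names(out))]
}

#' Argmax class prediction
#'
#' @inheritParams epanet_forward
#' @return integer array `[H, W, N]` of 0-based class indices.
#' @export
epanet_predict_mask <- function(net, x) {
  logits <- epanet_forward(net, x)
  logits_to_mask(logits)
}

#' Convert logits to a 0-based class mask
#' @param logits array `[H, W, K, N]` (or `[H, W, K]`).
#' @return integer array `[H, W, N]`.
#' @export
logits_to_mask <- function(logits) {
  logits <- as_feature_map(logits)
  d <- dim(logits)
  pm <- matrix(aperm(logits, c(3, 1, 2, 4)), d[3], d[1] * d[2] * d[4])
  array(max.col(t(pm), ties.method = "first") - 1L, dim = d[c(1, 2, 4)])
}

# ---- ablation presets -------------------------------------------------------

#' Ablation presets mirroring the incremental model variants
#'
#' Five configurations: the ERFnet baseline with plain cross-entropy, then
#' PSA, the coupled loss, SimAM and FDPN added one at a time.
#'
#' @param name one of `"erfnet-baseline"`, `"erf-psa-ce"`,
#'   `"erf-psa-doubleloss"`, `"erf-psa-doubleloss-simam"`, `"epanet-full"`.
#' @return list with `network` ([network_config()]), `loss`
#'   ([loss_config()]) and `label`.
#' @export
epanet_preset <- function(name = c("erfnet-baseline", "erf-psa-ce",
                                   "erf-psa-doubleloss",
                                   "erf-psa-doubleloss-simam",
                                   "epanet-full")) {
  name <- match.arg(name)
  flags <- switch(name,
    "erfnet-baseline"          = list(psa = FALSE, simam = FALSE, fdpn = FALSE, ce = TRUE),
    "erf-psa-ce"               = list(psa = TRUE,  simam = FALSE, fdpn = FALSE, ce = TRUE),
    "erf-psa-doubleloss"       = list(psa = TRUE,  simam = FALSE, fdpn = FALSE, ce = FALSE),
    "erf-psa-doubleloss-simam" = list(psa = TRUE,  simam = TRUE,  fdpn = FALSE, ce = FALSE),
    "epanet-full"              = list(psa = TRUE,  simam = TRUE,  fdpn = TRUE,  ce = FALSE))
  loss <- if (flags$ce) loss_config(ce_weight = 1, dice_weight = 0)
          else loss_config()
  list(network = network_config(simam = flags$simam, fdpn = flags$fdpn,
                                psa = flags$psa),
       loss = loss, label = name)
}

# ---- checkpoints ------------------------------------------------------------

# Walk a module tree collecting batch-norm layers by dotted path.
collect_bn_layers <- function(module, prefix = "") {
  out <- list()
  if (identical(module$kind, "batchnorm")) out[[prefix]] <- module
  for (nm in names(module$submodules)) {
    sub <- collect_bn_layers(module$submodules[[nm]],
                             if (prefix == "") nm else paste0(prefix, ".", nm))
    out <- c(out, sub)
  }
  out
}

#' Save a network checkpoint
#'
#' Stores the architecture config, all parameter arrays and batch-norm
#' running statistics in one RDS file.
#'
#' @param net network module.
#' @param path output file.
#' @param extra optional named list stored alongside (e.g. training
#'   history).
#' @export
save_checkpoint <- function(net, path, extra = list()) {
  params <- lapply(collect_params(net), function(p) p$value)
  bns <- collect_bn_layers(net)
  stats <- lapply(bns, function(b)
    list(mean = b$running_mean, var = b$running_var))
  saveRDS(list(config = net$cfg, params = params, bn_stats = stats,
               extra = extra), path)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return list with `net` (rebuilt network) and `extra`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- epanet_build(ck$config)
  # lazily-created PSA adaption layers must exist before assignment
  for (nm in names(ck$params)) {
    mt <- regmatches(nm, regexec(
      "L23_psa\\.adaption_(collect|distribute)_(\\d+)x(\\d+)\\.", nm))[[1]]
    if (length(mt) == 4)
      net$submodules$L23_psa$adaption_for(as.integer(mt[3]),
                                          as.integer(mt[4]), mt[2])
  }
  params <- collect_params(net)
  for (nm in names(ck$params)) {
    if (is.null(params[[nm]]))
      stop("checkpoint parameter ", nm, " has no slot in the rebuilt network")
    stopifnot(length(params[[nm]]$value) == length(ck$params[[nm]]))
    params[[nm]]$value <- ck$params[[nm]]
  }
  bns <- collect_bn_layers(net)
  for (nm in names(ck$bn_stats)) {
    bns[[nm]]$running_mean <- ck$bn_stats[[nm]]$mean
    bns[[nm]]$running_var <- ck$bn_stats[[nm]]$var
  }
  list(net = net, extra = ck$extra)
}
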