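# FDPN: feature-pyramid connector routing multi-scale encoder features into
# the decoder. Classic FPN top-down pathway -- 1x1 lateral to a common
# width, 2x upsample-and-add, 3x3 smoothing -- with every convolution a
# DO-Conv, plus 1x1 projections that inject the fused maps additively into
# the decoder stages at strides 4 and 2. It compensates information dropped
# by the encoder's aggressive downsampling.

#' Assemble encoder taps into a feature pyramid
#'
#' @param taps list of exactly three feature maps in fine-to-coarse order
#'   (strides 2, 4, 8 relative to the network input); each level must be
#'   half the spatial size of the previous one. Values are passed through
#'   unchanged.
#' @return object of class `pyramid_bundle` with element `levels`.
#' @export
collect_pyramid <- function(taps) {
  if (!is.list(taps) || length(taps) != 3L)
    stop("collect_pyramid: expected exactly 3 encoder taps, got ",
         if (is.list(taps)) length(taps) else class(taps)[1])
  dims <- lapply(taps, function(t) dim(ag_value(t)))
  for (k in 2:3) {
    if (dims[[k]][1] * 2L != dims[[k - 1]][1] ||
        dims[[k]][2] * 2L != dims[[k - 1]][2])
      stop("collect_pyramid: level ", k, " (", dims[[k]][1], "x",
           dims[[k]][2], ") is not half the size of level ", k - 1,
           " (", dims[[k - 1]][1], "x", dims[[k - 1]][2], ")")
  }
  structure(list(levels = taps), class = "pyramid_bundle")
}

#' FDPN connector module
#'
#' @param stage_widths channel widths of the three encoder taps,
#'   fine-to-coarse (default `c(16, 64, 128)`).
#' @param fpn_channels common width of the fused pyramid (default 64).
#' @param upsample_mode `"nearest"` (default) or `"bilinear"` top-down
#'   upsampling.
#' @param decoder_widths channel widths of the decoder stages receiving
#'   injections at strides 4 and 2 (default `c(64, 16)`).
#' @param smooth_levels which pyramid levels get a smoothing layer and a
#'   fused output (default all three; the network passes `1:2` since only
#'   the stride-2 and stride-4 maps are injected into its decoder).
#' @return a module with lateral, smoothing and injection layers.
#' @export
fdpn_module <- function(stage_widths = c(16L, 64L, 128L), fpn_channels = 64L,
                        upsample_mode = c("nearest", "bilinear"),
                        decoder_widths = c(64L, 16L), smooth_levels = 1:3) {
  upsample_mode <- match.arg(upsample_mode)
  stopifnot(fpn_channels >= 1, length(stage_widths) == 3)
  m <- new_module("fdpn")
  m$fpn_channels <- as.integer(fpn_channels)
  m$upsample_mode <- upsample_mode
  m$smooth_levels <- as.integer(smooth_levels)
  for (k in 1:3) {
    m$submodules[[paste0("lateral", k)]] <-
      do_conv(stage_widths[k], fpn_channels, 1L)
    if (k %in% m$smooth_levels)
      m$submodules[[paste0("smooth", k)]] <-
        do_conv(fpn_channels, fpn_channels, 3L, pad = c(1L, 1L))
  }
  m$submodules$inject4 <- layer_conv2d(1L, 1L, fpn_channels, decoder_widths[1])
  m$submodules$inject2 <- layer_conv2d(1L, 1L, fpn_channels, decoder_widths[2])
  m
}

fdpn_upsample2 <- function(m, x) {
  if (m$upsample_mode == "nearest") return(ag_upsample_nearest2(x))
  d <- dim(ag_value(x))
  ag_upsample_bilinear(x, 2L * d[1], 2L * d[2])
}

#' Top-down fusion of a feature pyramid
#'
#' Each level passes its 1x1 DO-Conv lateral; starting from the coarsest,
#' the running top-down map is 2x upsampled and added to the next lateral;
#' each summed map passes a 3x3 DO-Conv smoother. Every fused map keeps the
#' spatial size of its lateral input.
#'
#' @param bundle a [collect_pyramid()] result (a plain list of <= 3 levels
#'   in fine-to-coarse order is also accepted for degenerate configs).
#' @param m an [fdpn_module()].
#' @param training forward in training mode (affects nothing here but kept
#'   for interface symmetry).
#' @return list of fused maps, fine-to-coarse, each with `fpn_channels`
#'   channels.
#' @export
fuse_topdown <- function(bundle, m, training = FALSE) {
  levels <- if (inherits(bundle, "pyramid_bundle")) bundle$levels else bundle
  L <- length(levels)
  stopifnot(L >= 1, L <= 3)
  lat <- vector("list", L)
  for (k in seq_len(L))
    lat[[k]] <- m$submodules[[paste0("lateral", k)]]$forward(as_node(levels[[k]]), training)
  p <- vector("list", L)
  p[[L]] <- lat[[L]]
  if (L > 1) for (k in (L - 1):1)
    p[[k]] <- ag_add(lat[[k]], fdpn_upsample2(m, p[[k + 1]]))
  ks <- intersect(seq_len(L), m$smooth_levels)
  fused <- lapply(ks, function(k)
    m$submodules[[paste0("smooth", k)]]$forward(p[[k]], training))
  names(fused) <- paste0("stride", 2L^ks)
  fused
}

#' Inject a fused pyramid map into a decoder state
#'
#' Adds a 1x1 projection of the fused map (to the decoder's channel width)
#' onto the decoder state: an additive skip connection.
#'
#' @param m an [fdpn_module()].
#' @param fused fused map at the decoder state's stride.
#' @param decoder_state decoder feature map to augment.
#' @param stride 4 or 2, selecting the projection layer.
#' @return augmented decoder state (same shape as `decoder_state`).
#' @export
inject_into_decoder <- function(m, fused, decoder_state, stride) {
  df <- dim(ag_value(fused)); dd <- dim(ag_value(decoder_state))
  if (df[1] != dd[1] || df[2] != dd[2])
    stop("inject_into_decoder: fused map is ", df[1], "x", df[2],
         " but decoder state is ", dd[1], "x", dd[2])
  proj <- switch(as.character(stride),
                 "4" = m$submodules$inject4,
                 "2" = m$submodules$inject2,
                 stop("inject_into_decoder: stride must be 4 or 2"))
  ag_add(as_node(decoder_state), proj$forward(as_node(fused)))
}
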