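# Shared fixtures: tiny random feature maps and a small scene set, built
# fresh per run under fixed seeds.

rand_map <- function(H, W, C, N = 1L, seed = NULL, sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(H * W * C * N, sd = sd), dim = c(H, W, C, N))
}

tiny_scenes <- function(n = 3, size = 16L, seed = 11L) {
  render_scenes(n, scene_spec(size = c(size, size), n_seedlings = 1L,
                              n_weeds = 1L, seedling_radius_range = c(3, 5),
                              seed = seed))
}

# independent numeric gradient (central differences)
num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ag <- asNamespace("epanet")
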