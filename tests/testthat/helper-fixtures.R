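# Shared fixtures: tiny configurations, zeroed layer parameters, and
# naive metric oracles used for dual-route checks.

# A minimal 5-level template (32 x 32 inputs are divisible by 2^5)
tiny_config <- function(...) {
  networkConfig(encoder_filters = c(2L, 3L, 4L, 5L, 6L),
                decoder_filters = c(5L, 4L, 3L, 2L), ...)
}

# The desk-scale reduced-width template
reduced_config <- function() {
  networkConfig(encoder_filters = c(4L, 8L, 16L, 32L, 64L),
                decoder_filters = c(32L, 16L, 8L, 4L))
}

zero_encoder_params <- function(cin, f, k = 5L) {
  list(W = array(0, c(k, k, cin, f)), b = numeric(f),
       gamma = rep(1, f), beta = numeric(f))
}

zero_residual_params <- function(f, k = 5L) {
  list(W1 = array(0, c(k, k, f, f)), b1 = numeric(f),
       gamma1 = rep(1, f), beta1 = numeric(f),
       W2 = array(0, c(k, k, f, f)), b2 = numeric(f),
       gamma2 = rep(1, f), beta2 = numeric(f))
}

random_mask <- function(h, w, p = 0.3) {
  matrix(stats::rbinom(h * w, 1, p), h, w)
}

# Naive set-arithmetic oracles (independent of the implementation path)
oracle_dsc <- function(a, b) {
  A <- which(a == 1); B <- which(b == 1)
  if (length(A) + length(B) == 0) return(1)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

oracle_jsc <- function(a, b) {
  A <- which(a == 1); B <- which(b == 1)
  if (length(union(A, B)) == 0) return(1)
  length(intersect(A, B)) / length(union(A, B))
}

# O(n^2) all-pairs directed-max-min Hausdorff oracle, explicit loops
oracle_hausdorff <- function(pa, pb) {
  directed <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        d <- sqrt((p[i, 1] - q[j, 1])^2 + (p[i, 2] - q[j, 2])^2)
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(pa, pb), directed(pb, pa))
}

# Closed-form trainable-parameter count walked layer by layer from the
# configuration (independent of the model's own bookkeeping)
layer_walk_count <- function(cfg, in_channels = 1L, dual_skips = FALSE) {
  k <- prod(cfg@hyper@kernel_size)
  ef <- cfg@encoder_filters; df <- cfg@decoder_filters
  ne <- length(ef)
  total <- 0
  cin <- in_channels
  for (i in seq_len(ne)) {
    total <- total + k * cin * ef[i] + ef[i] + 2 * ef[i]   # conv + bn
    cin <- ef[i]
  }
  rf <- cfg@residual_filters
  total <- total + cfg@n_residual_blocks * 2 * (k * rf * rf + rf + 2 * rf)
  cin <- rf
  for (j in seq_along(df)) {
    fl <- ef[ne - j]; fint <- cfg@attention_int[j]
    total <- total + fl * fint +                 # Wx (1x1, no bias)
      cin * fint + fint +                        # Wg + b_g
      fint + 1                                   # psi + b_psi
    total <- total + k * df[j] * cin + df[j] + 2 * df[j]   # deconv + bn
    cin <- df[j] + fl * (if (dual_skips) 2L else 1L)
  }
  total + k * cfg@output_channels * cin + cfg@output_channels   # head
}

# Make a tiny on-disk dataset and return its loaded samples
make_synth_samples <- function(n, seed, height = 32L, width = 32L) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  generateDataset(synthConfig(height = height, width = width,
                              n_samples = n, seed = seed), d)
  readManifest(file.path(d, "manifest.tsv"))
}
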