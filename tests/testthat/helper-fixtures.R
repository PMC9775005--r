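# Shared fixtures and independent oracles, all built in code at test time.

# Naive O(n^2) double-sum estimator of the squared MK-MMD; the independent
# oracle for the vectorized production estimator.
naive_mk_mmd2 <- function(S, T_, family, estimator = "biased") {
  kfun <- function(x, y) {
    s <- 0
    for (u in seq_along(family$bandwidths)) {
      s <- s + family$beta[u] *
        exp(-sum((x - y)^2) / (2 * family$bandwidths[u]^2))
    }
    s
  }
  n <- nrow(S); np <- nrow(T_)
  ss <- 0; tt <- 0; st <- 0; ss_off <- 0; tt_off <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- kfun(S[i, ], S[j, ])
    ss <- ss + v
    if (i != j) ss_off <- ss_off + v
  }
  for (i in seq_len(np)) for (j in seq_len(np)) {
    v <- kfun(T_[i, ], T_[j, ])
    tt <- tt + v
    if (i != j) tt_off <- tt_off + v
  }
  for (i in seq_len(n)) for (j in seq_len(np)) st <- st + kfun(S[i, ], T_[j, ])
  if (estimator == "biased") {
    ss / n^2 + tt / np^2 - 2 * st / (n * np)
  } else {
    ss_off / (n * (n - 1)) + tt_off / (np * (np - 1)) - 2 * st / (n * np)
  }
}

# A single unit-bandwidth Gaussian kernel family for closed-form checks.
unit_gaussian_family <- function() {
  structure(list(bandwidths = 1, beta = 1, kernel = "gaussian"),
            class = "kernel_family")
}

# Small labelled image set with an easy, linearly separable class structure
# (slow low trace vs fast high trace), for overfit sanity checks.
toy_images <- function(n_per_class = 6, seed = 3, size = 64) {
  set.seed(seed)
  sp <- raster_spec(size, size)
  mk <- function(label, k) {
    tr <- if (label == "healthy") {
      0.3 + 0.2 * sin(seq(0, 6 * pi, length.out = 250))
    } else {
      0.7 + 0.2 * sin(seq(0, 20 * pi, length.out = 250))
    }
    w <- rbind(tr, tr, tr) + matrix(stats::rnorm(750, sd = 0.02), 3)
    w <- pmin(pmax(w, 0), 1)
    encode_merged_chart(w, sp, sprintf("s%02d", k), label, k)
  }
  c(lapply(seq_len(n_per_class), function(k) mk("healthy", k)),
    lapply(n_per_class + seq_len(n_per_class), function(k) mk("depressed", k)))
}

# Random normalized 3 x L window.
random_window <- function(L = 250) {
  matrix(stats::runif(3 * L), nrow = 3)
}

# Flatten every numeric parameter of the layers at the given stage into one
# vector, for bit-identity comparisons.
stage_param_vector <- function(model, stage) {
  unlist(lapply(model$layers, function(l) {
    if (l$stage == stage) unlist(l$params) else NULL
  }))
}

rms <- function(x) sqrt(mean(x^2))
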