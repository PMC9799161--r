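# Independent oracles and shared fixtures for the suite.

# Brute-force O(N^2) spatial-domain convolution with explicit padding:
# the reference the FFT path is checked against.
brute_convolve <- function(x, w, mode = c("replicate", "constant"),
                           value = 0) {
  mode <- match.arg(mode)
  R <- (nrow(w) - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  if (mode == "constant") {
    xp <- matrix(value, n + 2L * R, m + 2L * R)
    xp[(R + 1L):(R + n), (R + 1L):(R + m)] <- x
  } else {
    ri <- c(rep(1L, R), seq_len(n), rep(n, R))
    ci <- c(rep(1L, R), seq_len(m), rep(m, R))
    xp <- x[ri, ci]
  }
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    out[i, j] <- sum(w * xp[i:(i + 2L * R), j:(j + 2L * R)])
  out
}

# Term-by-term transcription of the disability-glare equation, evaluated as
# three separately computed bracketed components; independent of gsf_value().
gsf_terms_oracle <- function(theta, age = 25, p = 0.5) {
  a4 <- (age / 70)^4
  term1 <- (1 - 0.08 * a4) *
    (9.2e6 / (1 + (theta / 0.0046)^2)^1.5 +
       1.5e5 / (1 + (theta / 0.045)^2)^1.5)
  term2 <- (1 + 1.6 * a4) *
    (400 / (1 + (theta / 0.1)^2) +
       p * (1300 / (1 + (theta / 0.1)^2)^1.5 +
              0.8 / (1 + (theta / 0.1)^2)^0.5))
  term3 <- 2.5e-3 * p
  term1 + term2 + term3
}

# a small radial unit-sum toy kernel (33 x 33) for convolution tests
toy_kernel <- function(side = 33L) {
  r <- (side - 1L) %/% 2L
  d <- sqrt(outer((-r:r)^2, (-r:r)^2, "+"))
  w <- 1 / (1 + d)^2.5
  w / sum(w)
}

# ---- shared heavy fixtures (computed once per test run) -------------------
.acc <- new.env(parent = emptyenv())

acc_kernel_full <- function() {
  if (is.null(.acc$kernel))
    .acc$kernel <- build_kernel(angular_geometry(c(2048L, 2048L),
                                                 field_of_view_deg = 10))
  .acc$kernel
}

acc_target_run <- function(variant) {
  key <- paste0("ca_", variant)
  if (is.null(.acc[[key]])) {
    b <- make_contrast_assimilation(variant, 2048L)
    r <- convolve_glare(bundle_scene(b), acc_kernel_full())
    .acc[[key]] <- list(bundle = b, retina = r)
  }
  .acc[[key]]
}

acc_mondrian_run <- function(negative = FALSE) {
  key <- if (negative) "mond_neg" else "mond"
  if (is.null(.acc[[key]])) {
    b <- make_mondrian(seed = 1L, size = 2048L)
    if (negative)
      b <- invert_target(b, data.frame(darker = "circle_top",
                                       lighter = "circle_bottom",
                                       illusion = "contrast",
                                       stringsAsFactors = FALSE))
    r <- convolve_glare(bundle_scene(b), acc_kernel_full())
    .acc[[key]] <- list(bundle = b, retina = r)
  }
  .acc[[key]]
}

acc_todorovic_run <- function() {
  if (is.null(.acc$todo)) {
    b <- make_todorovic()
    k <- build_kernel(b$geometry, cache = FALSE)
    r <- convolve_glare(bundle_scene(b), k)
    rm(k)
    gc(verbose = FALSE)
    .acc$todo <- list(bundle = b, retina = r)
  }
  .acc$todo
}

# small-scale shared kernel for fast module tests (512 px, 10 deg field)
small_kernel <- function() {
  if (is.null(.acc$k512))
    .acc$k512 <- build_kernel(angular_geometry(c(512L, 512L),
                                               field_of_view_deg = 10))
  .acc$k512
}
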