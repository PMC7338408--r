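# Shared fixture builders; everything is generated in code at test time.

# Straight horizontal vessel band mask of a given width (px) in an image.
band_mask <- function(nrow = 120, ncol = 200, width_px = 80) {
  m <- matrix(FALSE, nrow, ncol)
  mid <- nrow / 2
  m[abs(seq_len(nrow) - mid) <= width_px / 2 - 0.5, ] <- TRUE
  m
}

# Horizontal-axis geometry for a band mask.
band_axis <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  list(center = c(mean(idx[, 2] - 1), mean(idx[, 1] - 1)),
       direction = c(1, 0))
}

# Analytic cortical-actin short-axis profile with edge fraction f, sampled
# densely on [0, 1]: uniform (1 - f) plus a 5*f edge band in the outer 10%.
cortical_profile <- function(f, n = 8001) {
  x <- seq(0, 1, length.out = n)
  y <- (1 - f) + 5 * f * (x <= 0.10 | x >= 0.90)
  line_profile(x, y)
}

# Hand-built cytokine_array object (bypasses rendering) for arithmetic
# oracles.
manual_array <- function(means, background, reference) {
  structure(list(densities = as.list(means), means = means,
                 background = background, reference = reference,
                 shift = c(0, 0), layout_spots = length(means) + 4L),
            class = "cytokine_array")
}

# Random strictly-increasing line profile for property sweeps.
random_profile <- function(n = 25) {
  x <- sort(runif(n)); x <- (x - min(x)) / (max(x) - min(x))
  while (any(diff(x) <= 0)) { x <- sort(runif(n)); x <- (x - min(x)) / (max(x) - min(x)) }
  y <- runif(n, 0.05, 1)
  list(position = x, intensity = y)
}

erfc_ <- function(z) 2 * stats::pnorm(z * sqrt(2), lower.tail = FALSE)
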