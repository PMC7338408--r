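# Internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Trapezoidal integral of y over x.
trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

# Add interpolated sample points at `breaks` to a (x, y) profile so that
# sub-interval integrals are exact for piecewise-linear data.
insert_breaks <- function(x, y, breaks) {
  add <- setdiff(breaks, x)
  add <- add[add > min(x) & add < max(x)]
  if (length(add)) {
    yi <- stats::approx(x, y, xout = add)$y
    o <- order(c(x, add))
    x <- c(x, add)[o]; y <- c(y, yi)[o]
  }
  list(x = x, y = y)
}

# Paint a filled disk of `value` onto matrix `img` (row, col center, radius
# in px); returns the modified matrix. Additive.
paint_disk <- function(img, row, col, radius, value) {
  r0 <- max(1L, floor(row - radius)); r1 <- min(nrow(img), ceiling(row + radius))
  c0 <- max(1L, floor(col - radius)); c1 <- min(ncol(img), ceiling(col + radius))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  img[rr, cc] <- img[rr, cc] + value * (d2 <= radius^2)
  img
}

fail_field <- function(cond, field, msg) {
  if (cond) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
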