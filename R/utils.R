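# Small internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rowNorms <- function(a) sqrt(rowSums(a * a))

normalizeRows <- function(a) {
  n <- rowNorms(a)
  n[n < 1e-300] <- 1
  a / n
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-300) stop("cannot normalize a zero vector")
  v / n
}

# Any unit vector orthogonal to v.
orthoVector <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(pracma_cross(v, a))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Cumulative arclength of a polyline (n x 3).
arclength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(rowNorms(diff(pts)))
}

cumArclength <- function(pts) {
  c(0, cumsum(rowNorms(diff(pts))))
}

# Linear interpolation of a polyline at arclength positions s (vectorized).
polylineAt <- function(pts, s) {
  cs <- cumArclength(pts)
  s <- pmin(pmax(s, 0), cs[length(cs)])
  out <- matrix(0, length(s), 3)
  for (k in seq_along(s)) {
    i <- max(which(cs <= s[k] + 1e-15))
    if (i >= nrow(pts)) { out[k, ] <- pts[nrow(pts), ]; next }
    f <- (s[k] - cs[i]) / max(cs[i + 1] - cs[i], 1e-300)
    out[k, ] <- (1 - f) * pts[i, ] + f * pts[i + 1, ]
  }
  out
}

# The statistical mode of an integer vector (smallest wins ties).
modeInt <- function(x) {
  tb <- table(x)
  as.integer(names(tb)[which.max(tb)])
}
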