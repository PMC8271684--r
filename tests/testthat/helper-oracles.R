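## Shared fixtures and independent oracles used across test files.

# a clean phantom spec: fixed geometry, no occluders/glints/degradations
cleanPhantomSpec <- function(irisR = 100, pupilFrac = 0.4, jitter = 0,
                             H = 512L, W = 640L) {
  PhantomSpec(imageHeight = H, imageWidth = W,
              irisRadiusRange = c(irisR, irisR),
              pupilFractionRange = c(pupilFrac, pupilFrac),
              centerJitter = jitter,
              blurSigmaRange = c(0, 0), noiseSigmaRange = c(0, 0),
              illuminationRange = c(0, 0),
              occluderParams = list(upper_prob = 0, lower_prob = 0,
                                    margin_range = c(1, 1),
                                    curvature_range = c(2, 2),
                                    lid_intensity = c(150, 150),
                                    retractor_prob = 0,
                                    retractor_width = c(6, 6),
                                    retractor_intensity = 235),
              glintParams = list(max_count = 0L, radius = c(2, 2),
                                 intensity = 250))
}

# brute-force disk pixel count: loop over the integer lattice
bruteDiskCount <- function(H, W, cr, cc, r) {
  n <- 0L
  for (i in 0:(H - 1)) for (j in 0:(W - 1))
    if ((i - cr)^2 + (j - cc)^2 <= r^2) n <- n + 1L
  n
}

# independent closed-form parameter summation for the U-Net family
oracleParamCount <- function(base, depth, inch = 1L, bn = TRUE,
                             decoder = "upconv_concat") {
  f <- base * 2^(0:(depth - 1))
  conv <- function(cin, cout, k) cin * cout * k^2 + cout +
    if (bn) 2 * cout else 0
  p <- 0; prev <- inch
  for (l in seq_len(depth - 1)) {
    p <- p + conv(prev, f[l], 3) + conv(f[l], f[l], 3)
    prev <- f[l]
  }
  p <- p + conv(prev, f[depth], 3) + conv(f[depth], f[depth], 3)
  prev <- f[depth]
  for (l in rev(seq_len(depth - 1))) {
    if (decoder == "upconv_concat") {
      p <- p + conv(prev, f[l], 2)
      cat_ch <- 2 * f[l]
    } else {
      cat_ch <- prev + f[l]
    }
    p <- p + conv(cat_ch, f[l], 3) + conv(f[l], f[l], 3)
    prev <- f[l]
  }
  p + prev + 1          # 1x1 head with bias
}

# moving-statistics count: two scalars per batch-normalised channel
oracleStatCount <- function(base, depth, bn = TRUE,
                            decoder = "upconv_concat") {
  if (!bn) return(0L)
  f <- base * 2^(0:(depth - 1))
  ch <- 0
  for (l in seq_len(depth - 1)) ch <- ch + 2 * f[l]     # encoder blocks
  ch <- ch + 2 * f[depth]                               # bottleneck
  for (l in rev(seq_len(depth - 1))) {
    if (decoder == "upconv_concat") ch <- ch + f[l]     # up-conv BN
    ch <- ch + 2 * f[l]
  }
  2L * ch
}

# contour of a mask under the 4-neighbour boundary definition (R oracle)
contourPoints <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pts <- which(m, arr.ind = TRUE)
  if (!nrow(pts)) return(pts)
  keep <- vapply(seq_len(nrow(pts)), function(k) {
    i <- pts[k, 1]; j <- pts[k, 2]
    i == 1 || !m[i - 1, j] || i == H || !m[i + 1, j] ||
      j == 1 || !m[i, j - 1] || j == W || !m[i, j + 1]
  }, logical(1))
  pts[keep, , drop = FALSE]
}

# brute-force symmetric Hausdorff distance over all contour pairs
bruteHausdorff <- function(A, B) {
  a <- contourPoints(A); b <- contourPoints(B)
  if (!nrow(a) || !nrow(b)) return(NA_real_)
  D <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}

# naive pixel-counting overlap statistics (loop-based, no vectorised sets)
bruteOverlap <- function(A, B) {
  a <- 0L; g <- 0L; i <- 0L
  for (k in seq_along(A)) {
    if (A[k]) a <- a + 1L
    if (B[k]) g <- g + 1L
    if (A[k] && B[k]) i <- i + 1L
  }
  list(dice = if (a + g > 0) 2 * i / (a + g) else NA_real_,
       simpson = if (a > 0 && g > 0) i / min(a, g) else NA_real_,
       iou = if (a + g - i > 0) i / (a + g - i) else NA_real_)
}

randomMask <- function(H = 10L, W = 10L, p = 0.35) {
  matrix(runif(H * W) < p, H, W)
}

# memoised scaled-down experiment shared by the acceptance blocks
acceptanceExperiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- runScaledExperiment(seed = 1L)
    cache
  }
})
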