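# Shared fixtures, all generated in code.

# A small panel with the full 40 x 30 cm physical extent (128 x 96 pixels,
# 3.125 mm pitch): same geometry, far fewer pixels, for fast chain tests.
smallPanelConfig <- function(...) {
  simConfig(nX = 128L, nY = 96L, pitchMm = 3.125, ...)
}

# Bilinear upsample of a 2x2 corner grid to n x n: the gentlest possible
# smooth random field (a bilinear saddle).
upsample2x2 <- function(z, n = 16L) {
  idx <- seq(0, 1, length.out = n)
  outer(1 - idx, 1 - idx) * z[1, 1] + outer(1 - idx, idx) * z[1, 2] +
    outer(idx, 1 - idx) * z[2, 1] + outer(idx, idx) * z[2, 2]
}

# Random reference/evaluated 16x16 pairs for gamma verification. Gradients
# are kept gentle (fractions of a percent of the normalization per mm), the
# regime where portal images live in-field and where a subsampled search and
# the fine-grid oracle measure the same minimum; dose offsets and sub-pixel
# shifts spread gamma over [0, ~1.7], both sides of the pass boundary.
randomGammaPair <- function(seed) {
  set.seed(seed)
  fam <- seed %% 3L
  ref <- 1 + 0.01 * upsample2x2(matrix(rnorm(4), 2, 2))
  if (fam == 0L) {
    ev <- ref * (1 + 0.02 * upsample2x2(matrix(rnorm(4), 2, 2)))
  } else if (fam == 1L) {
    tilt <- 0.0025 * upsample2x2(matrix(rnorm(4), 2, 2))
    ev <- ref * (1 + runif(1, -0.05, 0.05) + tilt)
  } else {
    sh <- runif(2, -0.4, 0.4)
    idx <- seq_len(16)
    jj <- pmin(pmax(idx + sh[1], 1), 16)
    ii <- pmin(pmax(idx + sh[2], 1), 16)
    j0 <- pmin(floor(jj), 15)
    i0 <- pmin(floor(ii), 15)
    fy <- jj - j0; fx <- ii - i0
    ev <- ref[j0, ] * (1 - fy) + ref[pmin(j0 + 1, 16), ] * fy
    ev <- t(t(ev[, i0]) * (1 - fx)) + t(t(ev[, pmin(i0 + 1, 16)]) * fx)
    ev <- ev * (1 + runif(1, -0.02, 0.02))
  }
  list(ref = ImageGrid(ref, 1), ev = ImageGrid(ev, 1))
}

rot180 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
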