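test_that("ROI selection is seeded, in-bounds, and respects margins", {
  img <- bmode_image(matrix(0L, 512L, 128L))
  r1 <- select_rois(img, 5L, seed = 99L)
  r2 <- select_rois(img, 5L, seed = 99L)
  expect_identical(lapply(r1, `[[`, "origin"), lapply(r2, `[[`, "origin"))
  for (p in r1) {
    expect_equal(dim(p$pixels), c(16L, 16L))
    expect_gte(p$origin[1], 32L)                    # top margin
    expect_gte(p$origin[2], 8L)
    expect_lte(p$origin[1] + 16L, 512L)
    expect_lte(p$origin[2] + 16L, 128L - 8L)
  }
  expect_length(select_rois(img, 0L, seed = 1L), 0L)

  tiny <- bmode_image(matrix(7L, 16L, 16L))
  only <- select_rois(tiny, 3L, seed = 4L, margin = 0L)
  expect_true(all(vapply(only, function(p) all(p$origin == c(0L, 0L)), TRUE)))
  expect_error(select_rois(tiny, 1L, seed = 1L), "too small")
  expect_error(extract_roi(img, 500L, 0L), "outside")
})

test_that("first-order histogram features on closed-form patches", {
  const <- matrix(7L, 16L, 16L)
  f <- glh_features(const)
  expect_equal(f$mean_gray_scale, 7)
  expect_equal(f$variance, 0)
  expect_equal(f$entropy, 0)

  half <- matrix(c(0L, 255L), 16L, 16L)
  f2 <- glh_features(half)
  expect_equal(f2$mean_gray_scale, 127.5)
  expect_equal(f2$entropy, 1)
  expect_equal(f2$std, 127.5)

  quarters <- matrix(rep(c(0L, 10L, 20L, 30L), each = 64L), 16L, 16L)
  expect_equal(glh_features(quarters)$entropy, 2)

  # entropy bounded by log2 of distinct levels present, and by 8 bits
  set.seed(2)
  px <- matrix(sample(0:255, 256, TRUE), 16L, 16L)
  ent <- glh_features(px)$entropy
  expect_lte(ent, log2(length(unique(as.vector(px)))))
  expect_lte(ent, 8)
  expect_gte(ent, 0)
})

test_that("gray-level quantization bins uniformly", {
  expect_equal(quantize_levels(matrix(0L), 16L)[1, 1], 0L)
  expect_equal(quantize_levels(matrix(255L), 16L)[1, 1], 15L)
  expect_equal(quantize_levels(matrix(16L), 16L)[1, 1], 1L)
  expect_equal(quantize_levels(matrix(15L), 16L)[1, 1], 0L)
  px <- matrix(sample(0:255, 64, TRUE), 8L)
  expect_identical(quantize_levels(px, 256L), px)
})

test_that("co-occurrence matrix on a hand-enumerable patch", {
  patch <- matrix(c(0L, 0L, 1L, 1L), 2L, 2L)   # [[0,1],[0,1]] by rows
  cfg <- glcm_config(levels = 2L)
  m <- glcm_matrix(patch, 0, cfg)
  expect_equal(m$probabilities[1, 2], 0.5)
  expect_equal(m$probabilities[2, 1], 0.5)
  expect_equal(sum(m$probabilities), 1)
  expect_equal(m$pair_count, 4L)               # 2 pairs counted both ways

  const <- matrix(3L, 4L, 4L)
  mc <- glcm_matrix(const, 90, glcm_config())
  expect_equal(mc$probabilities[4, 4], 1)

  f <- glcm_features(m)
  expect_equal(f$contrast, 1)
  expect_equal(f$energy, 0.5)
  expect_equal(f$homogeneity, 0.5)
  expect_equal(f$correlation, -1)

  fc <- glcm_features(mc)
  expect_equal(fc$contrast, 0)
  expect_equal(fc$energy, 1)
  expect_equal(fc$homogeneity, 1)
  expect_equal(fc$correlation, 0)             # degenerate marginals

  L <- 16L
  unif <- structure(list(probabilities = matrix(1 / L^2, L, L)),
                    class = "glcm_matrix")
  expect_equal(glcm_features(unif)$energy, 1 / L^2)
})

test_that("GLCM matrices and features match the brute-force oracle", {
  cfg <- glcm_config()
  for (seed in 1:20) {
    q <- quantize_levels(random_patch(seed), cfg$levels)
    for (ang in c(0, 45, 90, 135)) {
      m <- glcm_matrix(q, ang, cfg)
      expect_equal(m$probabilities, oracle_glcm(q, ang, cfg$levels),
                   tolerance = 1e-12)
      expect_equal(glcm_features(m),
                   oracle_glcm_features(m$probabilities), tolerance = 1e-12)
    }
  }
})

test_that("rotating a patch by 90 degrees swaps the direction pairs", {
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  cfg <- glcm_config()
  q <- quantize_levels(random_patch(77), cfg$levels)
  qr <- rot90(q)
  for (pair in list(c(0, 90), c(45, 135), c(90, 0), c(135, 45))) {
    expect_equal(glcm_features(glcm_matrix(q, pair[1], cfg)),
                 glcm_features(glcm_matrix(qr, pair[2], cfg)))
  }
})

test_that("bin-width gray shifts leave GLCM features invariant", {
  cfg <- glcm_config()
  px <- random_patch(5, levels = 200L)         # headroom for the shift
  q1 <- quantize_levels(px, cfg$levels)
  q2 <- quantize_levels(px + 32L, cfg$levels)  # shift by 2 full bins
  for (ang in cfg$angles) {
    f1 <- glcm_features(glcm_matrix(q1, ang, cfg))
    f2 <- glcm_features(glcm_matrix(q2, ang, cfg))
    expect_equal(f1[c("contrast", "energy", "homogeneity")],
                 f2[c("contrast", "energy", "homogeneity")])
  }
})

test_that("gradient magnitude behaves like a Sobel operator", {
  expect_true(all(gradient_image(matrix(50L, 8L, 8L)) == 0))

  step <- matrix(0L, 8L, 8L); step[, 5:8] <- 255L
  g <- gradient_image(step)
  expect_true(all(g[, c(4, 5)] > 0))
  expect_true(all(g[, c(1, 2, 7, 8)] == 0))
  expect_equal(max(g), 4 * 255)                 # full Sobel response

  px <- random_patch(9)
  expect_equal(gradient_image(t(px)), t(gradient_image(px)))
  expect_equal(gradient_image(px), oracle_sobel(px))

  cd <- gradient_image(step, ggcm_config(gradient_operator = "central-difference"))
  expect_true(all(cd[, c(4, 5)] > 0) && all(cd[, 1:3] == 0))
})

test_that("gray-gradient matrix tallies every pixel once", {
  cfg <- ggcm_config()
  const <- matrix(100L, 16L, 16L)
  g <- ggcm_matrix(const, cfg)
  expect_equal(g$counts[quantize_levels(const, 16L)[1, 1] + 1L, 1L], 256L)
  expect_equal(sum(g$counts), 256L)
  expect_equal(sum(g$probabilities), 1)

  px <- random_patch(33)
  gg <- ggcm_matrix(px, cfg)
  expect_equal(sum(gg$counts), length(px))
  expect_equal(gg$counts, oracle_ggcm(px, 16L, 16L))
})

test_that("the twelve gray-gradient statistics on closed-form cases", {
  f <- ggcm_features(ggcm_matrix(matrix(100L, 16L, 16L)))
  expect_equal(f$small_gradient, 1)
  expect_equal(f$large_gradient, 0)
  expect_equal(f$energy, 1)
  expect_equal(f$hybrid_entropy, 0)
  expect_equal(f$gradient_entropy, 0)
  expect_equal(f$mean_gradient, 0)
  expect_equal(f$gradient_msd, 0)
  expect_equal(f$correlation, 0)

  Lg <- 16L; Ls <- 16L
  unif <- structure(list(counts = matrix(1L, Lg, Ls)), class = "ggcm_matrix")
  expect_equal(ggcm_features(unif)$hybrid_entropy, 8)

  px <- random_patch(55)
  got <- ggcm_features(ggcm_matrix(px))
  want <- oracle_ggcm_features(oracle_ggcm(px, 16L, 16L))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the assembled feature vector has 31 finite stable-named entries", {
  fv <- extract_features(random_patch(101))
  expect_length(fv, 31L)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_features(random_patch(101)))

  const <- extract_features(matrix(42L, 16L, 16L))
  expect_equal(unname(const["glh.entropy"]), 0)
  expect_equal(unname(const["glcm.contrast.0"]), 0)
  expect_equal(unname(const["glcm.homogeneity.45"]), 1)
  expect_equal(unname(const["glcm.energy.90"]), 1)
  expect_equal(unname(const["ggcm.small_gradient"]), 1)
  expect_equal(unname(const["ggcm.hybrid_entropy"]), 0)
})

test_that("entropy and unit-interval bounds hold on random patches", {
  for (seed in 1:25) {
    fv <- extract_features(random_patch(seed + 500))
    expect_gte(fv[["glh.entropy"]], 0); expect_lte(fv[["glh.entropy"]], 8)
    expect_gte(fv[["ggcm.hybrid_entropy"]], 0)
    expect_lte(fv[["ggcm.hybrid_entropy"]], 8)
    for (a in c(0, 45, 90, 135)) {
      expect_gt(fv[[paste0("glcm.energy.", a)]], 0)
      expect_lte(fv[[paste0("glcm.energy.", a)]], 1)
      expect_gt(fv[[paste0("glcm.homogeneity.", a)]], 0)
      expect_lte(fv[[paste0("glcm.homogeneity.", a)]], 1)
    }
  }
})
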