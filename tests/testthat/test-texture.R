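test_that("GLCM pair counting matches hand enumeration on tiny images", {
  img <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)  # [[0,0],[1,1]]
  g <- compute_glcm(img, 1, 0, 2, symmetric = FALSE)
  expect_equal(g$P, matrix(c(0.5, 0, 0, 0.5), 2, 2))

  const <- matrix(3L, 4, 4)
  gc <- compute_glcm(const, 1, 0, 8)
  expect_equal(gc$P[4, 4], 1)
  expect_equal(sum(gc$P), 1)
})

test_that("GLCMs are normalized, non-negative and symmetric in symmetric mode", {
  set.seed(21)
  for (rep in 1:20) {
    img <- matrix(sample(0:7, 100, replace = TRUE), 10, 10)
    for (theta in c(0, pi / 4, pi / 2, 3 * pi / 4)) {
      g <- compute_glcm(img, 1, theta, 8, symmetric = TRUE)
      expect_true(all(g$P >= 0))
      expect_equal(sum(g$P), 1, tolerance = 1e-9)
      expect_equal(g$P, t(g$P))
    }
  }
})

test_that("GLCM equals the brute-force pair-count oracle", {
  set.seed(33)
  angles <- c(0, pi / 4, pi / 2, 3 * pi / 4)
  for (rep in 1:25) {
    img <- matrix(sample(0:7, 256, replace = TRUE), 16, 16)
    for (d in c(1L, 3L)) for (theta in angles) for (sym in c(TRUE, FALSE)) {
      off <- oracle_offset(d, theta)
      expect_equal(compute_glcm(img, d, theta, 8, symmetric = sym)$P,
                   brute_glcm(img, off[1], off[2], 8, symmetric = sym))
    }
  }
})

test_that("offsets that leave the image raise a degenerate-geometry error", {
  img <- matrix(sample(0:1, 9, replace = TRUE), 3, 3)
  expect_error(compute_glcm(img, 5, 0, 2), "no valid pixel pair")
})

test_that("Haralick features take their closed-form values", {
  U <- matrix(0.25, 2, 2)               # uniform 2x2 GLCM
  expect_equal(glcm_contrast(U), 0.5)
  expect_equal(glcm_energy(U), 0.25)
  expect_equal(glcm_correlation(U), 0)
  expect_equal(glcm_homogeneity(U), 0.75)
  expect_equal(glcm_entropy(U), 2, tolerance = 1e-9)
  expect_equal(glcm_dissimilarity(U), 0.5)

  S <- matrix(c(1, 0, 0, 0), 2, 2)      # single-cell GLCM
  expect_equal(glcm_contrast(S), 0)
  expect_equal(glcm_energy(S), 1)
  expect_equal(glcm_correlation(S), 0)  # degenerate marginals -> 0
  expect_equal(glcm_homogeneity(S), 1)
  expect_equal(glcm_entropy(S), 0, tolerance = 1e-9)
  expect_equal(glcm_dissimilarity(S), 0)

  D <- matrix(c(0.5, 0, 0, 0.5), 2, 2)  # diagonal pair
  expect_equal(glcm_energy(D), 0.5)
  expect_equal(glcm_correlation(D), 1)
  expect_equal(glcm_entropy(D), 1, tolerance = 1e-9)

  A <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)  # all mass at (0,1)
  expect_equal(glcm_homogeneity(A), 0.5)

  E <- matrix(0, 3, 3); E[1, 3] <- 1              # |i-j| = 2
  expect_equal(glcm_dissimilarity(E), 2)
})

test_that("checkerboard at d=1 yields contrast exactly 1", {
  img <- outer(1:8, 1:8, function(r, c) (r + c) %% 2L)
  g <- compute_glcm(img, 1, 0, 2, symmetric = TRUE)
  expect_equal(glcm_contrast(g), 1)
  expect_equal(glcm_dissimilarity(g), 1)
})

test_that("feature extraction covers the grid in a stable order", {
  cfg <- texture_config()
  expect_length(haralick_feature_names(cfg), 96)
  expect_equal(haralick_feature_names(cfg)[1:6],
               paste0("d1_a0_", c("contrast", "energy", "correlation",
                                  "homogeneity", "entropy", "dissimilarity")))

  set.seed(4)
  img <- matrix(sample(0:31, 32 * 32, replace = TRUE), 32, 32)
  f1 <- extract_features(img, cfg)
  f2 <- extract_features(img, cfg)
  expect_identical(f1, f2)
  expect_length(f1, 96)
})

test_that("constant images pin every feature to its extreme", {
  img <- matrix(5L, 16, 16)
  f <- extract_features(img, texture_config(levels = 32))
  expect_true(all(f[grep("contrast|dissimilarity", names(f))] == 0))
  expect_true(all(f[grep("energy|homogeneity", names(f))] == 1))
})

test_that("checkerboard whole-image features match the enumerated GLCM", {
  img <- outer(1:8, 1:8, function(r, c) (r + c) %% 2L)
  f <- extract_features(img, texture_config(distances = 1L, angles = 0,
                                            levels = 2L))
  P <- brute_glcm(img, 0L, 1L, 2L, symmetric = TRUE)
  expect_equal(unname(f["d1_a0_contrast"]), glcm_contrast(P))
  expect_equal(unname(f["d1_a0_energy"]), glcm_energy(P))
  expect_equal(unname(f["d1_a0_correlation"]), glcm_correlation(P))
  expect_equal(unname(f["d1_a0_homogeneity"]), glcm_homogeneity(P))
  expect_equal(unname(f["d1_a0_entropy"]), glcm_entropy(P))
  expect_equal(unname(f["d1_a0_dissimilarity"]), glcm_dissimilarity(P))
})

test_that("symmetric-GLCM invariances hold", {
  set.seed(55)
  img <- matrix(sample(0:7, 144, replace = TRUE), 12, 12)
  g <- compute_glcm(img, 1, 0, 8, symmetric = TRUE)
  expect_equal(glcm_correlation(g$P), glcm_correlation(t(g$P)))
  # intensity inversion preserves contrast and dissimilarity
  inv <- 7L - img
  gi <- compute_glcm(inv, 1, 0, 8, symmetric = TRUE)
  expect_equal(glcm_contrast(gi), glcm_contrast(g))
  expect_equal(glcm_dissimilarity(gi), glcm_dissimilarity(g))
})

test_that("window mode averages per-window features", {
  set.seed(6)
  img <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
  cfg <- texture_config(distances = 1L, angles = 0, levels = 4L,
                        window = 3L, stride = 1L)
  f <- extract_features(img, cfg)
  # oracle: average contrast over all 3x3 windows
  vals <- c()
  for (r in 1:4) for (cc in 1:4) {
    win <- img[r:(r + 2), cc:(cc + 2)]
    vals <- c(vals, glcm_contrast(brute_glcm(win, 0L, 1L, 4L)))
  }
  expect_equal(unname(f["d1_a0_contrast"]), mean(vals))
})

test_that("undersized images and bad angles are rejected", {
  img <- matrix(sample(0:1, 16, replace = TRUE), 4, 4)
  expect_error(extract_features(img, texture_config(distances = c(1L, 7L),
                                                    levels = 2L)),
               "smaller")
  expect_error(texture_config(angles = pi / 3), "unsupported angle")
})
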