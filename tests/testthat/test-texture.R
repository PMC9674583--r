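# GLCM texture: quantisation, co-occurrence, Haralick features, invariance

test_that("quantisation hits the range endpoints and constant blocks", {
  cfg <- glcm_config(levels = 64)
  b <- matrix(c(0, 255, 100, 30), 2, 2)
  q <- quantize_block(b, cfg)
  expect_equal(q[1, 1], 0L)
  expect_equal(q[2, 1], 63L)
  expect_true(all(quantize_block(matrix(9, 4, 4), cfg) == 0L))
})

test_that("quantisation matches the per-pixel binning formula", {
  set.seed(41)
  cfg <- glcm_config(levels = 16)
  b <- matrix(runif(100, 3, 250), 10, 10)
  q <- quantize_block(b, cfg)
  lo <- min(b); hi <- max(b)
  for (i in seq_along(b)) {
    want <- min(floor(16 * (b[i] - lo) / (hi - lo)), 15)
    expect_equal(as.integer(q[i]), as.integer(want))
  }
})

test_that("GLCM entries are a normalised, optionally symmetric distribution", {
  set.seed(42)
  q <- quantize_block(random_block(12, 12), glcm_config(levels = 8))
  for (k in 1:3) {
    g <- compute_glcm(q, dx = k, dy = sample(0:2, 1), levels = 8)
    expect_equal(sum(g), 1, tolerance = 1e-12)
    expect_true(all(g >= 0))
    expect_equal(g, t(g), ignore_attr = TRUE)    # symmetric by default
  }
})

test_that("constant block GLCM is a point mass with the closed-form features", {
  q <- matrix(0L, 10, 10)
  g <- compute_glcm(q, 1, 0, levels = 8)
  expect_equal(g[1, 1], 1)
  expect_equal(haralick_feature(g, "energy"), 1)
  expect_equal(haralick_feature(g, "contrast"), 0)
  expect_equal(haralick_feature(g, "homogeneity"), 1)
  tx <- block_texture(matrix(5, 10, 10))
  expect_equal(tx$energy, 1)
  expect_equal(tx$contrast, 0)
  expect_equal(tx$homogeneity, 1)
  expect_equal(tx$heterogeneity, 0)
})

test_that("vertical stripes give different counts at horizontal vs vertical offsets", {
  # columns alternate 0,1,0,1: horizontal neighbours always differ,
  # vertical neighbours never do (hand-enumerated)
  q <- outer(rep(1, 4), c(0L, 1L, 0L, 1L))
  storage.mode(q) <- "integer"
  gh <- compute_glcm(q, dx = 1, dy = 0, levels = 2, symmetric = FALSE)
  gv <- compute_glcm(q, dx = 0, dy = 1, levels = 2, symmetric = FALSE)
  # 12 horizontal pairs, row pattern 0,1,0,1: (0->1) twice and (1->0) once per
  # row, so counts 8 and 4; 12 vertical pairs: (0,0) x6, (1,1) x6
  expect_equal(gh, matrix(c(0, 1 / 3, 2 / 3, 0), 2, 2), ignore_attr = TRUE)
  expect_equal(gv, matrix(c(.5, 0, 0, .5), 2, 2), ignore_attr = TRUE)
})

test_that("uniform and two-entry GLCMs give the closed-form feature values", {
  L <- 8
  uni <- matrix(1 / L^2, L, L)
  expect_equal(haralick_feature(uni, "energy"), 1 / L^2)
  diag_g <- diag(L) / L
  expect_equal(haralick_feature(diag_g, "contrast"), 0)
  expect_equal(haralick_feature(diag_g, "homogeneity"), 1)
  two <- matrix(0, 2, 2); two[1, 2] <- 0.5; two[2, 1] <- 0.5
  expect_equal(haralick_feature(two, "energy"), 0.5)
  expect_equal(haralick_feature(two, "contrast"), 1)
  expect_equal(haralick_feature(two, "homogeneity"), 0.5)
})

test_that("per-offset features match a naive double-loop recomputation", {
  set.seed(43)
  cfg <- glcm_config(levels = 8)
  for (rep in 1:8) {
    b <- random_block(sample(6:16, 1), sample(6:16, 1))
    q <- quantize_block(b, cfg)
    off <- glcm_offsets()[sample(1:12, 4), ]
    for (k in seq_len(nrow(off))) {
      g <- compute_glcm(q, off$dx[k], off$dy[k], 8, symmetric = TRUE)
      for (f in c("energy", "contrast", "homogeneity")) {
        expect_equal(haralick_feature(g, f),
                     oracle_glcm_feature(q, off$dx[k], off$dy[k], 8, TRUE, f),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("alternative homogeneity form uses 1/(1+|i-j|) weights", {
  two <- matrix(0, 3, 3); two[1, 3] <- 0.5; two[3, 1] <- 0.5
  expect_equal(haralick_feature(two, "homogeneity"), 0.5 / (1 + 4) * 2)
  expect_equal(haralick_feature(two, "homogeneity",
                                homogeneity_form = "inverse_diff"),
               0.5 / (1 + 2) * 2)
})

test_that("invariant form: constant matrices are fixed points, columns permute freely", {
  m <- matrix(0.25, 4, 3)
  expect_equal(invariant_form(m), 0.25)
  set.seed(44)
  m <- matrix(runif(12), 4, 3)
  expect_equal(invariant_form(m), invariant_form(m[, c(3, 2, 1)]))
  expect_equal(invariant_form(m), oracle_leading_sv(m) / sqrt(12),
               tolerance = 1e-9)
  m[2, 3] <- NA
  expect_error(invariant_form(m), "row 2, angle column 3")
})

test_that("90-degree rotation permutes the 0/90-degree feature columns exactly", {
  set.seed(45)
  for (rep in 1:6) {
    b <- random_block(20, 20)
    d0 <- block_texture(b, detail = TRUE)$matrices
    d1 <- block_texture(rotate90(b, 1), detail = TRUE)$matrices
    for (f in names(d0)) {
      expect_equal(d1[[f]][, "0deg"], d0[[f]][, "90deg"], tolerance = 1e-12)
      expect_equal(d1[[f]][, "90deg"], d0[[f]][, "0deg"], tolerance = 1e-12)
    }
  }
})

test_that("180-degree rotation leaves all invariant features unchanged", {
  set.seed(46)
  for (rep in 1:6) {
    b <- random_block(18, 18)
    t0 <- unlist(block_texture(b)[c("energy", "contrast", "homogeneity")])
    t2 <- unlist(block_texture(rotate90(b, 2))[c("energy", "contrast", "homogeneity")])
    expect_lt(max(abs(t0 - t2) / pmax(abs(t0), 1e-12)), 1e-6)
  }
})

test_that("heterogeneity + homogeneity is exactly 1", {
  set.seed(47)
  for (rep in 1:5) {
    tx <- block_texture(random_block(12, 12))
    expect_equal(tx$heterogeneity + tx$homogeneity, 1)
  }
})

test_that("finer checkerboards raise contrast and lower energy", {
  # periods stay above the largest offset distance (4) so that no offset
  # aliases with the pattern period
  make_checker <- function(period) {
    idx <- outer(0:47, 0:47, function(r, c) ((r %/% period) + (c %/% period)) %% 2)
    idx * 100
  }
  txs <- lapply(c(24, 16, 12, 8), function(p) block_texture(make_checker(p)))
  contrasts <- vapply(txs, `[[`, numeric(1), "contrast")
  energies <- vapply(txs, `[[`, numeric(1), "energy")
  expect_true(all(diff(contrasts) > 0))
  expect_true(all(diff(energies) < 0))
  # and any checkerboard beats a constant block
  const <- block_texture(matrix(3, 48, 48))
  expect_gt(contrasts[1], const$contrast)
  expect_lt(energies[1], const$energy)
})

test_that("offsets larger than the block are rejected", {
  expect_error(compute_glcm(matrix(0L, 3, 3), dx = 4, dy = 0, levels = 2),
               "offset span")
})
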