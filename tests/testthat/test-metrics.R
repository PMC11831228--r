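test_that("psnr matches closed forms and a from-scratch MSE", {
  a <- random_gray(16, 16, 1)
  expect_equal(psnr(a, a), 100)
  # uniform difference of 16 gray levels
  a2 <- gray_image(matrix(100, 8, 8), "intensity")
  b2 <- gray_image(matrix(116, 8, 8), "intensity")
  expect_equal(psnr(a2, b2), 20 * log10(255 / 16), tolerance = 1e-12)
  # random pair vs direct computation
  set.seed(2)
  x <- random_gray(20, 20, 3); y <- random_gray(20, 20, 4)
  mse <- mean((as.numeric(unclass(x)) - as.numeric(unclass(y)))^2)
  expect_equal(psnr(x, y), 10 * log10(255^2 / mse), tolerance = 1e-9)
  expect_error(psnr(x, random_gray(10, 10, 5)), "shape")
  # strictly decreasing in MSE
  base <- matrix(128, 12, 12)
  ps <- sapply(c(2, 4, 8, 16), function(d)
    psnr(gray_image(base, "intensity"), gray_image(base + d, "intensity")))
  expect_true(all(diff(ps) < 0))
})

test_that("ssim is 1 on identity, matches closed form and a naive oracle", {
  a <- random_gray(16, 16, 7)
  expect_equal(ssim(a, a), 1.0)
  # constant images: structure/contrast terms drop, luminance only
  c1 <- (0.01 * 255)^2
  m1 <- 60; m2 <- 180
  got <- ssim(gray_image(matrix(m1, 12, 12), "intensity"),
              gray_image(matrix(m2, 12, 12), "intensity"))
  expect_equal(got, (2 * m1 * m2 + c1) / (m1^2 + m2^2 + c1),
               tolerance = 1e-9)
  # random pair vs double-loop reference
  set.seed(5)
  x <- random_gray(15, 14, 8); y <- random_gray(15, 14, 9)
  expect_equal(ssim(x, y), naive_ssim(x, y), tolerance = 1e-6)
  expect_error(ssim(random_gray(8, 8, 1), random_gray(8, 8, 2)), "11x11")
})

test_that("fid vanishes on identical sets and is symmetric", {
  set.seed(11)
  imgs <- lapply(1:10, function(i) random_gray(24, 24, 100 + i))
  emb <- embedder(seed = 4)
  expect_lt(fid(imgs, imgs, emb), 1e-6)
  other <- lapply(1:10, function(i)
    gray_image(pmin(unclass(imgs[[i]]) %/% 2 + 60, 255), "intensity"))
  f_ab <- fid(imgs, other, emb)
  expect_gt(f_ab, 0)
  expect_equal(f_ab, fid(other, imgs, emb), tolerance = 1e-9)
  expect_error(fid(imgs[1:3], imgs, emb), "at least")
})

test_that("fid on sampled Gaussians matches the closed-form distance", {
  set.seed(21)
  d <- 4; n <- 5000
  mu1 <- c(0, 1, -1, 2); mu2 <- c(0.5, 1, 0, 1)
  a1 <- matrix(rnorm(d * d), d); s1 <- crossprod(a1) / d + diag(d)
  a2 <- matrix(rnorm(d * d), d); s2 <- crossprod(a2) / d + diag(d)
  r1 <- chol(s1); r2 <- chol(s2)
  f1 <- sweep(matrix(rnorm(n * d), n) %*% r1, 2, mu1, "+")
  f2 <- sweep(matrix(rnorm(n * d), n) %*% r2, 2, mu2, "+")
  want <- frechet_distance(mu1, s1, mu2, s2)
  got <- fid(f1, f2)
  expect_equal(got, want, tolerance = 0.05 * want + 0.05)
  # closed form on equal Gaussians is zero
  expect_equal(frechet_distance(mu1, s1, mu1, s1), 0, tolerance = 1e-9)
})

test_that("fid error bars are seeded and shrink with subsample size", {
  set.seed(3)
  A <- lapply(1:16, function(i) random_gray(20, 20, 300 + i))
  B <- lapply(1:16, function(i) random_gray(20, 20, 400 + i))
  emb <- embedder(seed = 1)
  r1 <- fid_with_errorbars(A, B, emb, n_runs = 4, subsample_fraction = 0.75,
                           seed = 9)
  r2 <- fid_with_errorbars(A, B, emb, n_runs = 4, subsample_fraction = 0.75,
                           seed = 9)
  expect_identical(r1$runs, r2$runs)
  expect_length(r1$runs, 4)
  # identical sets: runs stay near zero (subsamples of the two copies
  # are drawn independently, so exact zero is not expected)
  same <- fid_with_errorbars(A, A, emb, n_runs = 3,
                             subsample_fraction = 0.9, seed = 2)
  expect_lt(same$mean, 0.01)
  expect_lt(same$sd, 0.01)
  # dispersion shrinks as the subsample approaches the full set
  sds <- sapply(1:6, function(s) {
    lo <- fid_with_errorbars(A, B, emb, 5, 0.55, seed = s)$sd
    hi <- fid_with_errorbars(A, B, emb, 5, 0.95, seed = s)$sd
    c(lo, hi)
  })
  expect_lt(mean(sds[2, ]), mean(sds[1, ]))
  expect_error(fid_with_errorbars(A[1:8], B, emb, 3, 0.5), "minimum")
})

test_that("variance-ratio f_test matches theory and stats::var.test", {
  x <- c(1, 2, 3, 4, 5)
  r <- f_test(x, x)
  expect_equal(r$statistic, 1)
  expect_equal(r$p_value, 1)
  # n = 11 each, variance ratio 4
  set.seed(13)
  a <- rnorm(11); a <- (a - mean(a)) / sd(a) * 2
  b <- rnorm(11); b <- (b - mean(b)) / sd(b)
  r <- f_test(a, b)
  expect_equal(r$statistic, 4, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * (1 - pf(4, 10, 10)), tolerance = 1e-12)
  vt <- stats::var.test(a, b)
  expect_equal(r$p_value, vt$p.value, tolerance = 1e-12)
  # two-sided symmetry under sample swap
  set.seed(14)
  u <- rnorm(9); v <- rnorm(14, sd = 2)
  expect_equal(f_test(u, v)$p_value, f_test(v, u)$p_value,
               tolerance = 1e-12)
  expect_error(f_test(rep(1, 5), u), "variance")
  expect_error(f_test(1, u), "at least 2")
})

test_that("f_test p-values are uniform under the null", {
  set.seed(17)
  ps <- replicate(2000, f_test(rnorm(8), rnorm(8))$p_value)
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("evaluate_model produces a coherent per-image report", {
  pairs <- toy_pairs(10, h = 32, w = 32, seed = 44, identity_task = TRUE)
  m <- ccr_gan(pairs, in_channels = 1,
               model = model_config(1, 5, 5, 2, 32, 32, seed = 1),
               train = train_config(max_epochs = 1, val_fraction = 0.1,
                                    seed = 1))
  rep <- evaluate_model(m, pairs, fid_runs = 3, emb = embedder(seed = 2),
                        seed = 3)
  expect_s3_class(rep, "metric_report")
  expect_equal(nrow(rep$per_image), 10)
  expect_true(all(rep$per_image$ssim >= -1 & rep$per_image$ssim <= 1))
  expect_true(all(rep$per_image$psnr >= 0))
  expect_length(rep$fid$runs, 3)
  expect_equal(rep$mean_psnr, mean(rep$per_image$psnr))
})
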