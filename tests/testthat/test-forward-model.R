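test_that("projection renders integrable beads centered in the box", {
  one <- conformation(matrix(c(0, 0, 0), 1), radii = 4, electrons = 120)
  img <- project(one, c(1, 0, 0, 0), pixel_size = 1.5, box_size = 32)
  # total intensity equals the electron count (to discretization tolerance;
  # the renderer truncates each Gaussian at five sigma)
  expect_equal(sum(img), 120, tolerance = 1e-4)
  # radially symmetric blob at the box center: peak at pixel (16, 16) 0-based
  expect_equal(which(img == max(img), arr.ind = TRUE)[1, ],
               c(row = 17, col = 17))
  # identical under any orientation (spherical symmetry)
  withr::with_seed(2, q <- random_quaternions(3))
  for (k in 1:3)
    expect_equal(project(one, q[k, ], pixel_size = 1.5, box_size = 32), img)
})

test_that("beads stacked along the optical axis superpose", {
  two <- conformation(matrix(c(0, 0, -5, 0, 0, 5), 2, 3, byrow = TRUE),
                      radii = c(4, 4), electrons = c(70, 50))
  one <- conformation(matrix(c(0, 0, 0), 1), radii = 4, electrons = 120)
  img2 <- project(two, c(1, 0, 0, 0), pixel_size = 1.5, box_size = 32)
  img1 <- project(one, c(1, 0, 0, 0), pixel_size = 1.5, box_size = 32)
  expect_equal(img2, img1, tolerance = 1e-10)
})

test_that("projection conserves intensity for multi-bead models and warns on clipping", {
  conf <- tiny_conf(6)
  img <- project(conf, c(1, 0, 0, 0), pixel_size = 1.5, box_size = 64)
  expect_equal(sum(img), sum(conf$electrons), tolerance = 1e-4)
  expect_warning(project(conf, c(1, 0, 0, 0), shift = c(40, 0),
                         pixel_size = 1.5, box_size = 64), "outside")
  expect_error(project(conf, c(1, 0, 0, 0), box_size = 15), "even")
  expect_error(project(conf, c(2, 0, 0, 0), box_size = 32), "unit quaternion")
})

test_that("CTF application is linear and self-consistent in defocus", {
  conf <- tiny_conf(6)
  img <- project(conf, c(1, 0, 0, 0), pixel_size = 2.2, box_size = 32)
  a <- apply_ctf(img, 1.5, pixel_size = 2.2)
  expect_equal(apply_ctf(3.5 * img, 1.5, pixel_size = 2.2), 3.5 * a,
               tolerance = 1e-10)
  # correlating a CTF image against references: the matching defocus wins
  ref_match <- apply_ctf(img, 1.5, pixel_size = 2.2)
  ref_far <- apply_ctf(img, 3.5, pixel_size = 2.2)
  corr <- function(x, y) cor(as.numeric(x), as.numeric(y))
  expect_gt(corr(a, ref_match), corr(a, ref_far))
  expect_error(apply_ctf(img[, 1:10], 1.5), "square")
  expect_error(apply_ctf(img, -1), "positive")
})

test_that("default CTF parameters are amplitude 0.1 and B-factor 1", {
  expect_equal(formals(apply_ctf)$ctf_amplitude, 0.1)
  expect_equal(formals(apply_ctf)$b_factor, 1)
})

test_that("noise variance honors the SNR contract within the central circle", {
  conf <- tiny_conf(8)
  img <- project(conf, c(1, 0, 0, 0), pixel_size = 1.2, box_size = 128)
  expect_identical(add_noise(img, Inf), img)
  # snr = 0.1: added noise variance ~ 10x the circle variance of the signal
  v <- cryofep:::circle_variance(img)
  noisy <- add_noise(img, 0.1, rng_seed = 99)
  expect_equal(var(as.numeric(noisy - img)), 10 * v, tolerance = 0.05)
  # determinism under a fixed seed
  expect_identical(add_noise(img, 0.1, rng_seed = 42),
                   add_noise(img, 0.1, rng_seed = 42))
  expect_error(add_noise(matrix(1, 32, 32), 0.5), "constant")
})

test_that("node sampling follows the Boltzmann weights", {
  # flat profile: uniform across nodes (chi-square at alpha = 0.01)
  draws <- sample_node_index(rep(1.3, 4), n = 1e4, rng_seed = 31)
  expect_gt(chisq.test(tabulate(draws, 4))$p.value, 0.01)
  # +Inf free energy gets zero weight
  d2 <- sample_node_index(c(0, Inf), n = 500, rng_seed = 3)
  expect_true(all(d2 == 1L))
  # 1D double-well at 20 nodes against directly computed weights
  gt <- ground_truth_profile("hsp90_1d", M = 20)
  w <- node_populations(gt)
  draws <- sample_node_index(gt, n = 1e5, rng_seed = 17)
  counts <- tabulate(draws, 20)
  keep <- w * 1e5 >= 5
  expect_gt(chisq.test(counts[keep], p = w[keep] / sum(w[keep]))$p.value, 0.01)
})

test_that("generate_dataset produces complete, reproducible stacks", {
  p <- small_path(4)
  gt <- ground_truth_profile("hsp90_1d", M = 4)
  one <- generate_dataset(p, gt, 1, box_size = 32, seed = 5)
  expect_equal(dim(one$images), c(32, 32, 1))
  expect_equal(nrow(one$meta), 1)
  expect_true(all(c("defocus_um", "snr", "truth_node", "qw") %in% names(one$meta)))

  a <- generate_dataset(p, gt, 6, box_size = 32, seed = 5)
  b <- generate_dataset(p, gt, 6, box_size = 32, seed = 5)
  expect_identical(a$images, b$images)          # bit-identical under the seed
  expect_identical(a$meta, b$meta)
  c2 <- generate_dataset(p, gt, 6, box_size = 32, seed = 6)
  expect_false(identical(a$images, c2$images))

  expect_true(all(a$meta$defocus_um >= 0.5 & a$meta$defocus_um <= 3))
  expect_true(all(a$meta$snr >= 0.001 & a$meta$snr <= 0.1))
})

test_that("flat profile yields uniform truth labels; SNR split is balanced", {
  p <- small_path(4)
  flat <- ground_truth_profile("tabulated", values = rep(0, 4))
  st <- generate_dataset(p, flat, 600, box_size = 32, seed = 12,
                         snr_range = c(0.001, 0.1))
  counts <- tabulate(st$meta$truth_node, 4)
  expect_gt(chisq.test(counts)$p.value, 0.01)
  # log-uniform SNR: the geometric midpoint 0.01 splits the stack in half
  # in expectation (binomial check at 3 sigma)
  frac <- mean(st$meta$snr < 0.01)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 600))
})
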