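test_that("per-pose likelihood is invariant to image offset and equivariant in scale", {
  withr::with_seed(4, {
    tmpl <- matrix(rnorm(64), 8, 8)
    img <- 0.7 * tmpl + matrix(rnorm(64, sd = 0.5), 8, 8)
  })
  base <- pose_log_likelihood(img, tmpl)
  # additive offset marginalized out exactly
  expect_equal(pose_log_likelihood(img + 3.2, tmpl), base, tolerance = 1e-9)
  # scaling the image shifts the log likelihood by a template-independent
  # amount: -(P-2) * log(a)
  p <- 64
  expect_equal(pose_log_likelihood(2.5 * img, tmpl),
               base - (p - 2) * log(2.5), tolerance = 1e-9)
  expect_error(pose_log_likelihood(img, matrix(1, 8, 8)), "degenerate")
})

test_that("analytic pose marginalization matches numerical triple integration", {
  # 8x8 images, several SNR regimes; the oracle integrates the Gaussian
  # likelihood over (normalization, offset, noise scale) on a dense grid
  conf <- tiny_conf(4)
  tmpl <- apply_ctf(project(conf, c(1, 0, 0, 0), pixel_size = 6, box_size = 16),
                    1.5, pixel_size = 6)[5:12, 5:12]
  withr::with_seed(8, {
    for (noise_sd in c(0.2, 1) * sd(tmpl)) {
      img <- 1.3 * tmpl + 0.4 + matrix(rnorm(64, sd = noise_sd), 8, 8)
      analytic <- pose_log_likelihood(img, tmpl)
      numeric <- numeric_pose_marginal(img, tmpl, n_grid = 140)
      expect_equal(analytic, numeric, tolerance = 1e-4)
    }
  })
})

test_that("R reference and compiled round-1 likelihoods agree", {
  st <- small_stack(n = 4, M = 3, box = 32, seed = 3)
  p <- small_path(3)
  cfg <- marginalization_config(round1_grid_size = 6, max_shift_px = 1,
                                n_defocus_r1 = 2, round2_top_k = 2,
                                round2_local_size = 8, seed = 5)
  llm <- compute_likelihood_matrix(st, p, cfg)
  grid <- build_uniform_orientation_grid(6, 5)
  dg1 <- llm$config$defocus_grid_r1
  ctr <- mean(range(st$meta$defocus_um))
  sc <- max(diff(range(st$meta$defocus_um)) / 2, 0.3)
  lw <- -(dg1 - ctr)^2 / (2 * sc^2)
  for (i in c(1, 4)) for (m in c(1, 3)) {
    ref <- image_node_log_likelihood(st$images[, , i], p$nodes[[m]], grid, cfg,
                                     pixel_size = st$pixel_size,
                                     defocus_grid = dg1, defocus_logprior = lw)
    expect_equal(llm$round1[i, m], ref, tolerance = 1e-8)
  }
})

test_that("noiseless self-projections are assigned to their generating node", {
  p <- small_path(4, total = 120)
  grid <- build_uniform_orientation_grid(12, seed = 2)
  cfg <- marginalization_config(max_shift_px = 1)
  for (m in c(1, 3)) {
    img <- apply_ctf(project(p$nodes[[m]], grid$quaternions[7, ],
                             pixel_size = 1.2, box_size = 32),
                     1.5, pixel_size = 1.2)
    ll <- vapply(p$nodes, function(nd)
      image_node_log_likelihood(img, nd, grid, cfg, pixel_size = 1.2,
                                defocus_grid = 1.5), numeric(1))
    expect_equal(which.max(ll), m)
  }
})

test_that("likelihood matrices are permutation-equivariant and scale-invariant", {
  st <- small_stack(n = 3, M = 3, box = 32, seed = 7)
  p <- small_path(3)
  cfg <- marginalization_config(round1_grid_size = 8, max_shift_px = 1,
                                n_defocus_r1 = 1, round2_top_k = 2,
                                round2_local_size = 8, seed = 5)
  llm <- compute_likelihood_matrix(st, p, cfg)

  # permuting nodes permutes columns
  perm <- c(3, 1, 2)
  p_perm <- make_path(p$nodes[perm])
  llm_perm <- compute_likelihood_matrix(st, p_perm, cfg)
  expect_equal(llm_perm$values, llm$values[, perm], tolerance = 1e-9)
  expect_equal(llm_perm$round1, llm$round1[, perm], tolerance = 1e-9)

  # rescaling an image shifts its row by a node-independent constant
  st2 <- st
  st2$images[, , 2] <- 4 * st2$images[, , 2]
  llm2 <- compute_likelihood_matrix(st2, p, cfg)
  row_shift <- llm2$values[2, ] - llm$values[2, ]
  expect_equal(diff(range(row_shift)), 0, tolerance = 1e-8)
  expect_equal(llm2$values[1, ], llm$values[1, ], tolerance = 1e-9)
  # hence the posterior over profiles is unchanged
  g <- c(0.4, -0.1, -0.3)
  expect_equal(log_posterior(g, llm2) - log_posterior(g, llm),
               sum(row_shift[1]), tolerance = 1e-6)
})

test_that("likelihood config validates and records derived settings", {
  expect_error(marginalization_config(round2_levels = 2, round2_local_size = 10),
               "perfect-cube")
  expect_error(marginalization_config(max_shift_px = -1), "non-negative")
  st <- small_stack(n = 2, M = 2, box = 32, seed = 1)
  p <- small_path(2)
  cfg <- marginalization_config(round1_grid_size = 4, max_shift_px = 0,
                                n_defocus_r1 = 1, round2_top_k = 1,
                                round2_local_size = 1, seed = 2)
  llm <- compute_likelihood_matrix(st, p, cfg)
  expect_equal(dim(llm$values), c(2, 2))
  expect_true(all(is.finite(llm$values)))
  expect_false(is.null(llm$config$round2_half_width))
  # round-2 default top-K is ten
  expect_equal(formals(marginalization_config)$round2_top_k, 10L)
})
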