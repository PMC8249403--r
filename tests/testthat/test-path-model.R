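test_that("make_path assigns equispaced path parameters and validates input", {
  confs2 <- lapply(c(0, 20), function(a) make_toy_rotor(rotation_deg = a))
  expect_equal(make_path(confs2)$s_values, c(0, 1))

  confs20 <- lapply(seq(0, 19), function(a) make_toy_rotor(rotation_deg = a))
  p <- make_path(confs20)
  expect_equal(p$s_values, (0:19) / 19)
  expect_identical(p$s_values[1], 0)
  expect_identical(p$s_values[20], 1)
  expect_true(all(diff(p$s_values) > 0))

  expect_error(make_path(confs2[1]), "at least 2")
  bad <- list(tiny_conf(5), tiny_conf(5), tiny_conf(6))
  expect_error(make_path(bad), "bead count")
})

test_that("quadrature implements the equispaced M-node rule exactly", {
  for (m in c(2, 3, 7, 20)) {
    s <- (seq_len(m) - 1) / (m - 1)
    expect_equal(quadrature(rep(3.7, m)), 3.7)      # exact for constants
    expect_equal(quadrature(s), 0.5)                # f(s) = s integrates to 1/2
  }
  expect_equal(quadrature(c(0, 0.5, 1)^2), (0 + 0.25 + 1) / 3)
  # linearity
  withr::with_seed(3, {
    f <- rnorm(9); g <- rnorm(9)
    expect_equal(quadrature(2 * f + 3 * g),
                 2 * quadrature(f) + 3 * quadrature(g))
  })
  expect_error(quadrature(1), "at least 2")
})

test_that("1D ground truth equals minus log of its printed density", {
  expect_equal(ground_truth_1d(6 / 19), -log(1 + exp(-4.5) / 3))
  expect_equal(ground_truth_1d(15 / 19), -log(exp(-81 / 8) + 1 / 3))
  expect_equal(ground_truth_1d(0), -log(exp(-4.5) + exp(-12.5) / 3))
  expect_equal(round(ground_truth_1d(0), 4), 4.4999, tolerance = 1e-4)
  # direct re-evaluation at random probe points
  withr::with_seed(7, s <- runif(100))
  expect_equal(ground_truth_1d(s),
               -log(exp(-(19 * s - 6)^2 / 8) + exp(-(19 * s - 15)^2 / 18) / 3),
               tolerance = 1e-14)
  expect_error(ground_truth_1d(1.2), "\\[0, 1\\]")
})

test_that("2D ground truth equals minus log of its printed density", {
  expect_equal(ground_truth_2d(6, 6), -log(1 + exp(-81 / 18 - 81 / 10)))
  expect_lt(abs(ground_truth_2d(6, 6)), 1e-5)
  expect_equal(ground_truth_2d(15, 15), ground_truth_2d(6, 6))  # symmetry
  expect_equal(ground_truth_2d(10.5, 10.5), 3.15 - log(2), tolerance = 1e-12)
  withr::with_seed(8, { u <- runif(100, 0, 21); v <- runif(100, 0, 21) })
  expect_equal(ground_truth_2d(u, v),
               -log(exp(-(u - 6)^2 / 18 - (v - 6)^2 / 10) +
                    exp(-(u - 15)^2 / 18 - (v - 15)^2 / 10)),
               tolerance = 1e-14)
})

test_that("path_on_surface traces the three CV lines over the model grid", {
  cv1 <- path_on_surface("CV1", 20)
  expect_equal(cv1[, "u"], cv1[, "v"])
  expect_equal(range(cv1[, "u"]), c(1, 20))
  cv2 <- path_on_surface("CV2", 20)
  expect_true(all(cv2[, "u"] == 10))
  cv3 <- path_on_surface("CV3", 20)
  expect_true(all(cv3[, "v"] == 10))
  expect_equal(path_on_surface("CV1", 2),
               cbind(u = c(1, 20), v = c(1, 20)))
  expect_error(path_on_surface("CV9", 5), "unknown cv_id")
})

test_that("coarse_grain collapses residues to center-of-mass beads", {
  # single glycine: two atoms, bead at the mass-weighted center
  atoms <- data.frame(x = c(0, 2), y = c(0, 0), z = c(0, 0),
                      resid = "GLY", resno = 1,
                      element = c("C", "O"))
  cg <- coarse_grain(atoms)
  expect_equal(n_beads <- nrow(cg$positions), 1)
  mw <- c(12.011, 15.999)
  expect_equal(cg$positions[1, 1], sum(mw * c(0, 2)) / sum(mw))
  tab <- residue_bead_table()
  expect_equal(cg$electrons, tab$electrons[tab$resid == "GLY"])
  expect_equal(cg$radii, tab$radius[tab$resid == "GLY"])

  # one bead per residue, chains concatenated
  atoms2 <- data.frame(x = rnorm(6), y = rnorm(6), z = rnorm(6),
                       resid = rep(c("ALA", "TRP", "LYS"), each = 2),
                       resno = rep(1:3, each = 2),
                       chain = rep(c("A", "A", "B"), each = 2),
                       element = "C")
  cg2 <- coarse_grain(atoms2)
  expect_equal(nrow(cg2$positions), 3)
  expect_equal(cg2$electrons, tab$electrons[match(c("ALA", "TRP", "LYS"), tab$resid)])

  expect_error(coarse_grain(data.frame(x = 1, y = 1, z = 1, resid = "XYZ",
                                       resno = 1)), "missing from the bead table")
  expect_error(coarse_grain(data.frame(x = NA_real_, y = NA, z = NA,
                                       resid = "GLY", resno = 1)),
               "no resolvable")
})

test_that("electron counts in the bead table are summed atomic numbers", {
  tab <- residue_bead_table()
  # glycine residue C2H3NO: 2*6 + 3*1 + 7 + 8
  expect_equal(tab$electrons[tab$resid == "GLY"], 30)
  # tryptophan residue C11H10N2O
  expect_equal(tab$electrons[tab$resid == "TRP"], 98)
  expect_true(all(tab$electrons > 0 & tab$radius > 0))
  expect_equal(nrow(tab), 20)
})

test_that("path_cv_value recovers node positions and is rigid-motion invariant", {
  p <- toy_rotor_path(5, 60)  # well-separated nodes
  m <- 5
  for (k in c(1, 3, 5)) {
    s <- path_cv_value(p$nodes[[k]], p, lambda_cv = 50)
    expect_equal(s, (k - 1) / (m - 1), tolerance = 1e-6)
  }
  # equidistant between the two nodes of a 2-node path -> 0.5 by mirror
  # symmetry: the query lies in the xz-plane, and the two nodes are y-mirror
  # images of one another, so their fitted RMSDs to the query are equal
  q_pos <- cbind(1:8, 0, sin(1:8) * 2)
  withr::with_seed(5, pert <- matrix(rnorm(24, sd = 0.8), 8, 3))
  n1_pos <- q_pos + pert
  n2_pos <- n1_pos %*% diag(c(1, -1, 1))
  mk <- function(pos) conformation(pos, rep(3, 8), rep(50, 8))
  p2 <- make_path(list(mk(n1_pos), mk(n2_pos)))
  expect_equal(path_cv_value(mk(q_pos), p2), 0.5, tolerance = 1e-9)
  # default lambda is 50 per-A^2
  expect_equal(formals(path_cv_value)$lambda_cv, 50)
  # rigid-body invariance (RMSD after optimal superposition)
  conf <- make_toy_rotor(rotation_deg = 7)
  r <- quat_to_rotmat(c(sqrt(0.5), sqrt(0.5), 0, 0))
  moved <- conformation(sweep(conf$positions %*% t(r), 2, c(5, -3, 2), "+"),
                        conf$radii, conf$electrons)
  expect_equal(path_cv_value(moved, p), path_cv_value(conf, p),
               tolerance = 1e-6)
  expect_error(path_cv_value(tiny_conf(4), p), "bead count mismatch")
})

test_that("select_nodes_by_metric matches the brute-force nearest-target choice", {
  withr::with_seed(21, {
    ens <- lapply(1:30, function(i) tiny_conf(4, seed = i))
    metric <- runif(30, 2, 20)
  })
  m <- 6
  p <- select_nodes_by_metric(ens, metric, m)
  idx <- attr(p, "indices")
  targets <- seq(min(metric), max(metric), length.out = m)
  # brute force: for each target in turn, nearest remaining candidate
  avail <- seq_along(metric); expect_idx <- integer(m)
  for (k in seq_len(m)) {
    j <- avail[which.min(abs(metric[avail] - targets[k]))]
    expect_idx[k] <- j; avail <- setdiff(avail, j)
  }
  expect_equal(idx, expect_idx)
  # metric values along the path are monotone in s
  expect_true(all(diff(metric[idx]) > 0))

  # exact-match ensemble: members 0..9 chosen verbatim
  ens10 <- lapply(1:12, function(i) tiny_conf(4, seed = i))
  met10 <- c(0:9, 4.2, 7.7)
  p10 <- select_nodes_by_metric(ens10, met10, 10)
  expect_equal(attr(p10, "indices"), 1:10)
  # equal spacing reproduces range/(M-1)
  expect_equal(diff(met10[attr(p10, "indices")]), rep(1, 9))
  expect_error(select_nodes_by_metric(ens10, met10, 13), "smaller than M")
})
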