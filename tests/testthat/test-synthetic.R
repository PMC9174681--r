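test_that("pure-birth trees are ultrametric at the requested depth", {
  tr2 <- simulate_tree(2, 10, seed = 1)
  expect_equal(ape::Ntip(tr2), 2)
  expect_equal(unname(tr2$edge.length), c(10, 10))
  tr <- simulate_tree(40, 35.78, seed = 2)
  depths <- ape::node.depth.edgelength(tr)[1:40]
  expect_lt(max(abs(depths - 35.78)), 1e-9)
  expect_identical(ape::write.tree(simulate_tree(12, 5, seed = 7)),
                   ape::write.tree(simulate_tree(12, 5, seed = 7)))
  expect_error(simulate_tree(1, 10), ">= 2")
})

test_that("lifestyle histories conserve branch lengths and respect zero rates", {
  tr <- simulate_tree(15, 20, seed = 3)
  h <- simulate_lifestyles(tr, seed = 4)
  expect_lt(max(abs(vapply(h$maps, sum, numeric(1)) - tr$edge.length)), 1e-9)
  Q0 <- matrix(0, 3, 3)
  h0 <- simulate_lifestyles(tr, Q0, root_state = "fossorial", seed = 5)
  expect_true(all(vapply(h0$maps, function(m)
    identical(names(m), "fossorial"), logical(1))))
  Qneg <- default_mk_rates(); Qneg[1, 2] <- -1; Qneg[1, 1] <- -sum(Qneg[1, -1])
  expect_error(simulate_lifestyles(tr, Qneg), "non-negative")
})

test_that("lifestyle jump counts match the analytic CTMC expectation", {
  ## single branch of length t from a known state; oracle integrates the
  ## instantaneous leaving intensity along the transient distribution
  t_len <- 12
  tr <- simulate_tree(2, t_len, seed = 6)
  Q <- default_mk_rates()
  expected <- stats::integrate(function(u) {
    sapply(u, function(ui) {
      p <- ape::matexpo(Q * ui)[1, ]      # row 1 = cursorial
      sum(p * -diag(Q))
    })
  }, 0, t_len, rel.tol = 1e-10)$value
  set.seed(7)
  nrep <- 10000
  counts <- numeric(nrep)
  for (r in 1:nrep) {
    h <- simulate_lifestyles(tr, Q, root_state = "cursorial")
    counts[r] <- length(h$maps[[1]]) - 1L   # one edge of the cherry
  }
  mc_se <- stats::sd(counts) / sqrt(nrep)
  expect_lt(abs(mean(counts) - expected), 3 * mc_se + 1e-9)
})

test_that("Brownian covariate has the right moments and determinism", {
  tr <- simulate_tree(3, 10, seed = 8)
  x0 <- simulate_covariate_bm(tr, 0, root_x = 1.5, seed = 9)
  expect_true(all(x0 == 1.5))
  ta <- ape::vcv(tr)
  pair <- which(ta == max(ta[upper.tri(ta)]), arr.ind = TRUE)[1, ]
  set.seed(10)
  reps <- replicate(10000, {
    x <- simulate_covariate_bm(tr, 0.3, 0)
    x[rownames(ta)[pair]]
  })
  emp <- stats::cov(t(reps))[1, 2]
  theo <- 0.3 * max(ta[upper.tri(ta)])
  v1 <- 0.3 * ta[pair[1], pair[1]]
  mc_se <- sqrt((v1 * v1 + theo^2) / 10000)
  expect_lt(abs(emp - theo), 3 * mc_se)
  expect_identical(simulate_covariate_bm(tr, 0.3, 0, seed = 11),
                   simulate_covariate_bm(tr, 0.3, 0, seed = 11))
  expect_error(simulate_covariate_bm(tr, -1, 0), "non-negative")
})

test_that("OU transitions have the exact conditional mean (ODE oracle)", {
  ## cherry whose branches are painted a different regime than the root:
  ## the tip mean follows dm/dt = alpha (theta_to - m) from the root optimum
  tr <- simulate_tree(2, 6, seed = 12)
  h <- simulate_lifestyles(tr, matrix(0, 3, 3), root_state = "cursorial")
  for (e in seq_along(h$maps))
    h$maps[[e]] <- stats::setNames(sum(h$maps[[e]]), "scansorial")
  alpha <- 0.23; theta <- c(cursorial = 0.5, fossorial = 0, scansorial = 2)
  ou <- list(alpha = alpha, sigma2 = 0.04, theta = theta, root = 0.5)
  ## RK4 integration of the mean ODE, independent of the sampler's formula
  m <- theta[["cursorial"]]; t_end <- 6; nstep <- 2000; dt <- t_end / nstep
  fdot <- function(m) alpha * (theta[["scansorial"]] - m)
  for (i in 1:nstep) {
    k1 <- fdot(m); k2 <- fdot(m + dt / 2 * k1); k3 <- fdot(m + dt / 2 * k2)
    k4 <- fdot(m + dt * k3)
    m <- m + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  set.seed(13)
  tips <- replicate(10000, simulate_trait_ou(tr, h, ou)[[1]])
  mc_se <- stats::sd(tips) / sqrt(10000)
  expect_lt(abs(mean(tips) - m), 3 * mc_se + 1e-8)
})

test_that("OU degenerates to Brownian motion at alpha = 0", {
  tr <- simulate_tree(2, 8, seed = 14)
  h <- simulate_lifestyles(tr, matrix(0, 3, 3), root_state = "cursorial")
  ou <- list(alpha = 0, sigma2 = 0.5, theta = c(cursorial = 0))
  set.seed(15)
  tips <- replicate(8000, simulate_trait_ou(tr, h, ou)[[1]])
  v <- stats::var(tips)
  expect_lt(abs(v - 0.5 * 8), 3 * v * sqrt(2 / 8000))
})

test_that("strong pull with a direct effect pins tips to optimum plus b x", {
  tr <- simulate_tree(6, 10, seed = 16)
  h <- simulate_lifestyles(tr, matrix(0, 3, 3), root_state = "scansorial")
  x <- simulate_covariate_bm(tr, 0.05, 0, seed = 17)
  ou <- list(alpha = 60, sigma2 = 1e-10, theta = c(scansorial = 0.7), b = 1)
  y <- simulate_trait_ou(tr, h, ou, x, seed = 18)
  expect_lt(max(abs(y - (0.7 + x[names(y)]))), 1e-4)
  expect_error(simulate_trait_ou(tr, h, list(alpha = -1, sigma2 = 1)), "alpha")
})

test_that("synthetic hip models satisfy the model invariants", {
  for (s in 1:10) {
    reg <- sample(lifestyle_states(), 1)
    m <- generate_hip_model(regime = reg, size_factor = runif(1, 0.5, 2),
                            seed = s)
    expect_s3_class(m, "hip_model")
    expect_gt(m$femoral_diameter, 0)
    expect_gt(compute_in_lever(m), 0)
  }
})

test_that("the femoral-head mesh yields the centre of rotation by sphere fit", {
  m <- generate_hip_model(include_meshes = TRUE, seed = 19)
  head_pts <- m$femur_mesh[1:240, ]
  f <- fit_sphere(head_pts)
  expect_lt(max(abs(f$center - m$cor)), 1e-6)
})

test_that("origins farther from the joint increase the early-extension arm", {
  base <- geometry_params(landmark_sd = 0)
  shifted <- geometry_params(landmark_sd = 0,
                             lifestyle_shift = c(cursorial = 0.25))
  i40 <- function(p) {
    po <- pose_femur(generate_hip_model(p, "cursorial"), 40, 30)
    compute_imma(po$cor, po$origin, po$insertion)$imma_cm
  }
  expect_gt(i40(shifted), i40(base))
})

test_that("dataset bundles are reproducible and priors default to indicators", {
  cfg <- sim_config(n_tips = 12, n_maps = 10, seed = 33)
  b1 <- generate_dataset(cfg)
  b2 <- generate_dataset(cfg)
  expect_equal(ape::Ntip(b1$tree), 12)
  expect_true(all(b1$tip_priors %in% c(0, 1)))
  d1 <- file.path(tempdir(), "bundleA"); d2 <- file.path(tempdir(), "bundleB")
  write_dataset(b1, d1); write_dataset(b2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  cfgb <- sim_config(n_tips = 12, blur_fraction = 0.5, seed = 33)
  bb <- generate_dataset(cfgb)
  expect_false(all(bb$tip_priors %in% c(0, 1)))
  expect_lt(max(abs(rowSums(bb$tip_priors) - 1)), 1e-12)
  unlink(c(d1, d2), recursive = TRUE)
})
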