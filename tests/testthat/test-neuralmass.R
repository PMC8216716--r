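test_that("the a priori grasping network has the stated structure", {
  net <- grasping_network()
  expect_setequal(net$nodes, c("IPL", "M1", "PMv", "SMA", "DLPFC"))
  expect_equal(n_extrinsic(net), 14)
  expect_equal(nrow(net$forward), 6)
  expect_equal(nrow(net$backward), 6)
  expect_equal(nrow(net$lateral), 2)
  edges <- rbind(net$forward, net$backward, net$lateral)
  expect_true(all(edges[, 1] != edges[, 2]))
  # backward edges run top-down as specified; forward are their reverses
  expect_true(all(paste(net$backward[, 1], net$backward[, 2]) %in%
                    paste(net$forward[, 2], net$forward[, 1])))
})

test_that("hiding the IPL removes exactly its four extrinsic edges", {
  net <- hide_source(grasping_network(), "IPL")
  expect_equal(n_extrinsic(net), 10)
  expect_true("IPL" %in% net$nodes)
  expect_error(hide_source(grasping_network(), "V1"), "unknown")
})

test_that("zero extrinsic baselines make the Jacobian block-diagonal", {
  m <- dcm_model(baseline = c(forward = 0, backward = 0, lateral = 0))
  J <- linearize(m)$J
  for (a in 1:5) for (b in 1:5) {
    if (a == b) next
    blk <- J[8 * (a - 1) + 1:8, 8 * (b - 1) + 1:8]
    expect_equal(max(abs(blk)), 0)
  }
})

test_that("the default model is stable and its linearization matches finite
          differences of the drift", {
  m <- dcm_model()
  lin <- linearize(m)
  expect_true(lin$stable)
  expect_true(all(Re(lin$eigenvalues) < 0))
  # the drift is x -> Jx; a centered difference oracle on random states
  set.seed(20)
  x0 <- rnorm(40)
  drift <- function(x) drop(lin$J %*% x)
  h <- 1e-6
  Jfd <- vapply(seq_along(x0), function(j) {
    e <- rep(0, 40); e[j] <- h
    (drift(x0 + e) - drift(x0 - e)) / (2 * h)
  }, numeric(40))
  expect_equal(Jfd, lin$J, tolerance = 1e-6)
})

test_that("predicted spectra are Hermitian and positive semidefinite with a
          flat innovation spectrum at a2 = -32", {
  m <- dcm_model()
  expect_equal(48^(exp(-32)), 1, tolerance = 1e-12)
  g <- predict(m, 4:48)
  for (k in c(1, 10, 45)) {
    Gk <- g$G[, , k]
    expect_equal(Gk, Conj(t(Gk)))
    expect_true(all(Re(diag(Gk)) >= 0))
    ev <- eigen(Gk, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(Re(ev) > -1e-12))
  }
  # innovations with a2 = -32 are flat across the band
  nz <- specdcm:::nuisance_spectra(m, c(4, 48))
  expect_equal(nz$gu[1, 1] / nz$gu[1, 2], 1, tolerance = 1e-10)
})

test_that("scaling one extrinsic coupling changes the predicted spectra", {
  m <- dcm_model()
  g0 <- predict(m, 4:48)
  for (edge in c("forward:IPL->PMv", "backward:SMA->M1", "lateral:PMv->SMA")) {
    m2 <- m
    m2$theta_A[[edge]] <- 0.5
    g1 <- predict(m2, 4:48)
    expect_gt(sum(Mod(g1$G - g0$G)^2), 0)
  }
})

test_that("edge types target the specified populations", {
  m <- dcm_model()
  m2 <- m
  m2$theta_A[["backward:DLPFC->PMv"]] <- 0.7
  J1 <- linearize(m)$J
  J2 <- linearize(m2)$J
  # stellate-current rows (x4 of each source) are untouched by a backward change
  stellate_rows <- 8 * (0:4) + 4
  expect_equal(J1[stellate_rows, ], J2[stellate_rows, ])
  expect_gt(max(abs(J1 - J2)), 0)
  # a forward change leaves pyramidal/interneuron input rows unchanged
  m3 <- m
  m3$theta_A[["forward:IPL->PMv"]] <- 0.7
  J3 <- linearize(m3)$J
  pyr_rows <- c(8 * (0:4) + 5, 8 * (0:4) + 8)
  expect_equal(J1[pyr_rows, ], J3[pyr_rows, ])
})

test_that("the analytic spectral gradient matches central finite differences", {
  m <- dcm_model()
  mt <- m
  mt$theta_A[c(2, 7)] <- c(0.3, -0.2)
  g <- predict(mt, 4:48)
  setup <- specdcm:::fit_setup(m, g)
  par <- c(rep(0.05, 14), 0.1)
  ag <- setup$fwd_grad(par)
  fj <- specdcm:::fd_jacobian(setup$fwd, par, 1e-4)
  expect_equal(ag$J, fj, tolerance = 1e-6)
  expect_equal(ag$pred, setup$fwd(par))
})

test_that("simulation is reproducible, silent when noiseless, and matches the
          analytic spectrum", {
  m <- dcm_model()
  x1 <- simulate(m, seed = 5, duration = 20, rate = 128)
  x2 <- simulate(m, seed = 5, duration = 20, rate = 128)
  expect_identical(x1$data, x2$data)

  m0 <- m
  m0$nuisance$a[["a1"]] <- -Inf
  m0$nuisance$b[["b1"]] <- -Inf
  m0$nuisance$c[["c1"]] <- -Inf
  x0 <- simulate(m0, seed = 5, duration = 5, rate = 128)
  expect_equal(max(abs(x0$data)), 0)

  x <- simulate(m, seed = 6, duration = 300, rate = 128)
  g_emp <- estimate_csd(x$data, rate = 128, method = "welch")
  g_th <- predict(m, 4:48)
  rel <- abs(Re(apply(g_emp$G, 3, diag)) - Re(apply(g_th$G, 3, diag))) /
    Re(apply(g_th$G, 3, diag))
  expect_lt(mean(rel), 0.1)
})

test_that("unstable models refuse to predict or simulate", {
  sp <- source_params()
  sp$sigmoid_slope <- 0.5  # far beyond the stable operating regime
  m <- dcm_model(sources = sp)
  expect_false(linearize(m)$stable)
  expect_error(predict(m, 4:48), "unstable")
  expect_error(simulate(m, seed = 1, duration = 2, rate = 128), "unstable")
})
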