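toy_cv <- function(width = 0.1)
  cv_spec("inter_bead_distance", sel_a = 0L, sel_b = 1L, grid_min = -2,
          grid_max = 2, grid_spacing = 0.01, width = width)

test_that("zero bias is gauged to zero and hills deposit at nominal height", {
  bias <- bias_state(list(toy_cv(), toy_cv()), height = 0.7)
  eb <- evaluate_bias(c(0.5, -0.5), bias, 300)
  expect_equal(eb$V_PB, 0)
  expect_equal(eb$dV_ds, c(0, 0))
  # first hill on a fresh single-CV bias has exactly the nominal height
  b1 <- bias_state(list(toy_cv()), height = 0.7)
  b1 <- deposit_hill(b1, 0.3, 300)
  expect_equal(evaluate_bias(0.3, b1, 300)$V_k, 0.7, tolerance = 1e-3)
})

test_that("repeated hills at one point decay (well-tempering)", {
  b <- bias_state(list(toy_cv()), height = 1, bias_factor = 5)
  hs <- numeric(6)
  for (k in 1:6) {
    v0 <- evaluate_bias(0, b, 300)$V_k
    b <- deposit_hill(b, 0, 300)
    hs[k] <- evaluate_bias(0, b, 300)$V_k - v0
  }
  expect_true(all(diff(hs) < 0))
  # with bias_factor -> Inf heights stay nominal (standard metadynamics)
  b <- bias_state(list(toy_cv()), height = 1, bias_factor = Inf)
  b <- deposit_hill(b, 0, 300); b <- deposit_hill(b, 0, 300)
  expect_equal(evaluate_bias(0, b, 300)$V_k, 2, tolerance = 1e-3)
})

test_that("the combined bias is the softmin of per-CV biases", {
  kt <- kB * 300
  b <- bias_state(list(toy_cv(), toy_cv()), height = 1, bias_factor = 1e9)
  for (k in 1:40) b$grids[[1]]$V <- b$grids[[1]]$V + 0.5  # flat offset CV 1
  eb <- evaluate_bias(c(0, 0), b, 300)
  vk <- eb$V_k
  # direct log-sum-exp oracle
  oracle <- -kt * log(mean(exp(-vk / kt)))
  expect_equal(eb$V_PB, oracle, tolerance = 1e-10)
  # softmin bound: V_PB <= min(V_k) + kBT log(n)
  expect_lte(eb$V_PB, min(vk) + kt * log(2) + 1e-9)
  # per-CV biases stay non-negative and finite after deposits
  expect_true(all(vapply(b$grids, function(g) all(is.finite(g$V)) &&
                           all(g$V >= 0), logical(1))))
})

test_that("single-CV parallel bias reduces to well-tempered metadynamics", {
  kt <- kB * 300
  set.seed(5)
  pts <- runif(30, -1, 1)
  b_pb <- bias_state(list(toy_cv()), height = 0.4, bias_factor = 8)
  for (s in pts) b_pb <- deposit_hill(b_pb, s, 300)
  # hand-rolled well-tempered reference on the same grid
  g <- seq(-2, 2, by = 0.01)
  V <- numeric(length(g))
  for (s in pts) {
    vs <- approx(g, V, xout = s)$y
    h <- 0.4 * exp(-vs / ((8 - 1) * kt))
    V <- V + h * exp(-0.5 * ((g - s) / 0.1)^2)
  }
  expect_equal(b_pb$grids[[1]]$V, V, tolerance = 1e-6)
})

test_that("the final bias recomputation matches direct Gaussian summation", {
  set.seed(6)
  cvs <- list(toy_cv(0.1), toy_cv(0.15))
  b <- bias_state(cvs, height = 0.6, bias_factor = 10)
  hills <- data.frame()
  for (k in 1:25) {
    s <- runif(2, -1, 1)
    # record the actual deposited heights the way the engine logs them
    kt <- kB * 300
    vk <- vapply(1:2, function(c2)
      evaluate_bias(s, b, 300)$V_k[c2], numeric(1))
    pk <- exp(-vk / kt) / sum(exp(-vk / kt))
    h <- 0.6 * exp(-vk / (9 * kt)) * pk
    hills <- rbind(hills, data.frame(step = k, replica = 1,
                                     s1 = s[1], s2 = s[2],
                                     h1 = h[1], h2 = h[2]))
    b <- deposit_hill(b, s, 300, step = k)
  }
  frames <- cbind(runif(50, -1.5, 1.5), runif(50, -1.5, 1.5))
  via_grid <- recompute_final_bias(frames, bias = b, temperature = 300)
  via_hills <- recompute_final_bias(frames, hills = as.matrix(hills),
                                    cvs = cvs, temperature = 300)
  expect_equal(via_grid, via_hills, tolerance = 1e-3)
  # no hills: all frames get the same (zero) bias
  empty <- recompute_final_bias(frames, hills = matrix(0, 0, 6), cvs = cvs,
                                temperature = 300)
  expect_equal(empty, rep(0, 50))
  expect_error(recompute_final_bias(frames, temperature = 300), "missing hill")
})

test_that("engine hill logs reproduce the per-frame bias", {
  topo <- tiny_topology()
  cvs <- default_cvs(10)
  st <- minimize(replica_state(random_walk_coords(10, seed = 2)), topo)
  run <- run_replicas(st, topo, 4000,
                      hooks = list(hook_metadynamics(cvs, height = 0.8,
                                                     pace = 200)),
                      friction = 1, save_every = 100, seed = 3)
  expect_equal(nrow(run$hills), 20)
  cv_series <- cbind(run$frame_cv[[1]][, 1], run$frame_cv[[2]][, 1])
  final_bias <- recompute_final_bias(cv_series, hills = run$hills, cvs = cvs,
                                     temperature = 298)
  expect_true(all(is.finite(final_bias)))
  # the recomputed end-of-run bias at the last frame agrees with the grids
  grids <- run$bias_grids
  b <- bias_state(cvs)
  for (c2 in 1:2) {
    b$grids[[c2]]$V <- grids[[c2]]$V
    b$grids[[c2]]$dV <- grids[[c2]]$dV
  }
  via_grid <- recompute_final_bias(cv_series, bias = b, temperature = 298)
  expect_equal(final_bias, via_grid, tolerance = 0.02)
})

test_that("CV values and gradients are consistent", {
  set.seed(7)
  x <- random_walk_coords(8, seed = 7)
  cvs <- list(
    cv_spec("radius_of_gyration", sel_a = 0:7, grid_min = 0, grid_max = 3),
    cv_spec("inter_bead_distance", sel_a = 0L, sel_b = 7L, grid_min = 0,
            grid_max = 5),
    cv_spec("segment_com_distance", sel_a = 0:2, sel_b = 5:7, grid_min = 0,
            grid_max = 5))
  # values against direct geometry
  cm <- colMeans(x)
  expect_equal(cv_value(x, cvs[[1]]), sqrt(mean(rowSums(sweep(x, 2, cm)^2))))
  expect_equal(cv_value(x, cvs[[2]]), sqrt(sum((x[1, ] - x[8, ])^2)))
  expect_equal(cv_value(x, cvs[[3]]),
               sqrt(sum((colMeans(x[1:3, ]) - colMeans(x[6:8, ]))^2)))
})
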