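## The one-gene linear limits of the model have closed forms:
## x'(t) = V + u - lambda x  =>  x(t) = a/lambda + (x0 - a/lambda) e^(-lambda t)
## with a = V + u; these serve as independent oracles for the integrator.
oneGene <- function(V = 1, lambda = 1) {
  net <- signedNetwork(matrix(0, 1, 1))
  list(net = net,
       par = new("KineticParams", V = V, lambda = lambda,
                 K = matrix(0, 1, 1), m = 2))
}

test_that("stimulus profiles evaluate per the condition definitions", {
  expect_equal(stimulusValue(stimulusProfile("normal"), t = 3, r = 0.5), 0)
  expect_equal(stimulusValue(stimulusProfile("constant", Ec = 0.7), t = 0), 0.7)

  sp <- stimulusProfile("spike", Es = 2, ts = 1, dtSpike = 0.2)
  expect_equal(stimulusValue(sp, t = 1.1, r = 0.5), 1.0)  # Es * r in window
  expect_equal(stimulusValue(sp, t = 2.0, r = 0.5), 0)    # spike over
  expect_equal(stimulusValue(sp, t = 1.0, r = 1), 2)      # onset included
  expect_equal(stimulusValue(sp, t = 1.2, r = 1), 0)      # offset excluded
  expect_error(stimulusValue(sp, t = -1, r = 1), "t")
  expect_error(stimulusValue(sp, t = 1.1, r = 2), "r")
  expect_error(stimulusValue(stimulusProfile("constant"), t = 0),
               "unresolved")
  expect_error(stimulusProfile("rich"), "arg")
})

test_that("noise-free trajectories match the linear closed forms", {
  g <- oneGene(V = 1, lambda = 1)
  tr <- simulateTrajectory(g$net, g$par, stimulusProfile("normal"),
                           x0 = 0, grid = c(0, 5), step = 0.01)
  expect_equal(tr[1, 1], 0)
  expect_equal(tr[2, 1], 1 - exp(-5), tolerance = 0.01)  # Euler error O(step)

  ## pure degradation: V = 0 decays monotonically as x0 e^(-lambda t)
  g0 <- oneGene(V = 0, lambda = 0.5)
  tr <- simulateTrajectory(g0$net, g0$par, stimulusProfile("normal"),
                           x0 = 2, grid = c(0, 1, 2, 4), step = 0.01)
  expect_true(all(diff(tr[, 1]) < 0))
  expect_equal(unname(tr[, 1]), 2 * exp(-0.5 * c(0, 1, 2, 4)),
               tolerance = 0.01)

  ## constant stimulus shifts the fixed point to (V + Ec) / lambda
  g1 <- oneGene(V = 1, lambda = 1)
  tr <- simulateTrajectory(g1$net, g1$par, stimulusProfile("constant", Ec = 0.5),
                           x0 = 0, grid = c(0, 30), step = 0.01)
  expect_equal(tr[2, 1], 1.5, tolerance = 0.01)
})

test_that("a saturated repressor shuts transcription down (Hill limit)", {
  ## G1 (pinned high, no inputs, V = 0 so it only decays slowly) represses G2
  A <- matrix(0, 2, 2); A[1, 2] <- -1
  net <- signedNetwork(A)
  K <- matrix(0, 2, 2); K[1, 2] <- 0.1
  par <- new("KineticParams", V = c(0, 1), lambda = c(0.001, 1), K = K, m = 2)
  ## x_rep = 5 >> K = 0.1: transcription term < 0.01 V, G2 decays toward 0
  tr <- simulateTrajectory(net, par, stimulusProfile("normal"),
                           x0 = c(5, 1), grid = c(0, 2, 5), step = 0.01)
  expect_lt(tr[3, 2], 1 * exp(-0.99 * 5) + 0.01 / 1 + 0.01)
  expect_true(all(diff(tr[, 2]) < 0))
})

test_that("trajectory argument errors are raised", {
  g <- oneGene()
  sp <- stimulusProfile("normal")
  expect_error(simulateTrajectory(g$net, g$par, sp, x0 = -1, grid = 0:1), "x0")
  expect_error(simulateTrajectory(g$net, g$par, sp, x0 = 0, grid = 0:1,
                                  step = 0), "step")
  expect_error(simulateTrajectory(g$net, g$par, sp, x0 = 0,
                                  grid = c(0, 0.015), step = 0.01),
               "multiples")
})

test_that("ensemble generation follows the T x E design", {
  net <- erdosRenyiNetwork(8, 0.2, seed = 2)
  grid <- c(0, 0.5, 1)
  ens <- generateEnsemble(net, stimulusProfile("normal"), grid,
                          E = 3, S = 5, seed = 9)
  expect_length(ens, length(grid) * 3)
  d <- ens[["e2_t3"]]
  expect_s4_class(d, "ExpressionDataset")
  expect_equal(dim(exprValues(d)), c(5, 8))
  expect_equal(d@time, 1)
  expect_equal(d@replicate, 2L)
  expect_true(all(exprValues(d) >= 0))
  expect_true(all(is.finite(exprValues(d))))

  ## determinism: same seed gives bitwise-identical values
  ens2 <- generateEnsemble(net, stimulusProfile("normal"), grid,
                           E = 3, S = 5, seed = 9)
  expect_identical(exprValues(ens[["e3_t2"]]), exprValues(ens2[["e3_t2"]]))

  ## t = 0 datasets are the (noisy) random initial conditions
  ens0 <- generateEnsemble(net, stimulusProfile("normal"), grid = 0,
                           E = 1, S = 3, seed = 4)
  expect_length(ens0, 1)
  expect_equal(dim(exprValues(ens0[[1]])), c(3, 8))

  expect_error(generateEnsemble(net, stimulusProfile("normal"), grid,
                                E = 1, S = 1, seed = 1), "S")
  expect_error(generateEnsemble(net, stimulusProfile("normal"), grid,
                                E = 0, S = 5, seed = 1), "E")
})

test_that("trajectory jitter and noise are the sole inter-sample variance", {
  net <- erdosRenyiNetwork(6, 0.25, seed = 3)
  params <- sampleKineticParams(net, seed = 1)
  ens <- generateEnsemble(net, stimulusProfile("normal"), grid = c(0, 30),
                          E = 1, S = 4, seed = 2, params = params,
                          sigmaDyn = 0, jitterSd = 0, measSd = 0)
  ## without jitter or noise the only variance source is x(0), and with
  ## shared kinetics that spread has contracted by t = 30 to a sliver
  ## of the expression scale (slowest genes relax on tau ~ 4)
  scale <- params@V / params@lambda  # per-gene dynamic range
  X <- exprValues(ens[[2]])
  spread <- apply(X, 2, function(col) diff(range(col)))
  expect_true(all(spread < 0.02 * scale))
  ## at t = 0 the spread is the full initial heterogeneity
  X0 <- exprValues(ens[[1]])
  spread0 <- apply(X0, 2, function(col) diff(range(col)))
  expect_gt(max(spread0 / scale), 0.2)
})

test_that("the population approaches steady state by the late grid times", {
  net <- erdosRenyiNetwork(30, seed = 6)
  params <- sampleKineticParams(net, seed = 6)
  x0 <- 0.05 * params@V / params@lambda
  tr <- simulateTrajectory(net, params, stimulusProfile("normal"), x0 = x0,
                           grid = c(0, 30, 50), step = 0.01, noise = 0)
  ## per gene: relative change < 2%, except genes decaying to ~0 where
  ## the relative measure is ill-defined (judged against the typical scale)
  scale <- median(params@V / params@lambda)
  ok <- abs(tr[3, ] - tr[2, ]) < pmax(0.02 * tr[2, ], 0.001 * scale)
  expect_true(all(ok))
})

test_that("constant stimulation raises steady-state expression", {
  ## comparison principle for the monotone (all-activator) system:
  ## adding a positive input raises every fixed point elementwise
  net <- erdosRenyiNetwork(20, activatorFraction = 1, seed = 8)
  params <- sampleKineticParams(net, seed = 8)
  x0 <- 0.05 * params@V / params@lambda
  trI <- simulateTrajectory(net, params, stimulusProfile("normal"),
                            x0 = x0, grid = c(0, 50), noise = 0)
  trII <- simulateTrajectory(net, params,
                             stimulusProfile("constant", Ec = 0.5),
                             x0 = x0, grid = c(0, 50), noise = 0)
  expect_true(all(trII[2, ] >= trI[2, ] - 1e-9))

  ## with repressors present the guarantee is population-level, not
  ## per-gene: the average expression still rises
  net2 <- erdosRenyiNetwork(20, seed = 9)
  params2 <- sampleKineticParams(net2, seed = 9)
  x02 <- 0.05 * params2@V / params2@lambda
  mI <- simulateTrajectory(net2, params2, stimulusProfile("normal"),
                           x0 = x02, grid = c(0, 50), noise = 0)[2, ]
  mII <- simulateTrajectory(net2, params2,
                            stimulusProfile("constant", Ec = 0.5),
                            x0 = x02, grid = c(0, 50), noise = 0)[2, ]
  expect_gt(mean(mII), mean(mI))
})

test_that("expression dataset TSV round trip preserves values", {
  path <- withr::local_tempfile()
  net <- erdosRenyiNetwork(4, 0.3, seed = 1)
  ens <- generateEnsemble(net, stimulusProfile("normal"), grid = 1,
                          E = 1, S = 3, seed = 2)
  writeExpressionDataset(ens[[1]], path)
  back <- readExpressionDataset(path, geneIds = geneIds(net))
  expect_equal(exprValues(back), exprValues(ens[[1]]), tolerance = 1e-9)

  expect_error(readExpressionDataset(path, geneIds = c("a", "b", "c", "d")),
               "gene ids")
  empty <- withr::local_tempfile()
  file.create(empty)
  expect_error(readExpressionDataset(empty), "empty")
  bad <- withr::local_tempfile()
  writeLines(c("G1\tG2", "1\tx"), bad)
  expect_error(readExpressionDataset(bad))
})
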