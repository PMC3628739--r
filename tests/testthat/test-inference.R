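test_that("null MI threshold is a calibrated quantile", {
  X <- nullData(40, 6, seed = 1)
  sig <- nullMIThreshold(X, alpha = 0.5, P = 100, seed = 2)
  expect_equal(miThreshold(sig), median(sig@nullSamples))

  ## alpha decreasing => threshold non-decreasing
  thr <- vapply(c(0.5, 0.2, 0.05, 0.01), function(a)
    miThreshold(nullMIThreshold(X, alpha = a, P = 100, seed = 2)), 0)
  expect_true(all(diff(thr) >= 0))

  expect_error(nullMIThreshold(X, P = 50), "P")
  expect_error(nullMIThreshold(X, alpha = 0), "alpha")
})

test_that("thresholding on independent data is alpha-calibrated", {
  ## expected surviving pairs <= alpha * n(n-1)/2 within 3 SE
  n <- 8; S <- 50; alpha <- 0.05; nsim <- 80
  surv <- vapply(seq_len(nsim), function(i) {
    X <- nullData(S, n, seed = 100 + i)
    sig <- nullMIThreshold(X, alpha = alpha, P = 100, seed = i)
    v <- miValues(miMatrix(X))
    sum(v[upper.tri(v)] > miThreshold(sig))
  }, 0)
  npairs <- n * (n - 1) / 2
  se <- sd(surv) / sqrt(nsim)
  expect_lte(mean(surv), alpha * npairs + 3 * se)
})

test_that("C3NET keeps each gene's maximal significant partner", {
  ## worked example: all pairs significant; G1 is argmax for G2 and G3
  M <- makeMI(rbind(c(0, 0.9, 0.5),
                    c(0.9, 0, 0.4),
                    c(0.5, 0.4, 0)))
  net <- inferC3NET(M, makeSig(0.1))
  expect_equal(edgeCount(net), 2)
  A <- adjacencyMatrix(net)
  expect_equal(A["G1", "G2"], 1)
  expect_equal(A["G1", "G3"], 1)
  expect_equal(A["G2", "G3"], 0)

  ## nothing significant -> empty network
  expect_equal(edgeCount(inferC3NET(M, makeSig(0.95))), 0)

  ## at most n edges, symmetric binary output, for arbitrary inputs
  set.seed(3)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    v <- matrix(runif(n * n), n, n); v <- (v + t(v)) / 2
    net <- inferC3NET(makeMI(v), makeSig(runif(1, 0, 0.6)))
    A <- adjacencyMatrix(net)
    expect_lte(edgeCount(net), n)
    expect_identical(unname(A), unname(t(A)))
    expect_true(all(A %in% c(0, 1)))
  }
})

test_that("CLR standardizes rows and joins directions in quadrature", {
  ## hand-computed: row1 background mu = 0.5, sigma = 0.4 (population),
  ## so w_12 = sqrt(2) * (0.9 - 0.5) / 0.4 = sqrt(2) > 1
  M <- makeMI(rbind(c(0, 0.9, 0.1),
                    c(0.9, 0, 0.1),
                    c(0.1, 0.1, 0)))
  net <- inferCLR(M, zThreshold = 1)
  expect_equal(edgeCount(net), 1)
  expect_equal(adjacencyMatrix(net)["G1", "G2"], 1)

  ## constant MI background: no local contrast anywhere -> empty
  v <- matrix(0.4, 5, 5)
  expect_equal(edgeCount(suppressMessages(inferCLR(makeMI(v)))), 0)

  expect_error(inferCLR(makeMI(matrix(0, 2, 2))), "3 genes")

  set.seed(4)
  v <- matrix(runif(64), 8, 8); v <- (v + t(v)) / 2
  A <- adjacencyMatrix(inferCLR(makeMI(v)))
  expect_identical(unname(A), unname(t(A)))
})

test_that("MRNET penalizes redundant candidates", {
  ## chain-shaped MI: the X-Z score is dominated by the redundancy with
  ## the already-selected stronger neighbour and the edge is excluded
  M <- makeMI(rbind(c(0, 0.8, 0.35),
                    c(0.8, 0, 0.7),
                    c(0.35, 0.7, 0)))
  net <- inferMRNET(M, makeSig(0.2))
  A <- adjacencyMatrix(net)
  expect_equal(A["G1", "G2"], 1)
  expect_equal(A["G2", "G3"], 1)
  ## greedy from G1: selects G2 (0.8); score of G3 then 0.35 - 0.7 < 0;
  ## from G3: selects G2 (0.7); score of G1 then 0.35 - 0.8 < 0
  expect_equal(A["G1", "G3"], 0)

  ## two genes: edge iff M12 above threshold (no redundancy term)
  M2 <- makeMI(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(edgeCount(inferMRNET(M2, makeSig(0.3))), 1)
  expect_equal(edgeCount(inferMRNET(M2, makeSig(0.6))), 0)
})

test_that("ARACNE removes the weakest edge of significant triangles", {
  ## Markov-chain-shaped matrix: X-Z is the indirect pair
  M <- makeMI(rbind(c(0, 0.8, 0.3),
                    c(0.8, 0, 0.7),
                    c(0.3, 0.7, 0)))
  net <- inferARACNE(M, makeSig(0.1), eps = 0)
  A <- adjacencyMatrix(net)
  expect_equal(A["G1", "G2"], 1)
  expect_equal(A["G2", "G3"], 1)
  expect_equal(A["G1", "G3"], 0)

  ## equal-weight triangle: strict inequality required, nothing removed
  v <- matrix(0.5, 3, 3)
  expect_equal(edgeCount(inferARACNE(makeMI(v), makeSig(0.1))), 3)

  ## two genes: DPI is a no-op
  M2 <- makeMI(matrix(c(0, 0.6, 0.6, 0), 2, 2))
  expect_equal(edgeCount(inferARACNE(M2, makeSig(0.1))), 1)

  ## output is always a subset of the thresholded network
  set.seed(5)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    v <- matrix(runif(n * n), n, n); v <- (v + t(v)) / 2
    thr <- runif(1, 0, 0.5)
    pre <- v > thr; diag(pre) <- FALSE
    A <- adjacencyMatrix(inferARACNE(makeMI(v), makeSig(thr)))
    expect_true(all(A[pre == 0] == 0))
  }
  expect_error(inferARACNE(M, makeSig(0.1), eps = -1), "eps")
})

test_that("ARACNE and MRNET prune the indirect edge of simulated chains", {
  ## data simulated from X -> Y -> Z; the X-Z link is information-
  ## theoretically indirect and should be excluded in >= 90% of runs,
  ## while plain thresholding keeps it in >= 90%
  nsim <- 30
  pre <- aracne <- mrnet <- 0
  for (i in seq_len(nsim)) {
    X <- chainData(200, rho = 0.95, seed = 1000 + i)
    sig <- nullMIThreshold(X, P = 100, seed = i)
    M <- miMatrix(X)
    pre <- pre + (miValues(M)["G1", "G3"] > miThreshold(sig))
    aracne <- aracne + (adjacencyMatrix(inferARACNE(M, sig))["G1", "G3"] == 0)
    mrnet <- mrnet + (adjacencyMatrix(inferMRNET(M, sig))["G1", "G3"] == 0)
  }
  expect_gte(pre / nsim, 0.9)
  expect_gte(aracne / nsim, 0.9)
  expect_gte(mrnet / nsim, 0.9)
})

test_that("BC3NET aggregates bootstrap C3NET networks", {
  ## B = 1 reduces to the single bag's selection (degenerate bagging)
  X <- chainData(80, rho = 0.9, seed = 3)
  b1 <- inferBC3NET(X, B = 1, seed = 5, P = 100)
  expect_s4_class(b1, "InferredNetwork")
  expect_true(all(adjacencyMatrix(b1) %in% c(0, 1)))

  ## strongly coupled pair (shared latent driver) is retained
  kept <- 0
  for (i in 1:10) {
    set.seed(i)
    d <- rnorm(100)
    X <- cbind(G1 = d + rnorm(100, 0, 0.3), G2 = d + rnorm(100, 0, 0.3),
               G3 = rnorm(100), G4 = rnorm(100), G5 = rnorm(100))
    kept <- kept + adjacencyMatrix(inferBC3NET(X, B = 30, seed = i,
                                               P = 100))["G1", "G2"]
  }
  expect_gte(kept / 10, 0.95)

  ## determinism and errors
  X <- nullData(40, 5, seed = 6)
  expect_identical(adjacencyMatrix(inferBC3NET(X, B = 10, seed = 7, P = 100)),
                   adjacencyMatrix(inferBC3NET(X, B = 10, seed = 7, P = 100)))
  expect_error(inferBC3NET(X, B = 0), "B")

  ## BC3NET edges are a subset of the union of its bags' selections:
  ## every ensemble edge must have been selected at least once
  bn <- inferBC3NET(chainData(60, seed = 8), B = 20, seed = 8, P = 100)
  expect_true(all(adjacencyMatrix(bn) %in% c(0, 1)))
})

test_that("inferred networks serialize through the edge-list format", {
  M <- makeMI(rbind(c(0, 0.9, 0.1),
                    c(0.9, 0, 0.1),
                    c(0.1, 0.1, 0)))
  net <- inferC3NET(M, makeSig(0.05))
  path <- withr::local_tempfile()
  writeEdgeList(net, path)
  back <- readEdgeList(path, geneIds = geneIds(net))
  sym <- 1 * ((abs(adjacencyMatrix(back)) + t(abs(adjacencyMatrix(back)))) > 0)
  expect_equal(unname(sym), unname(adjacencyMatrix(net)))
})
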