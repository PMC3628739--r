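test_that("confusion counts match hand-worked and brute-force oracles", {
  ## 4-gene worked case: truth {12, 23, 34}, estimate {12, 24}
  truth <- makeSigned(4, list(c(1, 2, 1), c(2, 3, -1), c(3, 4, 1)))
  est <- makeInferred(4, list(c(1, 2), c(2, 4)))
  cc <- confusionCounts(est, truth)
  expect_equal(cc, list(TP = 1L, FP = 1L, FN = 2L))

  ## perfect reconstruction and empty prediction
  symTruth <- makeInferred(4, list(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(confusionCounts(symTruth, truth), list(TP = 3L, FP = 0L, FN = 0L))
  expect_equal(confusionCounts(makeInferred(4, list()), truth),
               list(TP = 0L, FP = 0L, FN = 3L))

  expect_error(confusionCounts(makeInferred(3, list()), truth), "gene ids")

  ## brute-force double-loop oracle over random network pairs
  bruteForce <- function(Ae, At) {
    n <- nrow(Ae); TP <- FP <- FN <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      t_ <- At[i, j] != 0 || At[j, i] != 0
      if (Ae[i, j] == 1 && t_) TP <- TP + 1
      if (Ae[i, j] == 1 && !t_) FP <- FP + 1
      if (Ae[i, j] == 0 && t_) FN <- FN + 1
    }
    list(TP = TP / 2, FP = FP / 2, FN = FN / 2)  # ordered counts halved
  }
  set.seed(1)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    truth <- erdosRenyiNetwork(n, runif(1, 0, 0.5),
                               activatorFraction = runif(1), seed = i)
    Ae <- matrix(rbinom(n * n, 1, 0.3), n, n)
    Ae <- 1 * ((Ae + t(Ae)) > 0); diag(Ae) <- 0
    est <- new("InferredNetwork", geneIds = geneIds(truth), adjacency = Ae,
               method = "random", params = list())
    cc <- confusionCounts(est, truth)
    bf <- bruteForce(Ae, adjacencyMatrix(truth))
    expect_equal(cc$TP, bf$TP)
    expect_equal(cc$FP, bf$FP)
    expect_equal(cc$FN, bf$FN)
    ## invariants tying the counts to the edge totals
    expect_equal(cc$TP + cc$FP, sum(Ae) / 2)
  }
})

test_that("precision, recall and F follow the defining formulas", {
  expect_equal(precisionRecall(list(TP = 5, FP = 0, FN = 0)),
               c(precision = 1, recall = 1))
  expect_equal(precisionRecall(list(TP = 0, FP = 0, FN = 3)),
               c(precision = 0, recall = 0))
  expect_equal(precisionRecall(list(TP = 2, FP = 1, FN = 2)),
               c(precision = 2 / 3, recall = 1 / 2))

  expect_equal(fScore(1, 1), 1)
  expect_equal(fScore(0, 0), 0)
  expect_equal(fScore(2 / 3, 1 / 2), 4 / 7)
  expect_error(fScore(1.2, 0.5), "lie in")

  ## symmetry and the min-side bound F <= 2 min(P, R)
  set.seed(2)
  for (i in 1:50) {
    P <- runif(1); R <- runif(1)
    expect_equal(fScore(P, R), fScore(R, P))
    expect_lte(fScore(P, R), 2 * min(P, R) + 1e-12)
    expect_gte(fScore(P, R), 0)
    expect_lte(fScore(P, R), 1)
  }
})

test_that("F = 1 exactly for perfect reconstruction and only then", {
  set.seed(3)
  for (i in 1:20) {
    truth <- erdosRenyiNetwork(8, 0.25, seed = i)
    At <- adjacencyMatrix(truth)
    sym <- 1 * ((abs(At) + t(abs(At))) > 0)
    if (sum(sym) == 0) next
    perfect <- new("InferredNetwork", geneIds = geneIds(truth),
                   adjacency = sym, method = "oracle", params = list())
    expect_equal(scoreNetwork(perfect, truth)$fscore, 1)
    ## flip one pair: F must drop strictly below 1
    ij <- which(upper.tri(sym), arr.ind = TRUE)[1, ]
    mod <- sym
    mod[ij[1], ij[2]] <- mod[ij[2], ij[1]] <- 1 - mod[ij[1], ij[2]]
    imperfect <- new("InferredNetwork", geneIds = geneIds(truth),
                     adjacency = mod, method = "oracle", params = list())
    expect_lt(scoreNetwork(imperfect, truth)$fscore, 1)
  }
})

test_that("F-score series aggregate medians and steady-state ratios", {
  ## constant scores: every ratio is 1
  df <- expand.grid(timeIndex = 1:3, replicate = 1:5)
  df$time <- c(0, 1, 50)[df$timeIndex]
  df$fscore <- 0.3
  fs <- summarizeFScores(df)
  expect_equal(fscoreSummary(fs)$ratio, rep(1, 3))

  ## worked ratio: median 0.28 over median 0.20 = 1.4
  df2 <- data.frame(timeIndex = rep(1:2, each = 3), time = rep(c(1, 50), each = 3),
                    replicate = rep(1:3, 2),
                    fscore = c(0.27, 0.28, 0.30, 0.1, 0.2, 0.3))
  s <- fscoreSummary(summarizeFScores(df2))
  expect_equal(s$median, c(0.28, 0.20))
  expect_equal(s$ratio[1], 1.4)

  ## odd replicate count: median is the middle order statistic exactly
  df3 <- data.frame(timeIndex = 1, time = 0, replicate = 1:5,
                    fscore = c(0.9, 0.1, 0.5, 0.3, 0.7))
  expect_equal(fscoreSummary(summarizeFScores(df3, steadyIndex = 1))$median, 0.5)

  ## zero steady-state median: ratio undefined (NA), not 0
  df4 <- data.frame(timeIndex = rep(1:2, each = 3), time = rep(c(1, 50), each = 3),
                    replicate = rep(1:3, 2), fscore = c(0.2, 0.3, 0.4, 0, 0, 0))
  expect_true(all(is.na(fscoreSummary(summarizeFScores(df4))$ratio)))

  expect_error(summarizeFScores(df4[0, ]), "nonempty")
  expect_error(summarizeFScores(data.frame(a = 1)), "columns")
})
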