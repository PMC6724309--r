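test_that("confidence interval behaves in its analytic limits", {
  b <- buildLaplacianBlocks(toyNetwork())
  beta <- c(G1 = 1, G2 = 1)

  tiny <- confidenceInterval(b, beta, c(G1 = 1e-9, G2 = 1e-9))
  expect_equal(unname(tiny), c(4, 4), tolerance = 1e-6)  # collapses to score

  null <- confidenceInterval(b, c(G1 = 0, G2 = 0), c(G1 = 0.2, G2 = 0.2))
  expect_equal(unname(null), c(0, 0))                    # fails by convention

  ci1 <- confidenceInterval(b, beta, c(G1 = 0.1, G2 = 0.1))
  ci2 <- confidenceInterval(b, beta, c(G1 = 0.2, G2 = 0.2))
  expect_equal(ci2[2] - ci2[1], 2 * (ci1[2] - ci1[1]), tolerance = 1e-9)

  expect_error(confidenceInterval(b, beta, c(G1 = -0.1, G2 = 0.1)),
               "positive")
  # NA standard errors contribute no variance
  ciNA <- confidenceInterval(b, beta, c(G1 = 0.1, G2 = NA))
  expect_lt(ciNA[2] - ciNA[1], ci1[2] - ci1[1])
})

test_that("delta-method SD tracks a parametric bootstrap at moderate noise", {
  for (s in c(2, 5)) {
    inst <- randomInstance(s)
    # planted-scale beta with se/|beta| well below 0.3
    beta <- setNames(sign(inst$beta) + 0.2 * sign(inst$beta), names(inst$beta))
    beta[beta == 0] <- 1.2
    se <- setNames(rep(0.25, length(beta)), names(beta))
    ci <- confidenceInterval(inst$blocks, beta, se)
    sdDelta <- (ci[2] - ci[1]) / (2 * qnorm(0.975))
    boot <- withr::with_seed(1000 + s, {
      replicate(10000, {
        bstar <- beta + rnorm(length(beta), 0, se)
        computeNpa(inst$blocks, solveDifferentialValues(inst$blocks, bstar))
      })
    })
    expect_lt(abs(sdDelta - sd(boot)) / sd(boot), 0.15)
  }
})

test_that("transcript-layer (O) permutation has the stated p-value mechanics", {
  inst <- randomInstance(11)
  # a planted coherent beta (heterogeneous signs) sits far above every
  # gene-relabeled score
  noiseless <- synthConfig(nBackbone = 6, density = 0.6, negProb = 0.5,
                           footprintMin = 6, footprintMax = 6,
                           footprintFraction = 1, amplitude = 2,
                           noiseSd = 1e-4, nBackground = 0, balanced = TRUE,
                           seed = 21)
  net <- generateNetwork(noiseless)
  ctr <- generateContrast(net, noiseless)
  pn <- permutationO(net, ctr, nPerm = 200, seed = 7)
  expect_equal(pn@pValue, 1 / 201)
  expect_equal(pn@quantile95, unname(quantile(pn@nullScores, 0.95)))

  # deterministic under a fixed seed
  pn2 <- permutationO(net, ctr, nPerm = 200, seed = 7)
  expect_identical(pn@nullScores, pn2@nullScores)

  expect_error(permutationNull(inst$blocks, inst$beta, "O", nPerm = 0),
               "positive")
  few <- netFromEdges(edges("a", 1, "b"),
                      tedges("a", 1, "G1", "b", 1, "G2"))
  bf <- buildLaplacianBlocks(few)
  expect_error(suppressWarnings(
    permutationNull(bf, c(G1 = 1, G2 = 1), "O", nPerm = 10)), "3 genes")
})

test_that("backbone (K) permutation respects graph symmetry", {
  # complete all-positive backbone: every relabeling fixes the edge set
  net <- netFromEdges(edges("a", 1, "b", "a", 1, "c", "b", 1, "c"),
                      tedges("a", 1, "G1", "b", 1, "G2", "c", 1, "G3"))
  b <- buildLaplacianBlocks(net)
  beta <- c(G1 = 1, G2 = -0.5, G3 = 0.2)
  pn <- suppressWarnings(permutationNull(b, beta, "K", nPerm = 50, seed = 3))
  expect_equal(pn@pValue, 1)
  expect_equal(max(pn@nullScores) - min(pn@nullScores), 0, tolerance = 1e-12)

  # 2-node backbone: only identity and swap exist
  two <- buildLaplacianBlocks(toyNetwork())
  pn2 <- suppressWarnings(permutationNull(two, c(G1 = 1, G2 = -1), "K",
                                          nPerm = 60, seed = 3))
  expect_lte(length(unique(round(pn2@nullScores, 12))), 2)

  pn3 <- suppressWarnings(permutationNull(two, c(G1 = 1, G2 = -1), "K",
                                          nPerm = 60, seed = 3))
  expect_identical(pn2@nullScores, pn3@nullScores)
})

test_that("permutation tests are invariant to input row order", {
  be <- edges("a", 1, "b", "b", -1, "c")
  te <- tedges("a", 1, "G1", "b", -1, "G2", "c", 1, "G3")
  net1 <- netFromEdges(be, te)
  net2 <- netFromEdges(be[2:1, ], te[c(3, 1, 2), ])
  ctr <- contrastFrom(c(G1 = 0.4, G2 = -1, G3 = 0.7))
  for (kind in c("O", "K")) {
    p1 <- suppressWarnings(permutationNull(buildLaplacianBlocks(net1),
      matchContrast(net1, ctr, 1)$beta, kind, nPerm = 80, seed = 5))
    p2 <- suppressWarnings(permutationNull(buildLaplacianBlocks(net2),
      matchContrast(net2, ctr, 1)$beta, kind, nPerm = 80, seed = 5))
    expect_identical(p1@nullScores, p2@nullScores)
    expect_identical(p1@pValue, p2@pValue)
  }
})

test_that("test power grows with the planted amplitude", {
  # a balanced mixed-sign backbone: the coherent state has a heterogeneous
  # +/- pattern, which both reshuffling schemes are sensitive to (against a
  # constant-f perturbation the K statistic is blind by construction)
  mk <- function(a) synthConfig(nBackbone = 10, density = 0.4, negProb = 0.5,
                                footprintMin = 5, footprintMax = 5,
                                footprintFraction = 1, amplitude = a,
                                noiseSd = 0.4, nBackground = 0,
                                balanced = TRUE, seed = 99)
  net <- generateNetwork(mk(0))
  blocks <- buildLaplacianBlocks(net)
  amps <- c(0, 0.4, 1.2)
  reps <- 40
  power <- sapply(amps, function(a) {
    hits <- sapply(seq_len(reps), function(i) {
      ctr <- generateContrast(net, mk(a), seed = 7000 + round(100 * a) + i)
      beta <- ctr@beta[blocks@geneOrder]
      c(O = permutationNull(blocks, beta, "O", 150, seed = i)@pValue < 0.05,
        K = permutationNull(blocks, beta, "K", 150, seed = i)@pValue < 0.05)
    })
    rowMeans(hits)
  })
  for (k in 1:2) {
    expect_lte(power[k, 1], power[k, 2] + 0.1)
    expect_lte(power[k, 2], power[k, 3] + 0.1)
    expect_gte(power[k, 3], 0.8)
  }
})

test_that("significance labels encode the three statistics", {
  allPass <- resultFrom("n", "c", c(a = 1, b = 1))
  allPass@pO <- 0.01; allPass@pK <- 0.02
  expect_equal(significanceLabel(allPass), "*O*K")
  expect_true(allPass@significant && allPass@ciFlag)

  marginal <- resultFrom("n", "c", c(a = 1, b = 1))
  marginal@pO <- 0.07; marginal@pK <- 0.2
  expect_equal(significanceLabel(marginal), ".O")

  nullCase <- resultFrom("n", "c", c(a = 0, b = 0), score = 0,
                         significant = FALSE)
  expect_false(nullCase@significant)
})
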