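writeContrastFile <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("standard errors derive from the t-statistic as |beta/t|", {
  path <- writeContrastFile(c("nodeLabel\tfoldChange\tt",
                              "G1\t1.0\t4.0",
                              "G2\t-2.0\t-8.0"))
  cc <- loadContrasts(path)[[1]]
  expect_equal(cc@beta[["G1"]], 1.0)
  expect_equal(cc@se[["G1"]], 0.25)
  expect_equal(cc@se[["G2"]], 0.25)  # absolute value
})

test_that("duplicate genes error by default and average under the flag", {
  path <- writeContrastFile(c("nodeLabel\tfoldChange\tt",
                              "G1\t1.0\t4.0", "G1\t3.0\t4.0"))
  expect_error(loadContrasts(path), "duplicate")
  cc <- loadContrasts(path, aggregateDuplicates = "mean")[[1]]
  expect_equal(cc@beta[["G1"]], 2.0)
  expect_equal(cc@se[["G1"]], sqrt(mean(c(0.25, 0.75)^2)))  # rms
})

test_that("genes without a usable statistic are handled per the zero rule", {
  ok <- writeContrastFile(c("nodeLabel\tfoldChange\tt",
                            "G1\t0\t0", "G2\t1\t2"))
  cc <- loadContrasts(ok)[[1]]
  expect_true(is.na(cc@se[["G1"]]))       # kept, excluded from variance
  expect_equal(cc@beta[["G1"]], 0)
  bad <- writeContrastFile(c("nodeLabel\tfoldChange\tt", "G1\t1.5\t0"))
  expect_error(loadContrasts(bad), "t-statistic")
})

test_that("long-format and csv tables load into multiple contrasts", {
  path <- writeContrastFile(c("contrast,nodeLabel,foldChange,t",
                              "trt1,G1,1,4", "trt1,G2,2,4",
                              "trt2,G1,-1,-4"), ext = ".csv")
  ccs <- loadContrasts(path)
  expect_named(ccs, c("trt1", "trt2"))
  expect_equal(ccs$trt2@beta[["G1"]], -1)
  # round-trip through the writer
  out <- tempfile(fileext = ".tsv")
  writeContrasts(ccs, out)
  back <- loadContrasts(out)
  expect_equal(back$trt1@beta, ccs$trt1@beta)
  expect_equal(back$trt1@se, ccs$trt1@se)
})

test_that("matching keeps measured genes and re-runs the filters", {
  net <- netFromEdges(edges("a", 1, "b"),
                      tedges("a", 1, "G1", "a", 1, "G2",
                             "b", 1, "H1", "b", 1, "H2"))
  full <- contrastFrom(c(G1 = 1, G2 = 1, H1 = 1, H2 = 1))
  m <- matchContrast(net, full, minDownstream = 2)
  expect_setequal(names(m$beta), c("G1", "G2", "H1", "H2"))
  expect_equal(names(m$beta), sort(names(m$beta)))  # lexicographic order

  # dropping one of b's genes pushes b's footprint below the minimum, so the
  # re-run prune strips b's remaining footprint; a stays anchored but b
  # loses its own anchor and with it its scorable status depends on a:
  # a -> b keeps b (ancestor a is anchored) only if b still has an anchored
  # descendant, which it does not, so b is dropped and the backbone empties
  partial <- contrastFrom(c(G1 = 1, G2 = 1, H1 = 1))
  m2 <- matchContrast(net, partial, minDownstream = 2)
  expect_setequal(names(m2$beta), c("G1", "G2"))
  expect_setequal(backboneNodes(m2$network), "a")

  # fewer than half the transcript-layer genes measured draws a warning
  sparse <- contrastFrom(c(G1 = 1))
  expect_warning(matchContrast(net, sparse, minDownstream = 1), "matched")

  # no gene measured at all is an error
  none <- contrastFrom(c(X1 = 1, X2 = 1))
  expect_error(suppressWarnings(matchContrast(net, none)), "no transcript")

  # case-insensitive matching folds symbols
  lower <- contrastFrom(c(g1 = 1, g2 = 1, h1 = 1, h2 = 1))
  m3 <- matchContrast(net, lower, minDownstream = 2, caseInsensitive = TRUE)
  expect_setequal(names(m3$beta), c("G1", "G2", "H1", "H2"))
})

test_that("the analytic solve reproduces the 2-node system and is linear", {
  b <- buildLaplacianBlocks(toyNetwork())
  expect_equal(solveDifferentialValues(b, c(G1 = 0, G2 = 0)),
               setNames(c(0, 0), c("a", "b")), ignore_attr = TRUE)
  f <- solveDifferentialValues(b, c(G1 = 1, G2 = 1))
  expect_equal(unname(f), c(1, 1))
  beta <- c(G1 = 0.3, G2 = -1.2)
  expect_equal(solveDifferentialValues(b, 3 * beta),
               3 * solveDifferentialValues(b, beta))
  expect_error(solveDifferentialValues(b, c(G1 = 1)), "length")
})

test_that("the NPA is the edge-averaged coherence and scales quadratically", {
  b <- buildLaplacianBlocks(toyNetwork())
  expect_equal(computeNpa(b, c(a = 0, b = 0)), 0)
  expect_equal(computeNpa(b, c(a = 1, b = 1)), 4)
  f <- c(a = 0.7, b = -1.3)
  expect_equal(computeNpa(b, 2 * f), 4 * computeNpa(b, f))
})

test_that("contributions split the score additively", {
  b <- buildLaplacianBlocks(toyNetwork())
  expect_equal(nodeContributions(b, c(a = 1, b = 1)),
               c(a = 2, b = 2))
  for (s in 1:10) {
    inst <- randomInstance(s)
    f <- solveDifferentialValues(inst$blocks, inst$beta)
    contrib <- nodeContributions(inst$blocks, f)
    expect_equal(sum(contrib), computeNpa(inst$blocks, f), tolerance = 1e-10)
  }
})

test_that("a symmetric star with identical footprints has equal leaf shares", {
  net <- netFromEdges(edges("hub", 1, "l1", "hub", 1, "l2", "hub", 1, "l3"),
                      tedges("hub", 1, "GH",
                             "l1", 1, "G1", "l2", 1, "G2", "l3", 1, "G3"))
  b <- buildLaplacianBlocks(net)
  beta <- c(GH = 1, G1 = 1, G2 = 1, G3 = 1)
  contrib <- nodeContributions(b, solveDifferentialValues(b, beta))
  expect_equal(contrib[["l1"]], contrib[["l2"]])
  expect_equal(contrib[["l2"]], contrib[["l3"]])
})

test_that("differential values agree with the numerical minimizer", {
  for (s in 1:15) {
    inst <- randomInstance(s)
    f <- solveDifferentialValues(inst$blocks, inst$beta)
    fo <- oracleSolve(inst$net, inst$beta)
    expect_equal(unname(f), unname(fo[inst$blocks@nodeOrder]),
                 tolerance = 1e-6)
  }
})
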