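test_that("the TSV dialect reads back a hand-written network", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("# toy network", "source\tsign\ttarget\tlayer",
               "a\t1\tb\tfunctional",
               "a\t1\tG1\ttranscript",
               "b\t-1\tG2\ttranscript"), tsv)
  net <- readNetwork(tsv, name = "toy")
  expect_s4_class(net, "TwoLayerNetwork")
  expect_setequal(backboneNodes(net), c("a", "b"))
  expect_setequal(geneNodes(net), c("G1", "G2"))
  expect_equal(nrow(backboneEdges(net)), 1)
  expect_equal(transcriptEdges(net)$sign, c(1, -1))
})

test_that("increases/decreases are sign aliases", {
  numeric <- netFromEdges(edges("a", 1, "b"),
                          tedges("a", 1, "G1", "b", -1, "G2"))
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("source\tsign\ttarget\tlayer",
               "a\tincreases\tb\tfunctional",
               "a\tincreases\tG1\ttranscript",
               "b\tdecreases\tG2\ttranscript"), tsv)
  aliased <- readNetwork(tsv)
  expect_equal(backboneEdges(aliased), backboneEdges(numeric))
  expect_equal(transcriptEdges(aliased), transcriptEdges(numeric))
})

test_that("reader rejects malformed input with line numbers", {
  write_net <- function(lines) {
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("source\tsign\ttarget\tlayer", lines), tsv)
    tsv
  }
  expect_error(readNetwork(write_net("a\t1\tb\tfunctional")),
               "no transcript layer")
  expect_error(readNetwork(write_net(c("a\t1\tb", "a\t1\tG1\ttranscript"))),
               "line 2")
  expect_error(readNetwork(write_net("a\t1\tG1\tmystery")), "layer tag")
  expect_error(readNetwork(write_net("a\t2\tG1\ttranscript")), "sign token")
  expect_error(readNetwork(write_net(c("a\t1\ta\tfunctional",
                                       "a\t1\tG1\ttranscript"))),
               "self-loop")
  expect_warning(
    net <- readNetwork(write_net(c("a\t1\tb\tfunctional",
                                   "a\t1\tb\tfunctional",
                                   "a\t1\tG1\ttranscript"))),
    "duplicate")
  expect_equal(nrow(backboneEdges(net)), 1)
})

test_that("under-represented footprints are pruned at the stated boundary", {
  be <- edges("a", 1, "b")
  te4 <- tedges("a", 1, "G1", "a", 1, "G2", "a", 1, "G3", "a", 1, "G4",
                "b", 1, "H1", "b", 1, "H2", "b", 1, "H3", "b", 1, "H4",
                "b", 1, "H5")
  net <- netFromEdges(be, te4)
  pruned <- pruneUnderrepresented(net, minDownstream = 5)
  # a had 4 transcript edges: all removed; b had 5: untouched
  expect_false("a" %in% transcriptEdges(pruned)$source)
  expect_equal(sum(transcriptEdges(pruned)$source == "b"), 5)
  # the node itself and the backbone edges stay
  expect_setequal(backboneNodes(pruned), c("a", "b"))
  expect_equal(nrow(backboneEdges(pruned)), 1)
  # vacuous threshold leaves the network unchanged
  same <- pruneUnderrepresented(net, minDownstream = 1)
  expect_equal(transcriptEdges(same), transcriptEdges(net))
})

test_that("scorability keeps nodes with footprinted ancestors and descendants", {
  # chain a -> b -> c, only b has a footprint: a has no footprinted ancestor
  # and c no footprinted descendant, so both are extrapolated and dropped
  chain <- netFromEdges(edges("a", 1, "b", "b", 1, "c"),
                        tedges("b", 1, "G1"))
  kept <- restrictToScorable(chain)
  expect_setequal(backboneNodes(kept), "b")

  # a -> b -> c with footprints on a and c: b sits between two anchors and
  # is interpolated, not extrapolated; a and c anchor themselves
  bridged <- netFromEdges(edges("a", 1, "b", "b", 1, "c"),
                          tedges("a", 1, "G1", "c", 1, "G2"))
  expect_setequal(backboneNodes(restrictToScorable(bridged)),
                  c("a", "b", "c"))

  # a dead end d hanging off the anchored region is dropped
  branched <- netFromEdges(edges("a", 1, "b", "b", 1, "c", "c", 1, "d"),
                           tedges("a", 1, "G1", "c", 1, "G2"))
  kept2 <- restrictToScorable(branched)
  expect_setequal(backboneNodes(kept2), c("a", "b", "c"))

  # isolated node with no footprint disappears; fully footprinted net unchanged
  iso <- netFromEdges(edges("a", 1, "b"), tedges("a", 1, "G1", "b", 1, "G2"))
  iso@backboneNodes <- c(iso@backboneNodes, "zz")
  expect_setequal(backboneNodes(restrictToScorable(iso)), c("a", "b"))
  expect_setequal(backboneNodes(restrictToScorable(iso)),
                  backboneNodes(restrictToScorable(restrictToScorable(iso))))
})

test_that("scorability restriction is idempotent and monotone on random nets", {
  for (s in 1:10) {
    cfg <- synthConfig(nBackbone = 7, density = 0.3, footprintFraction = 0.4,
                       footprintMin = 1, footprintMax = 3, seed = s)
    net <- try(generateNetwork(cfg), silent = TRUE)
    if (inherits(net, "try-error")) next
    once <- try(restrictToScorable(net), silent = TRUE)
    if (inherits(once, "try-error")) next
    twice <- restrictToScorable(once)
    expect_setequal(backboneNodes(twice), backboneNodes(once))
    expect_true(all(backboneNodes(once) %in% backboneNodes(net)))
    # prune-then-restrict applied twice equals applied once
    f1 <- filterNetwork(net, minDownstream = 2)
    f2 <- filterNetwork(f1, minDownstream = 2)
    expect_equal(backboneEdges(f2), backboneEdges(f1))
    expect_equal(transcriptEdges(f2), transcriptEdges(f1))
  }
})

test_that("Laplacian blocks match the hand-expanded 2-node example", {
  b <- buildLaplacianBlocks(toyNetwork())
  expect_equal(unname(b@L3), matrix(c(2, -1, -1, 2), 2))
  expect_equal(unname(b@Q), matrix(c(1, 1, 1, 1), 2))
  expect_equal(unname(b@L2), -diag(2))
  expect_equal(b@Esize, 1)
})

test_that("parallel contradictory backbone edges sum term by term", {
  net <- netFromEdges(edges("a", 1, "b", "a", -1, "b"),
                      tedges("a", 1, "G1", "b", 1, "G2"))
  b <- buildLaplacianBlocks(net)
  expect_equal(b@Esize, 2)
  # off-diagonals cancel, degrees count both parallel edges (+1 transcript)
  expect_equal(unname(b@L3), matrix(c(3, 0, 0, 3), 2))
  expect_equal(unname(b@Q), matrix(c(2, 0, 0, 2), 2))
})

test_that("a disconnected backbone is reported as singular by component", {
  net <- netFromEdges(edges("a", 1, "b", "c", 1, "d"),
                      tedges("a", 1, "G1", "b", 1, "G2"))
  # c-d component carries no transcript edge: its block is a pure signed
  # Laplacian with a zero mode
  expect_error(buildLaplacianBlocks(net), "disconnected.*c,d")
})

test_that("quadratic forms reproduce the explicit edge sums", {
  for (s in 1:20) {
    inst <- randomInstance(s)
    net <- inst$net
    b <- inst$blocks
    n <- length(b@nodeOrder)
    te <- transcriptEdges(net)
    geneDeg <- table(te$gene)[b@geneOrder]
    for (rep in 1:5) {
      f <- setNames(rnorm(n), b@nodeOrder)
      beta <- setNames(rnorm(length(b@geneOrder)), b@geneOrder)
      # NPA form
      expect_equal(drop(crossprod(f, b@Q %*% f)) / b@Esize,
                   npaEdgeSum(net, f), tolerance = 1e-10)
      # full-Laplacian form: f'L3 f + 2 f'L2 beta + sum_g deg(g) beta_g^2
      viaBlocks <- drop(crossprod(f, b@L3 %*% f)) +
        2 * drop(crossprod(f, b@L2 %*% beta)) +
        sum(as.numeric(geneDeg) * beta^2)
      expect_equal(viaBlocks, objectiveValue(net, f, beta), tolerance = 1e-10)
    }
  }
})
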