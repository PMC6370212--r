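test_that("correlation matrices and p-values match the t-distribution oracle", {
  set.seed(31)
  m <- matrix(rnorm(90), 10, 9, dimnames = list(paste0("f", 1:10), NULL))
  cr <- correlationMatrix(m)
  rho <- cor(t(m))
  expect_equal(cr@rho, rho, tolerance = 1e-12)
  n <- 9
  tstat <- abs(rho) * sqrt((n - 2) / (1 - rho^2))
  pOracle <- 2 * (1 - pt(tstat, n - 2))
  diag(pOracle) <- 0
  expect_equal(cr@pval, pOracle, tolerance = 1e-9)

  # the significance boundary is the closed-form t critical value on |rho|
  tc <- qt(1 - 0.05 / 2, n - 2)
  rc <- tc / sqrt(n - 2 + tc^2)
  off <- !diag(TRUE, 10)
  expect_identical(cr@significant[off], (abs(rho) >= rc - 1e-12)[off])

  # duplicated and negated rows
  dup <- rbind(a = m[1, ], b = m[1, ], c = -m[1, ], d = rnorm(9))
  cr2 <- correlationMatrix(dup)
  expect_equal(cr2@rho["a", "b"], 1, tolerance = 1e-12)
  expect_equal(cr2@rho["a", "c"], -1, tolerance = 1e-12)
  expect_true(cr2@significant["a", "b"] && cr2@significant["a", "c"])

  expect_error(correlationMatrix(m[, 1:2]), "3 samples")
  expect_warning(correlationMatrix(rbind(m, const = rep(1, 9))), "constant")
})

test_that("a looser alpha never loses significant pairs", {
  set.seed(32)
  m <- matrix(rnorm(72), 8, 9)
  rownames(m) <- paste0("f", 1:8)
  tight <- correlationMatrix(m, alpha = 0.01)@significant
  loose <- correlationMatrix(m, alpha = 0.10)@significant
  expect_true(all(loose[tight]))
  expect_gte(sum(loose), sum(tight))
})

test_that("node strength averages |rho| over significant pairs only", {
  set.seed(33)
  m <- rbind(a = 1:5 + rnorm(5, 0, 0.01), b = 1:5 + rnorm(5, 0, 0.01),
             c = 1:5 + rnorm(5, 0, 0.01))
  cr <- correlationMatrix(m)
  expect_equal(unname(nodeStrength(cr)), rep(1, 3), tolerance = 1e-3)

  neg <- rbind(a = c(1, 2, 3, 4, 10), b = -c(1, 2, 3, 4, 10) * 2)
  crn <- correlationMatrix(neg)
  expect_equal(unname(nodeStrength(crn)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(nodeStrength(crn, useAbs = FALSE)), c(-1, -1),
               tolerance = 1e-12)

  for (k in 1:10) {
    mm <- matrix(rnorm(63), 7, 9, dimnames = list(paste0("f", 1:7), NULL))
    cr <- correlationMatrix(mm)
    expect_equal(unname(nodeStrength(cr)),
                 oracleNodeStrength(cr@rho, cr@significant),
                 tolerance = 1e-9)
  }

  expect_equal(networkStrength(c(1, 1, 1)), 1)
  expect_equal(networkStrength(c(0.8, 0.4)), 0.6)
  expect_error(networkStrength(numeric(0)), "empty")
})

test_that("network edges pass the display threshold but ns uses all significant pairs", {
  set.seed(34)
  # three features: one strong pair, one moderate significant pair
  x <- rnorm(9)
  m <- rbind(a = x,
             b = x + rnorm(9, 0, 0.1),
             c = x + rnorm(9, 0, 0.45))
  cr <- correlationMatrix(m)
  stopifnot(cr@significant["a", "b"], cr@significant["a", "c"])
  thr <- (abs(cr@rho["a", "b"]) + abs(cr@rho["a", "c"])) / 2
  net <- buildNetwork(cr, displayThreshold = thr)
  shown <- abs(cr@rho[upper.tri(cr@rho)]) >= thr &
    cr@significant[upper.tri(cr@rho)]
  expect_identical(nrow(net@edges), sum(shown))
  # node a's strength still averages both significant |rho| values
  expect_equal(unname(net@ns["a"]),
               mean(abs(cr@rho["a", c("b", "c")])), tolerance = 1e-12)

  # threshold 0: edge count equals the significant-pair count, and ns/NS
  # recomputed from the exported edge list agree with the matrix path
  net0 <- buildNetwork(cr, displayThreshold = 0)
  expect_identical(nrow(net0@edges),
                   sum(cr@significant[upper.tri(cr@significant)]))
  nsEdge <- sapply(rownames(cr@rho), function(v) {
    e <- net0@edges[net0@edges$source == v | net0@edges$target == v, ]
    if (!nrow(e)) 0 else mean(abs(e$rho))
  })
  expect_equal(unname(net0@ns), unname(nsEdge[names(net0@ns)]),
               tolerance = 1e-12)
  expect_equal(net0@NS, mean(nsEdge), tolerance = 1e-12)

  # NS is invariant under node relabeling
  m2 <- m[c(3, 1, 2), ]
  expect_equal(buildNetwork(correlationMatrix(m2), 0)@NS, net0@NS,
               tolerance = 1e-12)
})
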