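test_that("fold-over-IS normalization follows the two-fragment sum rule", {
  areas <- data.frame(
    compound_id = c("cmpA", "cmpA", "formononetin", "formononetin"),
    sample_id = "S1_1", stage = "S1", replicate = 1,
    fragment_rank = c(1, 2, 1, 2), area = c(10, 10, 15, 5))
  ab <- normalizeToIS(areas)
  expect_equal(unname(assay(ab)["cmpA", "S1_1"]), 1.0)

  areas$area[1:2] <- 0
  expect_equal(unname(assay(normalizeToIS(areas))["cmpA", "S1_1"]), 0)

  areas$area[3:4] <- 0
  expect_error(normalizeToIS(areas), "S1_1")

  # noiseless synthetic tables recover the generating abundances exactly
  d <- synthDesign(lognormalSigma = 0, ctSigma = 0)
  tabs <- simulateTables(d, seed = 3)
  ab <- normalizeToIS(tabs$areas)
  truth <- tabs$truth$trueAbundances
  expect_equal(assay(ab)[rownames(truth), colnames(truth)], truth,
               tolerance = 1e-12)
})

test_that("normalization is invariant to per-sample scaling of all areas", {
  set.seed(21)
  ab0 <- matrix(rlnorm(12), 4, 3,
                dimnames = list(paste0("c", 1:4),
                                c("S1_1", "S1_2", "S3_1")))
  areas <- makeAreaTable(ab0)
  scaled <- areas
  for (s in unique(scaled$sample_id)) {
    f <- runif(1, 0.1, 10)
    scaled$area[scaled$sample_id == s] <-
      scaled$area[scaled$sample_id == s] * f
  }
  expect_equal(assay(normalizeToIS(areas)), assay(normalizeToIS(scaled)),
               tolerance = 1e-12)
})

test_that("stage summaries average replicates and percentages sum to 100", {
  ab0 <- matrix(c(3, 3, 1, 1), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("S1_1", "S1_2")))
  ab <- normalizeToIS(makeAreaTable(ab0))
  ss <- stageSummary(ab)
  expect_equal(unname(ss$percent[, "S1"]), c(75, 25))

  # a constructed 11-compound profile with three dominant compounds
  pct <- c(62.5, 29.1, 6.8, rep(1.6 / 8, 8))
  m <- matrix(rep(pct, 3), ncol = 3,
              dimnames = list(sprintf("m%02d", 1:11),
                              c("S1_1", "S1_2", "S1_3")))
  ss <- stageSummary(normalizeToIS(makeAreaTable(m)))
  expect_equal(unname(ss$percent[c("m01", "m02", "m03"), "S1"]),
               c(62.5, 29.1, 6.8), tolerance = 1e-9)
  expect_equal(sum(ss$percent[, "S1"]), 100, tolerance = 1e-9)

  # a single compound is 100% wherever nonzero
  one <- matrix(c(2, 5), 1, 2, dimnames = list("only", c("S1_1", "S3_1")))
  ss <- stageSummary(normalizeToIS(makeAreaTable(one)))
  expect_equal(unname(ss$percent["only", ]), c(100, 100))

  set.seed(22)
  r <- matrix(rlnorm(33), 11, 3,
              dimnames = list(sprintf("m%02d", 1:11),
                              c("S1_1", "S3_1", "S5_1")))
  ss <- stageSummary(normalizeToIS(makeAreaTable(r)))
  expect_equal(unname(colSums(ss$percent)), rep(100, 3), tolerance = 1e-9)
})

test_that("row clustering matches a naive average-linkage oracle", {
  set.seed(23)
  m <- matrix(rnorm(48), 8, 6, dimnames = list(paste0("r", 1:8), NULL))
  hc <- hclRows(m)
  d <- 1 - cor(t(m[order(rownames(m)), ]))
  expect_equal(sort(hc$height),
               oracleAverageLinkHeights(as.dist(d)), tolerance = 1e-9)

  # identical rows merge at height zero
  m2 <- rbind(a = 1:6, b = 1:6, c = c(3, 1, 4, 1, 5, 9))
  hc2 <- hclRows(m2)
  expect_equal(min(hc2$height), 0, tolerance = 1e-12)

  # perfect anticorrelation sits at distance 2 under 1 - rho
  m3 <- rbind(a = c(1, 2, 3, 5), b = -c(1, 2, 3, 5))
  expect_equal(max(hclRows(m3)$height), 2, tolerance = 1e-12)

  # permutation invariance up to relabeling
  perm <- sample(nrow(m))
  expect_equal(sort(hclRows(m[perm, ])$height), sort(hc$height),
               tolerance = 1e-12)

  expect_error(hclRows(rbind(a = rep(1, 4), b = rnorm(4))), "euclidean")
  expect_error(hclRows(m[1, , drop = FALSE]), "two rows")

  # Newick export round-trips through ape
  nwk <- hclToNewick(hc)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, rownames(m))
})
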