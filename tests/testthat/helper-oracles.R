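# Independent oracles, written before the implementation paths they check.
# They share no code with the package: masses come from a separately
# transcribed NIST table, enumeration uses expand.grid, clustering is the
# naive O(n^3) Lance-Williams loop.

# NIST atomic masses, independently transcribed (more digits than the
# package's table)
.oracleMass <- c(C = 12, H = 1.00782503224, O = 15.99491461960,
                 N = 14.00307400446, S = 31.97207117)
.oracleElectron <- 0.000548579909

oracleFormulaMass <- function(s) {
  toks <- regmatches(s, gregexpr("[A-Z][a-z]?[0-9]*", s))[[1]]
  sum(vapply(toks, function(tok) {
    sym <- gsub("[0-9]", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    (if (nzchar(n)) as.numeric(n) else 1) * .oracleMass[[sym]]
  }, numeric(1)))
}

# exhaustive composition lattice via expand.grid: returns the set of
# matching composition keys "aglycone|dec1,dec2,..."
oracleDecompose <- function(mz, ppm = 5, maxG = 4, maxA = 3) {
  glyc <- c(hexose = "C6H10O5", deoxyhexose = "C6H10O4")
  acyl <- c(malonyl = "C3H2O3", coumaroyl = "C9H6O2",
            caffeoyl = "C9H6O3", feruloyl = "C10H8O3")
  ags <- c(pelargonidin = "C15H11O5", cyanidin = "C15H11O6",
           delphinidin = "C15H11O7")
  decs <- c(glyc, acyl)
  grid <- do.call(expand.grid,
                  c(lapply(glyc, function(.) 0:maxG),
                    lapply(acyl, function(.) 0:maxA)))
  grid <- grid[rowSums(grid[, names(glyc)]) <= maxG &
               rowSums(grid[, names(acyl)]) <= maxA, , drop = FALSE]
  decMass <- as.matrix(grid) %*% vapply(decs, oracleFormulaMass, numeric(1))
  keys <- character(0)
  for (ag in names(ags)) {
    total <- oracleFormulaMass(ags[[ag]]) - .oracleElectron + decMass
    hits <- which(abs(total - mz) <= mz * ppm * 1e-6)
    for (h in hits) {
      ms <- sort(rep(names(decs), as.integer(grid[h, names(decs)])))
      keys <- c(keys, paste(ag, paste(ms, collapse = ","), sep = "|"))
    }
  }
  sort(keys)
}

decompositionKeys <- function(cands) {
  sort(vapply(cands, function(x)
    paste(aglycone(x), paste(decorations(x), collapse = ","), sep = "|"),
    character(1)))
}

# naive average-linkage agglomeration over a distance matrix; returns the
# sorted merge heights
oracleAverageLinkHeights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  sizes <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(0)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestD <- Inf
    idx <- which(active)
    for (i in idx) for (j in idx) if (i < j && d[i, j] < bestD) {
      bestD <- d[i, j]; best <- c(i, j)
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bestD)
    # average linkage update into slot i
    for (k in idx) if (k != i && k != j) {
      d[i, k] <- d[k, i] <-
        (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j])
    }
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  sort(heights)
}

# per-node mean |rho| over significant pairs, as an explicit loop
oracleNodeStrength <- function(rho, sig) {
  n <- nrow(rho)
  out <- numeric(n)
  for (i in seq_len(n)) {
    vals <- c()
    for (j in seq_len(n)) if (j != i && sig[i, j])
      vals <- c(vals, abs(rho[i, j]))
    out[i] <- if (length(vals)) mean(vals) else 0
  }
  out
}

# small long-format peak-area table builder for quantification tests
makeAreaTable <- function(abundances, isArea = 100, split = c(0.5, 0.5),
                          isName = "formononetin") {
  # abundances: compounds x samples matrix; sample names "S1_1" style
  rows <- list()
  for (s in colnames(abundances)) {
    stage <- sub("_.*", "", s)
    repl <- as.integer(sub(".*_", "", s))
    for (m in rownames(abundances)) for (r in 1:2)
      rows[[length(rows) + 1]] <- data.frame(
        compound_id = m, sample_id = s, stage = stage, replicate = repl,
        fragment_rank = r, area = abundances[m, s] * isArea * split[r])
    for (r in 1:2)
      rows[[length(rows) + 1]] <- data.frame(
        compound_id = isName, sample_id = s, stage = stage,
        replicate = repl, fragment_rank = r, area = isArea * split[r])
  }
  do.call(rbind, rows)
}
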