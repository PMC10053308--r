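# Region-pair geometry, Wright's Nc and the KS comparison.

test_that("region pairs follow the antipodal construction and gap rule", {
  # system [10k,20k) on a 100 kbp circle: control [50k,80k), gap 20 kbp
  rp <- makeRegionPair(100000, "circular", 10000, 20000)
  expect_true(rp$valid)
  expect_equal(rp$system, c(0, 30000))
  expect_equal(rp$control, c(50000, 80000))
  expect_equal(rp$gap, 20000)

  # same system on 50 kbp: regions cannot be 20 kbp apart
  rp2 <- makeRegionPair(50000, "circular", 10000, 20000)
  expect_false(rp2$valid)

  # control length always equals system length, wrapping included
  rp3 <- makeRegionPair(120000, "circular", 2000, 9000)
  expect_true(rp3$valid)
  expect_equal(diff(rp3$control), diff(rp3$system))

  # linear: farthest in-bounds placement
  rp4 <- makeRegionPair(100000, "linear", 10000, 20000)
  expect_true(rp4$valid)
  expect_equal(rp4$control, c(70000, 100000))
  expect_equal(rp4$gap, 40000)
})

test_that("circular region pairs are invariant to origin rotation", {
  base <- makeRegionPair(150000, "circular", 40000, 52000)
  for (shift in c(10000, 77000, 130000)) {
    s <- (40000 + shift) %% 150000
    rp <- makeRegionPair(150000, "circular", s, s + 12000)
    expect_equal(rp$gap, base$gap)
    expect_equal(diff(rp$control), diff(base$control))
  }
})

test_that("Nc hits its analytic limits", {
  fams <- dgrscan:::.codonFamilies()
  # one codon per family used heavily -> every F = 1 -> Nc = 20
  counts1 <- unlist(lapply(fams, function(cs)
    stats::setNames(c(100L, rep(0L, length(cs) - 1L)), cs)))
  names(counts1) <- unlist(fams)
  expect_equal(as.numeric(effectiveNumberOfCodons(counts1)), 20)

  # uniform heavy usage -> Nc at the 61 cap
  counts61 <- stats::setNames(rep(1000L, length(unlist(fams))),
                              unlist(fams))
  expect_equal(as.numeric(effectiveNumberOfCodons(counts61)), 61)
})

test_that("Nc matches an independent implementation on a fixed toy ORF", {
  cc <- dgrscan:::codonCounts(toyOrf)
  got <- as.numeric(effectiveNumberOfCodons(cc))
  expect_equal(got, oracleNc(toyOrf), tolerance = 1e-12)
  expect_equal(got, 48.7455358063, tolerance = 1e-9)
})

test_that("Nc decreases as synonymous usage concentrates", {
  # expected counts for 40 residues of every amino acid under increasing
  # skew
  ncAt <- function(delta) {
    usage <- codonUsageTable(delta)
    counts <- unlist(lapply(usage, function(p) 40 * p))
    names(counts) <- unlist(lapply(usage, names))
    as.numeric(effectiveNumberOfCodons(counts))
  }
  ncs <- vapply(c(0, 0.25, 0.5, 0.75, 1), ncAt, numeric(1))
  expect_true(all(diff(ncs) < 0))
  expect_equal(ncs[5], 20)  # delta 1 = single codon per family
})

test_that("missing 3-fold family is imputed from the 2- and 4-fold means", {
  fams <- dgrscan:::.codonFamilies()
  counts <- stats::setNames(rep(50L, length(unlist(fams))), unlist(fams))
  counts[c("ATT", "ATC", "ATA")] <- 0L  # no Ile
  nc <- effectiveNumberOfCodons(counts)
  expect_true(nc >= 20 && nc <= 61)
  # identical class means -> imputed F3 equals them; result still capped 61
  expect_equal(as.numeric(nc), 61)
})

test_that("KS outcomes cover identity, disjoint supports and small samples", {
  same <- ksTwoSample(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  disj <- ksTwoSample(c(1, 2, 3), c(10, 11, 12))
  expect_equal(disj$D, 1)

  tiny <- ksTwoSample(c(1, 2), c(3, 4, 5))
  expect_false(tiny$testable)
  expect_true(is.na(tiny$p_value))
})

test_that("KS statistic agrees with a hand-rolled ECDF supremum", {
  set.seed(8)
  for (i in 1:20) {
    x <- stats::rnorm(sample(5:40, 1))
    y <- stats::rnorm(sample(5:40, 1), mean = stats::runif(1, 0, 2))
    got <- ksTwoSample(x, y)$D
    z <- sort(unique(c(x, y)))
    d <- max(abs(stats::ecdf(x)(z) - stats::ecdf(y)(z)))
    expect_equal(got, d, tolerance = 1e-6)
  }
})

test_that("island genes show depressed Nc when the planted shift is strong", {
  sim <- simulateDataset(dgrSimConfig(nContigs = 10, fractionLong = 1,
                                      codonShiftDelta = 0.9,
                                      backgroundPfamRate = 0.5,
                                      pImmuneColocalization = 1,
                                      seed = 41))
  ds <- sim$dataset
  co <- contigTable(ds)
  nc <- do.call(rbind, lapply(seq_len(nrow(co)), function(i)
    ncForRegion(ds, co$contig_id[i], c(0, co$length[i]))))
  island <- sim$truth$genes$island[match(nc$gene_id,
                                         sim$truth$genes$gene_id)]
  expect_gt(mean(nc$nc[!island]) - mean(nc$nc[island]), 10)
})
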