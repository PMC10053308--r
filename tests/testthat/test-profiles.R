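# Residence/clade/taxon profiling and gene-map export.

# small CompositionSet over a hand-built dataset with known labels
makeProfileFixture <- function(residence, clades) {
  n <- length(residence)
  co <- data.frame(contig_id = paste0("c", 1:n), length = 30000,
                   topology = "linear", residence = residence,
                   taxon = "unknown", stringsAsFactors = FALSE)
  ge <- do.call(rbind, lapply(1:n, function(i)
    data.frame(gene_id = paste0("c", i, "_rt"),
               contig_id = paste0("c", i), start = 1000L, end = 1900L,
               strand = "+", stringsAsFactors = FALSE)))
  ph <- data.frame(gene_id = ge$gene_id, accession = "PF90001.1",
                   evalue = 1e-20, stringsAsFactors = FALSE)
  sy <- data.frame(system_id = paste0("s", 1:n),
                   contig_id = paste0("c", 1:n), rt_gene_id = ge$gene_id,
                   tr_start = 2000L, tr_end = 2100L, clade = clades,
                   stringsAsFactors = FALSE)
  ds <- DgrDataset(co, ge, ph, sy)
  loci <- data.frame(composition = "X", system_id = sy$system_id,
                     contig_id = sy$contig_id, stringsAsFactors = FALSE)
  loci$member_gene_ids <- as.list(ge$gene_id)
  loci$long_contig <- TRUE
  cs <- new("CompositionSet", loci = loci,
            summary = data.frame(composition = "X", n_pfams = 1L,
                                 n_occurrences = n, n_long_contigs = n,
                                 stringsAsFactors = FALSE),
            keys = list(X = "PF90001"), immuneCatalog = "PF90001")
  list(ds = ds, cs = cs)
}

test_that("residence minority fractions follow the counting rule", {
  f <- makeProfileFixture(c(rep("cellular", 3), "viral"), rep(1, 4))
  r <- residenceProfile(f$cs, f$ds)
  expect_equal(r$minority_fraction, 0.25)

  f2 <- makeProfileFixture(c("cellular", "viral"), c(1, 2))
  expect_equal(residenceProfile(f2$cs, f2$ds)$minority_fraction, 0.5)

  f3 <- makeProfileFixture(rep("cellular", 4), rep(1, 4))
  expect_equal(residenceProfile(f3$cs, f3$ds)$minority_fraction, 0)

  f4 <- makeProfileFixture(rep("unknown", 3), rep(1, 3))
  expect_true(is.na(residenceProfile(f4$cs, f4$ds)$minority_fraction))
})

test_that("clade profiles flag single-clade systems and modal fractions", {
  f <- makeProfileFixture(rep("cellular", 3), c(2, 2, 2))
  p <- cladeProfile(f$cs, f$ds)
  expect_true(p$single_clade)
  expect_equal(p$modal_clade_fraction, 1)

  f2 <- makeProfileFixture(rep("cellular", 3), c(2, 2, 5))
  p2 <- cladeProfile(f2$cs, f2$ds)
  expect_false(p2$single_clade)
  expect_equal(p2$modal_clade_fraction, 2 / 3)
  expect_equal(p2$modal_clade, 2L)

  f3 <- makeProfileFixture(rep("cellular", 4), 1:4)
  expect_equal(cladeProfile(f3$cs, f3$ds)$modal_clade_fraction, 0.25)
})

test_that("profiles are invariant to input row ordering", {
  f <- makeProfileFixture(c("cellular", "viral", "cellular", "viral",
                            "viral"), c(1, 1, 2, 3, 3))
  shuffled <- f$ds
  perm <- c(4, 2, 5, 1, 3)
  ds2 <- DgrDataset(contigTable(shuffled)[perm, ],
                    geneTable(shuffled)[perm, ],
                    pfamHitTable(shuffled)[perm, ],
                    dgrSystemTable(shuffled)[perm, ])
  expect_equal(residenceProfile(f$cs, ds2), residenceProfile(f$cs, f$ds))
  expect_equal(cladeProfile(f$cs, ds2), cladeProfile(f$cs, f$ds))
})

test_that("clade-by-taxon matrix recovers the planted association", {
  sim <- simulateDataset(dgrSimConfig(nContigs = 120, fractionLong = 1,
                                      emitSequences = FALSE,
                                      pImmuneColocalization = 1,
                                      taxonCladeBias = 1, seed = 61))
  it <- runIcity(sim$dataset, subsampleFraction = 1, seed = 1)
  cs <- assignCompositions(sim$dataset, selectPfams(it, "all_runs"),
                           sim$immuneCatalog)
  tx <- taxonProfile(cs, sim$dataset)
  m <- tx$cladeByTaxon
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
  # with bias 1, each taxon maps to exactly one clade
  expect_true(all(apply(m, 1, max) == 1))
  expect_equal(sum(tx$taxonCounts$n), nrow(compositionLoci(cs)))
})

test_that("gene maps draw oriented arrows with VR labels, deterministically", {
  sim <- simulateDataset(dgrSimConfig(nContigs = 3, emitSequences = FALSE,
                                      pImmuneColocalization = 1,
                                      arrangementConservation = 0,
                                      seed = 71))
  it <- runIcity(sim$dataset, subsampleFraction = 1, seed = 1)
  cs <- assignCompositions(sim$dataset, selectPfams(it, "all_runs"),
                           sim$immuneCatalog)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- exportGeneMaps(cs, sim$dataset, d1)
  exportGeneMaps(cs, sim$dataset, d2)
  expect_true(length(p1) >= 1)
  svg <- readLines(p1[1])
  genesDrawn <- sum(grepl("<polygon", svg))
  expect_gte(genesDrawn, 3)
  expect_true(any(grepl(">VR<", svg)))
  expect_identical(unname(dirChecksums(d1)), unname(dirChecksums(d2)))

  # arrow tips point with the strand: right for +, left for -
  plus <- dgrscan:::.svgArrow(10, 50, 20, 10, "#fff", "", FALSE, "+")
  minus <- dgrscan:::.svgArrow(10, 50, 20, 10, "#fff", "", FALSE, "-")
  expect_true(grepl("50.0,20.0", plus[1], fixed = TRUE))
  expect_true(grepl("10.0,20.0", minus[1], fixed = TRUE))
})
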