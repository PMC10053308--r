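# Neighborhood extraction, redundancy weighting and the w'/w score.

test_that("window membership respects half-open boundaries and wrapping", {
  ge <- data.frame(
    gene_id = c("rt", "in1", "out1"), contig_id = "c1",
    start = c(5000L, 15999L, 16000L), end = c(6000L, 17000L, 17500L),
    strand = "+")
  sy <- data.frame(system_id = "s1", contig_id = "c1", rt_gene_id = "rt",
                   tr_start = 6100L, tr_end = 6200L, clade = 1L)
  ds <- makeContigDataset(length = 40000, genes = ge, systems = sy)
  nb <- extractNeighborhoods(ds, D = 10000)
  expect_equal(nrow(nb), 1L)
  members <- nb$member_gene_ids[[1]]
  expect_true(all(c("rt", "in1") %in% members))  # 1 bp overlap counts
  expect_false("out1" %in% members)              # half-open window end

  # circular wrap: window of RT at [19000,20000) reaches [0,500)
  gec <- data.frame(gene_id = c("rt", "wrap"), contig_id = "c1",
                    start = c(19000L, 0L), end = c(20000L, 500L),
                    strand = "+")
  syc <- data.frame(system_id = "s1", contig_id = "c1", rt_gene_id = "rt",
                    tr_start = 18500L, tr_end = 18600L, clade = 1L)
  dsc <- makeContigDataset(length = 20000, topology = "circular",
                           genes = gec, systems = syc)
  nbc <- extractNeighborhoods(dsc, D = 10000)
  expect_true("wrap" %in% nbc$member_gene_ids[[1]])
})

test_that("redundancy weights follow fingerprint dereplication", {
  # 4 identical neighborhoods -> every member weighted 1/4
  ds4 <- makeBaitFixture(rep(list("PF00010.1"), 4))
  nb4 <- extractNeighborhoods(ds4, D = 10000)
  w4 <- redundancyWeights(nb4, ds4)
  members <- unique(unlist(nb4$member_gene_ids))
  expect_true(all(w4[members] == 0.25))

  # all fingerprints unique -> all weights 1
  dsU <- makeBaitFixture(list("PF00010.1", "PF00020.1", "PF00030.1"))
  nbU <- extractNeighborhoods(dsU, D = 10000)
  wU <- redundancyWeights(nbU, dsU)
  expect_true(all(wU == 1))

  # mixed: 3 shared + 3 unique fingerprints -> weights 1/3 and 1
  dsM <- makeBaitFixture(c(rep(list("PF00010.1"), 3),
                           list("PF00020.1", "PF00030.1", "PF00040.1")))
  nbM <- extractNeighborhoods(dsM, D = 10000)
  wM <- redundancyWeights(nbM, dsM)
  shared <- unlist(lapply(1:3, function(i)
    c(paste0("c", i, "_rt"), paste0("c", i, "_g1"))))
  uniqueM <- unlist(lapply(4:6, function(i)
    c(paste0("c", i, "_rt"), paste0("c", i, "_g1"))))
  expect_true(all(abs(wM[shared] - 1 / 3) < 1e-12))
  expect_true(all(wM[uniqueM] == 1))
})

test_that("icityScore matches the hand-computed weighted example", {
  # A(0.5,in), B(0.5,in), C(1.0,in), D(1.0,out) -> 2/3
  ds <- makeBaitFixture(c(rep(list("PF00010.1"), 2),
                          list(c("PF00010.1", "PF00020.1"))),
                        withFar = "PF00010.1")
  nb <- extractNeighborhoods(ds, D = 10000)
  w <- redundancyWeights(nb, ds)
  expect_equal(icityScore("PF00010", w, nb, ds), 2 / 3)
  expect_equal(icityScore("PF00020", w, nb, ds), 1)    # all members inside
  expect_error(icityScore("PF99999", w, nb, ds), "no members")

  # far-only cluster scores 0
  dsFar <- makeBaitFixture(list("PF00010.1"), withFar = "PF00050.1")
  nbF <- extractNeighborhoods(dsFar, D = 10000)
  wF <- redundancyWeights(nbF, dsFar)
  expect_equal(icityScore("PF00050", wF, nbF, dsFar), 0)
})

test_that("icityScore equals the brute-force oracle on small datasets", {
  for (seed in c(2, 9)) {
    sim <- simulateDataset(dgrSimConfig(nContigs = 8,
                                        emitSequences = FALSE,
                                        pImmuneColocalization = 0.6,
                                        backgroundPfamRate = 0.3,
                                        seed = seed))
    ds <- sim$dataset
    nbAll <- extractNeighborhoods(ds, D = 10000)
    for (kind in c("RT", "VR")) {
      nb <- nbAll[nbAll$bait_kind == kind, , drop = FALSE]
      w <- redundancyWeights(nb, ds)
      gk <- unique(paste0(
        stripPfamVersion(pfamHitTable(ds)$accession),
        ifelse(geneTable(ds)$contains_vr[
          match(pfamHitTable(ds)$gene_id, geneTable(ds)$gene_id)],
          ":VR", "")))
      for (key in gk) {
        expect_equal(icityScore(key, w, nb, ds),
                     bruteIcity(ds, key, 10000, kind),
                     info = paste(seed, kind, key))
      }
    }
  }
})

test_that("bait self-Pfam scores 1 in every run; fraction 1 stops at 2 runs", {
  sim <- simulateDataset(dgrSimConfig(nContigs = 10,
                                      emitSequences = FALSE, seed = 5))
  it <- runIcity(sim$dataset, subsampleFraction = 1, seed = 1)
  expect_equal(it@nRuns, 2L)
  s <- runScores(it)
  expect_equal(s[, 1], s[, 2])                 # deterministic runs
  expect_equal(unname(s["PF90001", ]), c(1, 1))  # RT's own Pfam
  expect_equal(unname(s["PF90002:VR", ]), c(1, 1))  # VR host's Pfam
})

test_that("scores are invariant to contig relabeling and strand flips", {
  sim <- simulateDataset(dgrSimConfig(nContigs = 8, emitSequences = FALSE,
                                      seed = 13))
  ds <- sim$dataset
  base <- meanScores(runIcity(ds, subsampleFraction = 1, seed = 1))

  # relabel every contig
  relabel <- function(x) paste0("renamed_", x)
  co <- contigTable(ds); co$contig_id <- relabel(co$contig_id)
  ge <- geneTable(ds); ge$contig_id <- relabel(ge$contig_id)
  sy <- dgrSystemTable(ds); sy$contig_id <- relabel(sy$contig_id)
  ds2 <- DgrDataset(co, ge, pfamHitTable(ds), sy, vrIntervalTable(ds))
  expect_equal(meanScores(runIcity(ds2, subsampleFraction = 1, seed = 1)),
               base)

  # flip every strand on one contig
  ge3 <- geneTable(ds)
  onC <- ge3$contig_id == contigTable(ds)$contig_id[1]
  ge3$strand[onC] <- ifelse(ge3$strand[onC] == "+", "-", "+")
  ds3 <- DgrDataset(contigTable(ds), ge3, pfamHitTable(ds),
                    dgrSystemTable(ds), vrIntervalTable(ds))
  expect_equal(meanScores(runIcity(ds3, subsampleFraction = 1, seed = 1)),
               base)
})

test_that("selectPfams applies strict/lenient modes with strict inequality", {
  keys <- data.frame(key = c("A", "B", "C"), accession = c("A", "B", "C"),
                     vr_flag = FALSE, stringsAsFactors = FALSE)
  s <- rbind(rep(0.8, 7), c(0.8, 0.6, rep(0.8, 5)), rep(0.7, 7))
  rownames(s) <- keys$key
  tab <- new("IcityTable", keys = keys, runScores = s,
             meanScore = rowMeans(s), w = rep(1, 3), wPrime = rep(1, 3),
             nRuns = 7L, runSeeds = 1:7, threshold = 0.7)
  expect_equal(selectPfams(tab, "all_runs"), "A")
  expect_equal(selectPfams(tab, "any_run"), c("A", "B"))
  expect_true(all(selectPfams(tab, "all_runs") %in%
                  selectPfams(tab, "any_run")))
})

test_that("planted immune Pfam mean score rises with co-localization", {
  means <- vapply(c(0.1, 0.5, 0.9), function(p) {
    sim <- simulateDataset(dgrSimConfig(nContigs = 60, fractionLong = 1,
                                        emitSequences = FALSE,
                                        pImmuneColocalization = p,
                                        seed = 31))
    unname(meanScores(runIcity(sim$dataset, seed = 7))["PF90101"])
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})
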