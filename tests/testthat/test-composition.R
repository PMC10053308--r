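# Composition assignment, selection filters and arrangement
# canonicalization.

test_that("possibleArrangements matches 2^(n-1) n! and rejects n < 1", {
  expect_equal(possibleArrangements(1), 1)
  expect_equal(possibleArrangements(2), 4)
  expect_equal(possibleArrangements(3), 24)
  expect_error(possibleArrangements(0), "n must be")
})

test_that("canonicalSignature is orientation-symmetric and idempotent", {
  a <- canonicalSignature(c("A", "B"), c("+", "-"))
  b <- canonicalSignature(c("B", "A"), c("+", "-"))  # flipped locus
  expect_equal(a, b)
  # canonical form is a fixed point: re-canonicalizing the parsed form
  parts <- strsplit(strsplit(a, "|", fixed = TRUE)[[1]], "(?=[+-]$)",
                    perl = TRUE)
  labs <- vapply(parts, `[`, "", 1)
  strs <- vapply(parts, `[`, "", 2)
  expect_equal(canonicalSignature(labs, strs), a)
})

test_that("enumeration yields exactly 2^(n-1) n! canonical forms (n <= 4)", {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  for (n in 1:4) {
    labels <- LETTERS[1:n]
    sigs <- character(0)
    strandGrids <- expand.grid(rep(list(c("+", "-")), n),
                               stringsAsFactors = FALSE)
    for (p in perms(labels)) {
      for (r in seq_len(nrow(strandGrids))) {
        sigs <- c(sigs, canonicalSignature(p,
                                           unlist(strandGrids[r, ])))
      }
    }
    expect_equal(length(unique(sigs)), possibleArrangements(n))
  }
})

test_that("reverse-complementing a contig leaves locus signatures unchanged", {
  sim <- simulateDataset(dgrSimConfig(nContigs = 6, emitSequences = FALSE,
                                      pImmuneColocalization = 1,
                                      seed = 17))
  ds <- sim$dataset
  keys <- c("PF90001", "PF90002:VR", "PF90003", "PF90101")
  cs <- assignCompositions(ds, keys, sim$immuneCatalog)
  arr <- arrangementProfile(cs, ds)

  # reverse-complement one contig's annotation: coords mirrored, strands
  # flipped
  ge <- geneTable(ds); co <- contigTable(ds)
  cid <- co$contig_id[1]; L <- co$length[1]
  onC <- ge$contig_id == cid
  s <- ge$start[onC]; e <- ge$end[onC]
  ge$start[onC] <- L - e; ge$end[onC] <- L - s
  ge$strand[onC] <- ifelse(ge$strand[onC] == "+", "-", "+")
  sy <- dgrSystemTable(ds); vr <- vrIntervalTable(ds)
  onS <- sy$contig_id == cid
  ts <- sy$tr_start[onS]; te <- sy$tr_end[onS]
  sy$tr_start[onS] <- L - te; sy$tr_end[onS] <- L - ts
  onV <- vr$system_id %in% sy$system_id[onS]
  vs <- vr$start[onV]; veOld <- vr$end[onV]
  vr$start[onV] <- L - veOld; vr$end[onV] <- L - vs
  ds2 <- DgrDataset(co, ge, pfamHitTable(ds), sy, vr)
  cs2 <- assignCompositions(ds2, keys, sim$immuneCatalog)
  arr2 <- arrangementProfile(cs2, ds2)
  expect_equal(arr2$arrangements, arr$arrangements)
})

test_that("loci without an immune Pfam are dropped and keys separate VR", {
  # one locus with immune, one without; VR-host and plain copies of the
  # same family are distinct key members
  ds <- makeBaitFixture(list(c("PF00010.1", "PF05635.1"),
                             c("PF00010.1")))
  # mark c1_g1 as VR-containing via a VR interval
  vr <- data.frame(system_id = "sys1", start = 3100L, end = 3200L,
                   host_gene_id = "c1_g1")
  ds <- DgrDataset(contigTable(ds), geneTable(ds)[
    , c("gene_id", "contig_id", "start", "end", "strand")],
    pfamHitTable(ds), dgrSystemTable(ds), vr)
  keys <- c("PF90001", "PF00010", "PF00010:VR", "PF05635")
  cs <- assignCompositions(ds, keys, "PF05635")
  s <- compositionSummary(cs)
  expect_equal(nrow(s), 1L)  # locus 2 dropped: no immune Pfam
  expect_true(grepl("PF00010:VR", s$composition))
  expect_equal(s$n_occurrences, 1L)
})

test_that("composition filter applies strict >20 and >=4 long contigs", {
  mk <- function(occ, lng) {
    loci <- data.frame(composition = "X", system_id = paste0("s", 1:occ),
                       contig_id = paste0("c", 1:occ),
                       stringsAsFactors = FALSE)
    loci$member_gene_ids <- rep(list(character(0)), occ)
    loci$long_contig <- c(rep(TRUE, lng), rep(FALSE, occ - lng))
    summary <- data.frame(composition = "X", n_pfams = 2L,
                          n_occurrences = occ, n_long_contigs = lng,
                          stringsAsFactors = FALSE)
    new("CompositionSet", loci = loci, summary = summary,
        keys = list(X = c("PF00001", "PF05635")),
        immuneCatalog = "PF05635")
  }
  expect_equal(nrow(compositionSummary(selectCompositions(mk(25, 5)))), 1L)
  expect_equal(nrow(compositionSummary(selectCompositions(mk(20, 5)))), 0L)
  expect_equal(nrow(compositionSummary(selectCompositions(mk(30, 3)))), 0L)
})

test_that("modal arrangement fractions are tallied per composition", {
  sim <- simulateDataset(dgrSimConfig(nContigs = 2, emitSequences = FALSE,
                                      pImmuneColocalization = 1,
                                      arrangementConservation = 1,
                                      seed = 23))
  keys <- c("PF90001", "PF90002:VR", "PF90003", "PF90101")
  cs <- assignCompositions(sim$dataset, keys, sim$immuneCatalog)
  arr <- arrangementProfile(cs, sim$dataset)
  expect_equal(arr$modal$modal_fraction, 1)
  expect_equal(arr$modal$modal_signature, plantedSignature())
  expect_equal(arr$modal$possible_count, possibleArrangements(4))
  expect_equal(sum(arr$arrangements$fraction), 1)
})

test_that("planted composition keys are recovered exactly without decoys", {
  sim <- simulateDataset(dgrSimConfig(nContigs = 12, emitSequences = FALSE,
                                      pImmuneColocalization = 1,
                                      backgroundPfamRate = 0,
                                      seed = 29))
  it <- runIcity(sim$dataset, subsampleFraction = 1, seed = 1)
  sel <- selectPfams(it, "all_runs")
  cs <- assignCompositions(sim$dataset, sel, sim$immuneCatalog)
  s <- compositionSummary(cs)
  expect_equal(nrow(s), 1L)
  expect_equal(s$composition,
               unique(sim$truth$contigs$planted_keys))
  expect_equal(s$n_occurrences, 12L)
  um <- upsetMatrix(cs)
  expect_equal(sum(um[1, -(1:2)]), 4)
})
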