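# Seeded synthetic-contig generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# contig lengths log-normal with mode 3 kbp plus a controlled fraction of
# long (> 20 kbp) contigs, linear and circular topology, one planted DGR
# cassette per contig (RT gene, TR interval, VR inside a target host
# gene, an accessory gene and an immune-Pfam gene), immune genes
# co-localized with the cassette at a controlled probability and placed
# far (> co-localization window on both arcs) otherwise, Poisson decoy
# genes with no positional association to the cassette, conserved vs
# scrambled cassette gene orders, a codon-usage-shifted island around the
# cassette, and residence/clade/taxon labels with a configurable
# taxon-clade association. Every draw comes from the single seeded RNG
# stream, so a fixed seed reproduces the dataset byte-identically.

.simPfams <- c(rt = "PF90001.1", target = "PF90002.1",
               accessory = "PF90003.1", immune = "PF90101.1")
.decoyPfams <- sprintf("PF80%03d.1", 1:20)
.simTaxa <- c("Pseudomonadota", "Bacteroidota", "Bacillota",
              "Cyanobacteriota", "Actinomycetota", "Euryarchaeota")

#' DgrSimConfig: parameters of the synthetic-contig generator
#'
#' @slot nContigs number of contigs.
#' @slot lengthMode mode of the log-normal contig length distribution in
#'   bp (default 3000).
#' @slot lengthSdLog log-scale sd of the length distribution.
#' @slot minLength,maxLength hard length bounds in bp (3000 / 200000).
#' @slot fractionLong fraction of contigs drawn uniformly from
#'   (20 kbp, maxLength] instead of the short log-normal component.
#' @slot pImmuneColocalization probability the immune-Pfam gene is planted
#'   within the co-localization window of the cassette.
#' @slot backgroundPfamRate expected decoy genes per kbp.
#' @slot arrangementConservation probability a cassette keeps the
#'   canonical gene order and strands.
#' @slot codonShiftDelta synonymous-usage skew inside the planted island
#'   (0 = null, no shift).
#' @slot islandFlank island extent beyond the cassette span, bp.
#' @slot colocDistance the window used to define "co-localized", bp.
#' @slot pViral probability of viral residence.
#' @slot pCircular probability of circular topology.
#' @slot cladeWeights length-6 RT clade sampling weights (sum 1).
#' @slot taxonCladeBias probability a contig's taxon is its clade's
#'   preferred taxon (drives the clade-by-taxon association).
#' @slot emitSequences generate nucleotide sequences (needed for the
#'   codon-bias stage).
#' @slot seed integer RNG seed.
#' @export
setClass("DgrSimConfig",
  slots = c(nContigs = "integer", lengthMode = "numeric",
            lengthSdLog = "numeric", minLength = "numeric",
            maxLength = "numeric", fractionLong = "numeric",
            pImmuneColocalization = "numeric",
            backgroundPfamRate = "numeric",
            arrangementConservation = "numeric",
            codonShiftDelta = "numeric", islandFlank = "numeric",
            colocDistance = "numeric", pViral = "numeric",
            pCircular = "numeric", cladeWeights = "numeric",
            taxonCladeBias = "numeric", emitSequences = "logical",
            seed = "integer"))

setValidity("DgrSimConfig", function(object) {
  msg <- character(0)
  probs <- c(object@fractionLong, object@pImmuneColocalization,
             object@arrangementConservation, object@codonShiftDelta,
             object@pViral, object@pCircular, object@taxonCladeBias)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "probabilities and the codon shift must lie in [0, 1]")
  if (object@nContigs < 1) msg <- c(msg, "nContigs must be >= 1")
  if (length(object@cladeWeights) != 6 ||
      abs(sum(object@cladeWeights) - 1) > 1e-8 ||
      any(object@cladeWeights < 0))
    msg <- c(msg, "cladeWeights must be 6 non-negative values summing to 1")
  if (object@backgroundPfamRate < 0)
    msg <- c(msg, "backgroundPfamRate must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DgrSimConfig", function(object) {
  cat("DgrSimConfig:", object@nContigs, "contig(s), seed", object@seed,
      "\n  length mode", object@lengthMode, "bp, fraction long",
      object@fractionLong, "\n  p(immune co-localized)",
      object@pImmuneColocalization, ", decoy rate",
      object@backgroundPfamRate, "/kbp\n  arrangement conservation",
      object@arrangementConservation, ", codon shift",
      object@codonShiftDelta, "\n")
})

#' Build a simulation configuration
#'
#' Defaults reflect the contig population the analysis is designed for:
#' length mode 3 kbp with about half the contigs longer than 20 kbp,
#' circular topology for half the contigs, and the 10 kbp co-localization
#' window used throughout the pipeline.
#'
#' @param nContigs,lengthMode,lengthSdLog,minLength,maxLength,fractionLong
#'   see \code{\link{DgrSimConfig-class}}.
#' @param pImmuneColocalization,backgroundPfamRate,arrangementConservation
#'   see \code{\link{DgrSimConfig-class}}.
#' @param codonShiftDelta,islandFlank,colocDistance,pViral,pCircular see
#'   \code{\link{DgrSimConfig-class}}.
#' @param cladeWeights,taxonCladeBias,emitSequences,seed see
#'   \code{\link{DgrSimConfig-class}}.
#' @return a validated \code{DgrSimConfig}.
#' @export
dgrSimConfig <- function(nContigs = 100, lengthMode = 3000,
                         lengthSdLog = 0.8, minLength = 3000,
                         maxLength = 200000, fractionLong = 0.5,
                         pImmuneColocalization = 0.9,
                         backgroundPfamRate = 0.2,
                         arrangementConservation = 0.95,
                         codonShiftDelta = 0.5, islandFlank = 10000,
                         colocDistance = 10000, pViral = 0.3,
                         pCircular = 0.5,
                         cladeWeights = c(0.3, 0.25, 0.15, 0.1, 0.1, 0.1),
                         taxonCladeBias = 0.8, emitSequences = TRUE,
                         seed = 1L) {
  new("DgrSimConfig", nContigs = as.integer(nContigs),
      lengthMode = lengthMode, lengthSdLog = lengthSdLog,
      minLength = minLength, maxLength = maxLength,
      fractionLong = fractionLong,
      pImmuneColocalization = pImmuneColocalization,
      backgroundPfamRate = backgroundPfamRate,
      arrangementConservation = arrangementConservation,
      codonShiftDelta = codonShiftDelta, islandFlank = islandFlank,
      colocDistance = colocDistance, pViral = pViral,
      pCircular = pCircular, cladeWeights = cladeWeights,
      taxonCladeBias = taxonCladeBias, emitSequences = emitSequences,
      seed = as.integer(seed))
}

#' Sample a coding sequence codon by codon
#'
#' Draws one synonymous codon per amino acid from a usage table, so the
#' translation of the output equals the input and codon frequencies
#' converge to the table as the sequence grows.
#'
#' @param aaSeq amino-acid sequence (single string or character vector of
#'   one-letter codes).
#' @param usage per-amino-acid codon probability table as returned by
#'   \code{\link{codonUsageTable}}.
#' @return nucleotide string of length \code{3 * length(aaSeq)}.
#' @examples
#' set.seed(1)
#' sampleCodons("MW", codonUsageTable(0))  # single-codon families: "ATGTGG"
#' @export
sampleCodons <- function(aaSeq, usage) {
  aa <- if (length(aaSeq) == 1L && nchar(aaSeq[1]) > 1L)
    strsplit(aaSeq, "")[[1]] else as.character(aaSeq)
  if (!length(aa)) return("")
  missing <- setdiff(unique(aa), names(usage))
  if (length(missing))
    stop("amino acid(s) absent from usage table: ",
         paste(missing, collapse = ", "))
  codons <- character(length(aa))
  for (a in unique(aa)) {
    i <- which(aa == a)
    tab <- usage[[a]]
    codons[i] <- if (length(tab) == 1L) names(tab) else
      names(tab)[sample.int(length(tab), length(i), replace = TRUE,
                            prob = tab)]
  }
  paste(codons, collapse = "")
}

# contig length from the two-component mixture, resampled until it can
# hold the planned cassette
.sampleContigLength <- function(cfg, needed) {
  meanlog <- log(cfg@lengthMode) + cfg@lengthSdLog^2
  shortCap <- min(20000, cfg@maxLength)
  for (t in 1:500) {
    if (stats::runif(1) < cfg@fractionLong) {
      L <- round(stats::runif(1, max(20000, needed), cfg@maxLength))
    } else {
      x <- stats::rlnorm(1, meanlog, cfg@lengthSdLog)
      if (x < cfg@minLength || x > shortCap) next
      L <- round(x)
    }
    if (L >= needed) return(as.integer(L))
  }
  warning("contig too short for its cassette after resampling; ",
          "using the minimum feasible length")
  as.integer(ceiling(needed))
}

# uniform placement of an interval of length len in the free space left
# by occupied intervals; NULL when nothing fits
.freePlace <- function(occStarts, occEnds, L, len, pad = 20L) {
  ord <- order(occStarts)
  s <- occStarts[ord]; e <- occEnds[ord]
  gapStart <- c(0L, e)
  gapEnd <- c(s, L)
  width <- gapEnd - gapStart
  slack <- width - len - 2L * pad
  ok <- which(slack >= 0)
  if (!length(ok)) return(NULL)
  g <- if (length(ok) == 1L) ok else
    ok[sample.int(length(ok), 1L, prob = slack[ok] + 1)]
  start <- gapStart[g] + pad + sample.int(slack[g] + 1L, 1L) - 1L
  c(start, start + len)
}

.randGeneLen <- function() 3L * sample(100:800, 1L)

# one synthetic contig; returns the table fragments and ground truth
.simContig <- function(cfg, i, bgUsage, skewUsage, aaLetters) {
  D <- cfg@colocDistance
  coloc <- stats::runif(1) < cfg@pImmuneColocalization
  canonical <- stats::runif(1) < cfg@arrangementConservation
  topology <- if (stats::runif(1) < cfg@pCircular) "circular" else "linear"
  canonOrder <- c("immune", "accessory", "rt", "target")
  blockRoles <- if (coloc) canonOrder else c("accessory", "rt", "target")
  lens <- vapply(canonOrder, function(r) .randGeneLen(), integer(1))
  ord <- blockRoles
  strands <- stats::setNames(rep("+", length(ord)), ord)
  if (!canonical) {
    ord <- sample(blockRoles)
    strands <- stats::setNames(sample(c("+", "-"), length(ord),
                                      replace = TRUE), ord)
  }
  gaps <- sample(150:400, length(ord), replace = TRUE)
  coreSpan <- sum(lens[ord]) + sum(gaps[-length(gaps)]) + 200L
  needed <- if (coloc) coreSpan + 400 else
    200 + coreSpan + D + lens[["immune"]] +
      (if (topology == "circular") D else 200) + 200
  L <- .sampleContigLength(cfg, needed)

  casStart <- if (coloc) {
    200L + sample.int(max(1L, L - as.integer(coreSpan) - 400L + 1L), 1L) - 1L
  } else {
    200L + sample.int(201L, 1L) - 1L
  }
  pos <- casStart
  gs <- integer(0); gePos <- integer(0); roleAt <- character(0)
  for (j in seq_along(ord)) {
    gs <- c(gs, pos); gePos <- c(gePos, pos + lens[[ord[j]]])
    roleAt <- c(roleAt, ord[j])
    pos <- pos + lens[[ord[j]]] + gaps[j]
  }
  names(gs) <- names(gePos) <- roleAt
  casEnd <- max(gePos)
  trStart <- gePos[["rt"]] + 20L
  trEnd <- trStart + 90L
  casEnd <- max(casEnd, trEnd)

  if (!coloc) {
    immLen <- lens[["immune"]]
    lo <- as.integer(casEnd + D)
    hi <- if (topology == "circular")
      as.integer(L - D + casStart - immLen) else
      as.integer(L - 200L - immLen)
    immStart <- lo + sample.int(max(1L, hi - lo + 1L), 1L) - 1L
    gs <- c(gs, immune = immStart)
    gePos <- c(gePos, immune = immStart + immLen)
    strands <- c(strands, immune = "+")
  }
  vrEnd <- gePos[["target"]] - 60L
  vrStart <- vrEnd - 90L

  islandStart <- casStart - cfg@islandFlank
  islandEnd <- casEnd + cfg@islandFlank
  if (topology == "linear") {
    islandStart <- max(0, islandStart)
    islandEnd <- min(L, islandEnd)
  }

  # decoys, uniform in the remaining space
  nDecoy <- stats::rpois(1, cfg@backgroundPfamRate * L / 1000)
  occS <- c(unname(gs), trStart); occE <- c(unname(gePos), trEnd)
  dS <- integer(0); dE <- integer(0); dPf <- character(0)
  dStr <- character(0)
  for (k in seq_len(nDecoy)) {
    len <- .randGeneLen()
    slot <- .freePlace(occS, occE, L, len)
    if (is.null(slot)) next
    dS <- c(dS, slot[1]); dE <- c(dE, slot[2])
    occS <- c(occS, slot[1]); occE <- c(occE, slot[2])
    dPf <- c(dPf, .decoyPfams[sample.int(length(.decoyPfams), 1L)])
    dStr <- c(dStr, sample(c("+", "-"), 1L))
  }

  roles <- c(names(gs), rep("decoy", length(dS)))
  starts <- c(unname(gs), dS)
  ends <- c(unname(gePos), dE)
  strs <- c(unname(strands[names(gs)]), dStr)
  pfams <- c(unname(.simPfams[names(gs)]), dPf)
  ordGenes <- order(starts)
  roles <- roles[ordGenes]; starts <- starts[ordGenes]
  ends <- ends[ordGenes]; strs <- strs[ordGenes]; pfams <- pfams[ordGenes]
  contigId <- sprintf("contig_%04d", i)
  geneIds <- sprintf("%s_g%03d", contigId, seq_along(starts))

  inIsland <- intervalsWithinRegion(islandStart, islandEnd, starts, ends,
                                    L, topology == "circular")

  clade <- sample.int(6L, 1L, prob = cfg@cladeWeights)
  taxon <- if (stats::runif(1) < cfg@taxonCladeBias) .simTaxa[clade] else
    .simTaxa[sample.int(6L, 1L)]
  residence <- if (stats::runif(1) < cfg@pViral) "viral" else "cellular"

  seqStr <- NULL
  if (cfg@emitSequences) {
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    for (j in seq_along(starts)) {
      usage <- if (inIsland[j]) skewUsage else bgUsage
      aa <- aaLetters[sample.int(length(aaLetters),
                                 (ends[j] - starts[j]) %/% 3L,
                                 replace = TRUE)]
      cs <- sampleCodons(aa, usage)
      if (strs[j] == "-") cs <- revComp(cs)
      base[(starts[j] + 1L):ends[j]] <- strsplit(cs, "")[[1]]
    }
    trSeq <- sample(c("A", "C", "G", "T"), trEnd - trStart, replace = TRUE)
    base[(trStart + 1L):trEnd] <- trSeq
    # VR = TR copy with adenine-position substitutions
    vrSeq <- trSeq
    aPos <- which(vrSeq == "A")
    if (length(aPos))
      vrSeq[aPos] <- sample(c("C", "G", "T"), length(aPos), replace = TRUE)
    base[(vrStart + 1L):vrEnd] <- vrSeq
    seqStr <- paste(base, collapse = "")
  }

  rtGene <- geneIds[roles == "rt"]
  tgtGene <- geneIds[roles == "target"]
  immGene <- geneIds[roles == "immune"]
  plantedKeys <- sort(c("PF90001", "PF90002:VR", "PF90003",
                        if (coloc) "PF90101"))
  list(
    contig = data.frame(contig_id = contigId, length = L,
                        topology = topology, residence = residence,
                        taxon = taxon, stringsAsFactors = FALSE),
    genes = data.frame(gene_id = geneIds, contig_id = contigId,
                       start = starts, end = ends, strand = strs,
                       stringsAsFactors = FALSE),
    hits = data.frame(gene_id = geneIds, accession = pfams,
                      evalue = signif(10^-stats::runif(length(pfams), 5, 30), 3),
                      start_aa = NA_integer_, end_aa = NA_integer_,
                      stringsAsFactors = FALSE),
    system = data.frame(system_id = paste0("dgr_", contigId),
                        contig_id = contigId, rt_gene_id = rtGene,
                        tr_start = trStart, tr_end = trEnd, clade = clade,
                        stringsAsFactors = FALSE),
    vr = data.frame(system_id = paste0("dgr_", contigId), start = vrStart,
                    end = vrEnd, host_gene_id = tgtGene,
                    stringsAsFactors = FALSE),
    truthContig = data.frame(
      contig_id = contigId, length = L, topology = topology,
      residence = residence, clade = clade, taxon = taxon,
      immune_colocalized = coloc, arrangement_canonical = canonical,
      island_start = islandStart, island_end = islandEnd,
      immune_gene_id = immGene,
      planted_keys = paste(plantedKeys, collapse = "+"),
      stringsAsFactors = FALSE),
    truthGenes = data.frame(gene_id = geneIds, contig_id = contigId,
                            role = roles, island = inIsland,
                            stringsAsFactors = FALSE),
    seqStr = seqStr)
}

#' Simulate an annotated contig dataset with ground truth
#'
#' @param config a \code{\link{DgrSimConfig-class}} object.
#' @return list with elements \code{dataset} (a \code{DgrDataset}),
#'   \code{truth} (list of data.frames \code{contigs} and \code{genes}),
#'   \code{immuneCatalog} (the planted immune accession) and
#'   \code{config}.
#' @examples
#' sim <- simulateDataset(dgrSimConfig(nContigs = 3, emitSequences = FALSE,
#'                                     seed = 7))
#' sim$dataset
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "DgrSimConfig"))
  validObject(config)
  set.seed(config@seed)
  bgUsage <- codonUsageTable(0)
  skewUsage <- codonUsageTable(config@codonShiftDelta)
  aaLetters <- names(bgUsage)
  parts <- lapply(seq_len(config@nContigs), function(i)
    .simContig(config, i, bgUsage, skewUsage, aaLetters))
  bind <- function(field) {
    out <- do.call(rbind, lapply(parts, `[[`, field))
    rownames(out) <- NULL
    out
  }
  seqs <- NULL
  if (config@emitSequences) {
    seqs <- Biostrings::DNAStringSet(vapply(parts, `[[`, character(1),
                                            "seqStr"))
    names(seqs) <- vapply(parts, function(p) p$contig$contig_id,
                          character(1))
  }
  dataset <- DgrDataset(bind("contig"), bind("genes"), bind("hits"),
                        bind("system"), bind("vr"), sequences = seqs)
  list(dataset = dataset,
       truth = list(contigs = bind("truthContig"),
                    genes = bind("truthGenes")),
       immuneCatalog = "PF90101",
       config = config)
}

#' Ground-truth canonical arrangement signature of the planted cassette
#'
#' The canonical planted order is immune, accessory, RT, VR-target, all on
#' the forward strand; this returns its canonical signature for comparison
#' with \code{\link{arrangementProfile}} output.
#'
#' @return canonical signature string.
#' @export
plantedSignature <- function() {
  canonicalSignature(c("PF90101", "PF90003", "PF90001", "PF90002:VR"),
                     rep("+", 4))
}

#' Write a simulation to a directory
#'
#' Emits the \code{\link{writeDataset}} layout plus
#' \code{ground_truth_contigs.tsv}, \code{ground_truth_genes.tsv} and
#' \code{immune_pfams.txt}.
#'
#' @param sim result of \code{\link{simulateDataset}}.
#' @param dir output directory.
#' @return invisibly, \code{dir}.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeDataset(sim$dataset, dir)
  writeTable(sim$truth$contigs, file.path(dir, "ground_truth_contigs.tsv"))
  writeTable(sim$truth$genes, file.path(dir, "ground_truth_genes.tsv"))
  writeImmuneCatalog(sim$immuneCatalog, file.path(dir, "immune_pfams.txt"))
  invisible(dir)
}
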