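# Fixtures and independent oracles built in code. The oracles deliberately
# use naive scalar loops and hardcoded tables so they share no code path
# with the package implementation they check.

# --- tiny dataset builders ------------------------------------------------

# one-contig dataset builder with free-form genes
makeContigDataset <- function(contigId = "c1", length = 40000,
                              topology = "linear", genes, hits = NULL,
                              systems = NULL, vr = NULL,
                              residence = "unknown", taxon = "unknown") {
  co <- data.frame(contig_id = contigId, length = length,
                   topology = topology, residence = residence,
                   taxon = taxon, stringsAsFactors = FALSE)
  DgrDataset(co, genes, hits, systems, vr)
}

# n small contigs, each with an RT bait gene plus companion genes at fixed
# offsets; `extras` is a list (one element per contig) of character vectors
# of companion Pfam accessions placed at successive 1 kbp offsets
makeBaitFixture <- function(extras, L = 30000, withFar = character(0)) {
  n <- length(extras)
  co <- data.frame(contig_id = paste0("c", seq_len(n)), length = L,
                   topology = "linear", residence = "unknown",
                   taxon = "unknown", stringsAsFactors = FALSE)
  ge <- list(); ph <- list(); sy <- list()
  for (i in seq_len(n)) {
    cid <- paste0("c", i)
    rtId <- paste0(cid, "_rt")
    rows <- data.frame(gene_id = rtId, contig_id = cid, start = 1000L,
                       end = 1900L, strand = "+", stringsAsFactors = FALSE)
    hits <- data.frame(gene_id = rtId, accession = "PF90001.1",
                       evalue = 1e-20, stringsAsFactors = FALSE)
    for (j in seq_along(extras[[i]])) {
      gid <- paste0(cid, "_g", j)
      s <- 3000L + (j - 1L) * 1000L
      rows <- rbind(rows, data.frame(gene_id = gid, contig_id = cid,
                                     start = s, end = s + 900L,
                                     strand = "+",
                                     stringsAsFactors = FALSE))
      hits <- rbind(hits, data.frame(gene_id = gid,
                                     accession = extras[[i]][j],
                                     evalue = 1e-10,
                                     stringsAsFactors = FALSE))
    }
    ge[[i]] <- rows; ph[[i]] <- hits
    sy[[i]] <- data.frame(system_id = paste0("sys", i), contig_id = cid,
                          rt_gene_id = rtId, tr_start = 2000L,
                          tr_end = 2100L, clade = 1L,
                          stringsAsFactors = FALSE)
  }
  ge <- do.call(rbind, ge); ph <- do.call(rbind, ph)
  # far genes: outside every neighborhood (>10 kbp from any bait)
  for (acc in withFar) {
    gid <- paste0("far_", acc)
    ge <- rbind(ge, data.frame(gene_id = gid, contig_id = "c1",
                               start = 25000L, end = 25900L, strand = "+",
                               stringsAsFactors = FALSE))
    ph <- rbind(ph, data.frame(gene_id = gid, accession = acc,
                               evalue = 1e-10, stringsAsFactors = FALSE))
  }
  DgrDataset(co, ge, ph, do.call(rbind, sy))
}

# --- brute-force Icity oracle --------------------------------------------

# naive scalar reimplementation of neighborhood membership, fingerprint
# dereplication and the weighted w'/w count for one bait kind
bruteIcity <- function(dataset, key, D, kind) {
  co <- contigTable(dataset)
  ge <- geneTable(dataset)
  ph <- pfamHitTable(dataset)
  sy <- dgrSystemTable(dataset)
  vr <- vrIntervalTable(dataset)

  keyOf <- function(gid) {
    accs <- unique(sub("\\.[0-9]+$", "", ph$accession[ph$gene_id == gid]))
    if (!length(accs)) return(character(0))
    isVr <- ge$contains_vr[ge$gene_id == gid]
    paste0(accs, if (isVr) ":VR" else "")
  }
  overlaps1 <- function(a1, a2, b1, b2) max(a1, b1) < min(a2, b2)
  memberOf <- function(ws, we, gs, geEnd, L, circ) {
    if (!circ) return(overlaps1(max(0, ws), min(L, we), gs, geEnd))
    if (we - ws >= L) return(TRUE)
    ws0 <- ws %% L
    we0 <- ws0 + (we - ws)
    any(vapply(c(-1, 0, 1), function(k)
      overlaps1(ws0, we0, gs + k * L, geEnd + k * L), logical(1)))
  }
  baitRows <- if (kind == "RT") {
    data.frame(gene = sy$rt_gene_id, system = sy$system_id,
               stringsAsFactors = FALSE)
  } else {
    unique(data.frame(gene = vr$host_gene_id, system = vr$system_id,
                      stringsAsFactors = FALSE))
  }
  if (nrow(baitRows)) {
    bc <- ge$contig_id[match(baitRows$gene, ge$gene_id)]
    baitRows <- baitRows[order(bc, baitRows$gene, baitRows$system), ,
                         drop = FALSE]
  }
  nbs <- list()
  for (b in seq_len(nrow(baitRows))) {
    bi <- which(ge$gene_id == baitRows$gene[b])
    ci <- which(co$contig_id == ge$contig_id[bi])
    ws <- ge$start[bi] - D; we <- ge$end[bi] + D
    circ <- co$topology[ci] == "circular"
    members <- character(0)
    for (g in which(ge$contig_id == co$contig_id[ci])) {
      if (memberOf(ws, we, ge$start[g], ge$end[g], co$length[ci], circ))
        members <- c(members, ge$gene_id[g])
    }
    nbs[[b]] <- members
  }
  fp <- vapply(nbs, function(members) {
    idx <- match(members, ge$gene_id)
    members <- members[order(ge$start[idx], members)]
    paste(vapply(members, function(g)
      paste(sort(keyOf(g)), collapse = ","), character(1)),
      collapse = "|")
  }, character(1))
  weights <- stats::setNames(rep(1, nrow(ge)), ge$gene_id)
  seen <- character(0)
  for (b in seq_along(nbs)) {
    for (g in nbs[[b]]) {
      if (g %in% seen) next
      weights[g] <- 1 / sum(fp == fp[b])
      seen <- c(seen, g)
    }
  }
  carriers <- unique(ph$gene_id[vapply(ph$gene_id, function(g)
    key %in% keyOf(g), logical(1))])
  if (!length(carriers)) return(NA_real_)
  inside <- carriers %in% unique(unlist(nbs))
  sum(weights[carriers][inside]) / sum(weights[carriers])
}

# --- Nc oracle ------------------------------------------------------------

# standard-code synonymous families, hardcoded (independent of
# Biostrings::GENETIC_CODE)
.oracleFamilies <- list(
  c("TTT", "TTC"), c("TAT", "TAC"), c("CAT", "CAC"), c("CAA", "CAG"),
  c("AAT", "AAC"), c("AAA", "AAG"), c("GAT", "GAC"), c("GAA", "GAG"),
  c("TGT", "TGC"),
  c("ATT", "ATC", "ATA"),
  c("GTT", "GTC", "GTA", "GTG"), c("CCT", "CCC", "CCA", "CCG"),
  c("ACT", "ACC", "ACA", "ACG"), c("GCT", "GCC", "GCA", "GCG"),
  c("GGT", "GGC", "GGA", "GGG"),
  c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
  c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"))

oracleNc <- function(nt) {
  codons <- substring(nt, seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))
  Fs <- list()
  for (fam in .oracleFamilies) {
    n <- sum(codons %in% fam)
    if (n < 2) next
    p <- vapply(fam, function(cd) sum(codons == cd), numeric(1)) / n
    Fv <- (n * sum(p^2) - 1) / (n - 1)
    if (Fv <= 0) next
    k <- as.character(length(fam))
    Fs[[k]] <- c(Fs[[k]], Fv)
  }
  f2 <- mean(Fs[["2"]]); f4 <- mean(Fs[["4"]]); f6 <- mean(Fs[["6"]])
  f3 <- if (is.null(Fs[["3"]])) mean(c(f2, f4)) else mean(Fs[["3"]])
  min(61, max(20, 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6))
}

# fixed 600 nt toy ORF used for the frozen-value Nc check
toyOrf <- paste0(
  "GTTGAAACTTTAAACCTCGAAGAGTGGGCTTCTAAATTTATTTATATGCAAAAATGTAACTGGTTGTTTACT",
  "TGTTCTAACTTTATTAAAGACGGGAGCATGTGTAAGCACGAATTTGATTTACAAGTAACTTGTTTACCCAAT",
  "AAGAAATCAGTGACGAACAAATGGTTTTGCATGTTACATGTCTATGGCTATATGGACTTCTGTTGTAAGACT",
  "AAAGCATATTATCCCGAACAAATCACTTGCCATCGCCAACGTACCTCCAATTTTAACTGGCACGGCTGGTTA",
  "TGGGTTTGGATGGAAGCGGCTATGGGTGTTCGAATTAGCCACATGGTTATGCTCACATCTTGGAAAATGGGT",
  "CGAAACTGTTGTTTTGACGGTCAGTTATTAACTTTCTCATCTAACGGTCCTGAATGTAGTCAAGGCCGTATC",
  "TGGACTAGCGGGTCAACTTGGGGAGTTCGTCGTATTGGTAGCATGAACTACATGTGGACAACGTCGCGCCCG",
  "AAACGTGTCGTAAAATTTATTTGGAATTACATGCAGTGTGACTACCAAGAAGAACTCTGTCTCAGAGGATTA",
  "TGGTCTAAGATTGGTGCGTATTGT")

# md5 of every file under a directory, named by relative path
dirChecksums <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  stats::setNames(tools::md5sum(file.path(dir, files)), files)
}
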