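# Codon-usage-bias screen for recent horizontal transfer.
#
# For each DGR locus the putative system span extended by +/-E bp is
# compared against a control region of identical length on the most
# distant part of the same sequence (the antipodal region, assuming
# circularity; on linear contigs the control is placed as far in-bounds as
# possible). Pairs whose regions are separated by less than G_min bp are
# omitted. Per region, Wright's effective number of codons (Nc) is
# computed for every ORF longer than 360 nt, and the two per-ORF Nc
# distributions are compared with a two-sided two-sample
# Kolmogorov-Smirnov test (asymptotic p-value, alpha = 0.05).

#' Build the system/control region pair for one contig
#'
#' The system region is \code{[systemStart - E, systemEnd + E)}. On
#' circular contigs the control region has the same length with its
#' midpoint offset by half the contig length (modular); the gap between
#' the two arcs is then \code{(L - 2R)/2} on each side. On linear contigs
#' the control is placed at the farthest in-bounds position of equal
#' length. The pair is omitted when the gap is below \code{gMin} or the
#' regions cannot fit.
#'
#' @param contigLength contig length in bp.
#' @param topology \code{"linear"} or \code{"circular"}.
#' @param systemStart,systemEnd putative system span (0-based half-open).
#' @param E flank in bp (default 10000).
#' @param gMin minimum separation between the regions (default 20000).
#' @return list with elements \code{valid} (logical), \code{reason}
#'   (character, \code{NA} when valid), \code{system} and \code{control}
#'   (numeric length-2 start/end; control end may exceed the contig length
#'   when it wraps the origin) and \code{gap}.
#' @export
makeRegionPair <- function(contigLength, topology, systemStart, systemEnd,
                           E = 10000, gMin = 20000) {
  stopifnot(systemStart < systemEnd, topology %in% c("linear", "circular"))
  L <- contigLength
  omitted <- function(reason) list(valid = FALSE, reason = reason,
                                   system = NULL, control = NULL,
                                   gap = NA_real_)
  if (topology == "circular") {
    R <- (systemEnd - systemStart) + 2 * E
    if (2 * R > L) return(omitted("system region longer than half the contig"))
    sysRegion <- c(systemStart - E, systemEnd + E)
    mid <- (systemStart + systemEnd) / 2
    cm <- (mid + L / 2) %% L
    control <- c(cm - R / 2, cm + R / 2)
    gap <- (L - 2 * R) / 2
  } else {
    s0 <- max(0, systemStart - E)
    s1 <- min(L, systemEnd + E)
    R <- s1 - s0
    sysRegion <- c(s0, s1)
    mid <- (s0 + s1) / 2
    if (mid <= L / 2) {
      control <- c(L - R, L)
      gap <- control[1] - s1
    } else {
      control <- c(0, R)
      gap <- s0 - control[2]
    }
    if (gap < 0) return(omitted("control region overlaps system region"))
  }
  if (gap < gMin)
    return(omitted(sprintf("gap %.0f bp below minimum %d bp", gap, gMin)))
  list(valid = TRUE, reason = NA_character_, system = sysRegion,
       control = control, gap = gap)
}

#' Wright's effective number of codons (Nc)
#'
#' Computes Nc from the codon counts of one ORF. Per synonymous family
#' with n >= 2 observed codons, the codon homozygosity is estimated as
#' F = (n * sum(p_i^2) - 1)/(n - 1); families with a non-positive estimate
#' are excluded as uninformative. Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6 using
#' the mean F per degeneracy class (six-fold families form their own class,
#' which gives the 61-codon uniform limit Nc = 61). A missing 3-fold class
#' is imputed as the mean of the 2- and 4-fold class means; any other
#' entirely missing class uses the mean of the available classes. The
#' result is capped to [20, 61].
#'
#' @param counts named integer vector of codon counts (names are codons;
#'   stop codons and non-sense codons are ignored).
#' @return Nc value in [20, 61], with attribute \code{n_codons} (total
#'   sense codons counted).
#' @examples
#' cc <- codonCounts(strrep("GCTGCAGCGGCC", 30))  # uniform Ala usage
#' effectiveNumberOfCodons(cc)
#' @export
effectiveNumberOfCodons <- function(counts) {
  fams <- .codonFamilies()
  deg <- vapply(fams, length, integer(1))
  Fhat <- rep(NA_real_, length(fams))
  names(Fhat) <- names(fams)
  for (a in names(fams)) {
    cs <- fams[[a]]
    if (deg[[a]] == 1L) next
    cnt <- counts[cs]
    cnt[is.na(cnt)] <- 0
    n <- sum(cnt)
    if (n < 2) next
    p <- cnt / n
    Fhat[a] <- (n * sum(p^2) - 1) / (n - 1)
  }
  classMean <- function(k) {
    v <- Fhat[deg == k]
    v <- v[!is.na(v) & v > 0]
    if (length(v)) mean(v) else NA_real_
  }
  f2 <- classMean(2L); f3 <- classMean(3L)
  f4 <- classMean(4L); f6 <- classMean(6L)
  avail <- c(`2` = f2, `3` = f3, `4` = f4, `6` = f6)
  if (all(is.na(avail)))
    stop("no synonymous family with enough codons to estimate Nc")
  if (is.na(f3)) {
    f3 <- if (!is.na(f2) && !is.na(f4)) mean(c(f2, f4))
          else mean(avail, na.rm = TRUE)
  }
  fallback <- mean(avail, na.rm = TRUE)
  if (is.na(f2)) f2 <- fallback
  if (is.na(f4)) f4 <- fallback
  if (is.na(f6)) f6 <- fallback
  nc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  nc <- min(61, max(20, nc))
  attr(nc, "n_codons") <- sum(counts, na.rm = TRUE)
  nc
}

# extract a gene's coding sequence from its contig (strand-aware; modular
# for features wrapping a circular origin)
.geneSequence <- function(dataset, geneIdx) {
  ge <- dataset@genes[geneIdx, ]
  sq <- dataset@sequences[[ge$contig_id]]
  L <- length(sq)
  if (ge$end <= L) {
    s <- as.character(Biostrings::subseq(sq, ge$start + 1L, ge$end))
  } else {
    s <- paste0(as.character(Biostrings::subseq(sq, ge$start + 1L, L)),
                as.character(Biostrings::subseq(sq, 1L, ge$end - L)))
  }
  if (ge$strand == "-") s <- revComp(s)
  n <- (nchar(s) %/% 3L) * 3L
  substr(s, 1L, n)
}

#' Per-ORF Nc for genes inside a region
#'
#' @param dataset a \code{DgrDataset} with sequences.
#' @param contigId contig to scan.
#' @param region numeric length-2 region (0-based half-open; the end may
#'   exceed the contig length when the region wraps a circular origin).
#' @param minOrf minimum ORF length in nt, strict (default 360).
#' @return data.frame with columns \code{gene_id}, \code{nc},
#'   \code{n_codons}.
#' @export
ncForRegion <- function(dataset, contigId, region, minOrf = 360) {
  stopifnot(is(dataset, "DgrDataset"))
  if (!length(dataset@sequences) ||
      !contigId %in% names(dataset@sequences))
    stop("no sequence available for contig ", contigId)
  ge <- dataset@genes
  co <- dataset@contigs
  m <- match(contigId, co$contig_id)
  idx <- which(ge$contig_id == contigId)
  inside <- intervalsWithinRegion(region[1], region[2], ge$start[idx],
                                  ge$end[idx], co$length[m],
                                  co$topology[m] == "circular")
  long <- (ge$end[idx] - ge$start[idx]) > minOrf
  idx <- idx[inside & long]
  rows <- lapply(idx, function(i) {
    s <- .geneSequence(dataset, i)
    cc <- codonCounts(s)
    nc <- tryCatch(effectiveNumberOfCodons(cc), error = function(e) NULL)
    if (is.null(nc)) return(NULL)
    data.frame(gene_id = ge$gene_id[i], nc = as.numeric(nc),
               n_codons = attr(nc, "n_codons"), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(gene_id = character(0), nc = numeric(0),
                      n_codons = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Two-sample Kolmogorov-Smirnov comparison of Nc distributions
#'
#' Two-sided KS statistic; the p-value is exact for small tie-free
#' samples (the \code{stats::ks.test} default) and asymptotic otherwise,
#' which keeps the screen's type-I error calibrated at the region sample
#' sizes this analysis produces. Samples smaller than \code{minN} make
#' the outcome untestable (excluded from screen proportions).
#'
#' @param x,y numeric samples (per-ORF Nc values of the two regions).
#' @param alpha significance level (default 0.05).
#' @param minN minimum per-sample size (default 3).
#' @return one-row data.frame with columns \code{D}, \code{p_value},
#'   \code{n_system}, \code{n_control}, \code{significant},
#'   \code{testable}.
#' @export
ksTwoSample <- function(x, y, alpha = 0.05, minN = 3) {
  nx <- length(x); ny <- length(y)
  if (nx < minN || ny < minN) {
    return(data.frame(D = NA_real_, p_value = NA_real_, n_system = nx,
                      n_control = ny, significant = NA,
                      testable = FALSE))
  }
  kt <- suppressWarnings(stats::ks.test(x, y))
  data.frame(D = unname(kt$statistic), p_value = unname(kt$p.value),
             n_system = nx, n_control = ny,
             significant = kt$p.value < alpha, testable = TRUE)
}

# putative system span of one DGR system: RT gene, TR interval and VR host
# gene spans combined
.systemSpan <- function(dataset, systemId) {
  sy <- dataset@dgrSystems
  vr <- dataset@vrIntervals
  ge <- dataset@genes
  row <- sy[sy$system_id == systemId, ]
  rt <- ge[ge$gene_id == row$rt_gene_id, ]
  hosts <- ge[ge$gene_id %in% vr$host_gene_id[vr$system_id == systemId], ]
  starts <- c(rt$start, row$tr_start, hosts$start)
  ends <- c(rt$end, row$tr_end, hosts$end)
  c(min(starts), max(ends))
}

#' Codon-usage-bias screen across selected compositions
#'
#' For every member locus of every composition, builds the system/control
#' region pair, computes per-ORF Nc in both regions and runs the KS test;
#' reports per-composition the fraction of testable loci with a
#' significant difference (KS p < alpha). Omitted (gap too small) and
#' untestable (too few ORFs) loci are excluded from the denominator.
#'
#' @param dataset a \code{DgrDataset} with sequences.
#' @param compositions a \code{CompositionSet} (typically after
#'   \code{\link{selectCompositions}}).
#' @param E region flank in bp (default 10000).
#' @param gMin minimum region separation in bp (default 20000).
#' @param minOrf minimum ORF length in nt (default 360).
#' @param alpha significance level (default 0.05).
#' @param minN minimum per-region ORF count for a testable KS (default 3).
#' @return list with data.frames \code{perLocus} (one row per member
#'   locus: region geometry, sample sizes, D, p, status) and
#'   \code{perComposition} (composition, n_tested, n_significant,
#'   prop_significant; \code{NA} proportion when nothing was testable).
#' @export
biasScreen <- function(dataset, compositions, E = 10000, gMin = 20000,
                       minOrf = 360, alpha = 0.05, minN = 3) {
  stopifnot(is(dataset, "DgrDataset"), is(compositions, "CompositionSet"))
  loci <- compositions@loci
  co <- dataset@contigs
  rows <- list()
  ncRows <- list()
  for (i in seq_len(nrow(loci))) {
    sid <- loci$system_id[i]
    ci <- loci$contig_id[i]
    m <- match(ci, co$contig_id)
    span <- .systemSpan(dataset, sid)
    rp <- makeRegionPair(co$length[m], co$topology[m], span[1], span[2],
                         E = E, gMin = gMin)
    base <- data.frame(composition = loci$composition[i], system_id = sid,
                       contig_id = ci, stringsAsFactors = FALSE)
    if (!rp$valid) {
      rows[[i]] <- cbind(base, data.frame(
        status = "omitted", reason = rp$reason, gap = NA_real_,
        D = NA_real_, p_value = NA_real_, n_system = NA_integer_,
        n_control = NA_integer_, significant = NA))
      next
    }
    ncSys <- ncForRegion(dataset, ci, rp$system, minOrf = minOrf)
    ncCtl <- ncForRegion(dataset, ci, rp$control, minOrf = minOrf)
    if (nrow(ncSys)) ncSys$region <- "system"
    if (nrow(ncCtl)) ncCtl$region <- "control"
    ncAll <- rbind(ncSys, ncCtl)
    if (nrow(ncAll)) {
      ncAll$system_id <- sid
      ncAll$contig_id <- ci
      ncRows[[length(ncRows) + 1L]] <- ncAll
    }
    ks <- ksTwoSample(ncSys$nc, ncCtl$nc, alpha = alpha, minN = minN)
    rows[[i]] <- cbind(base, data.frame(
      status = if (ks$testable) "tested" else "untestable",
      reason = NA_character_, gap = rp$gap, D = ks$D,
      p_value = ks$p_value, n_system = ks$n_system,
      n_control = ks$n_control, significant = ks$significant))
  }
  perLocus <- if (length(rows)) do.call(rbind, rows) else
    data.frame(composition = character(0), system_id = character(0),
               contig_id = character(0), status = character(0),
               reason = character(0), gap = numeric(0), D = numeric(0),
               p_value = numeric(0), n_system = integer(0),
               n_control = integer(0), significant = logical(0))
  rownames(perLocus) <- NULL
  perComposition <- do.call(rbind, lapply(
    split(perLocus, perLocus$composition), function(d) {
      tested <- d$status == "tested"
      data.frame(composition = d$composition[1],
                 n_loci = nrow(d),
                 n_tested = sum(tested),
                 n_significant = sum(d$significant[tested]),
                 prop_significant = if (any(tested))
                   mean(d$significant[tested]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  if (is.null(perComposition)) {
    perComposition <- data.frame(composition = character(0),
                                 n_loci = integer(0), n_tested = integer(0),
                                 n_significant = integer(0),
                                 prop_significant = numeric(0))
  }
  rownames(perComposition) <- NULL
  perGene <- if (length(ncRows)) do.call(rbind, ncRows) else
    data.frame(gene_id = character(0), nc = numeric(0),
               n_codons = integer(0), region = character(0),
               system_id = character(0), contig_id = character(0))
  rownames(perGene) <- NULL
  list(perLocus = perLocus, perComposition = perComposition,
       perGene = perGene)
}
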