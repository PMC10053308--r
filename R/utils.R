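# Internal helpers shared across modules: Pfam accession handling,
# interval arithmetic on linear and circular contigs, genetic-code tables.
# All coordinates are 0-based half-open throughout the package.

#' Strip the version suffix from Pfam accessions
#'
#' Pfam accessions carry a version (\code{PF05635.13}); family identity must
#' not split on version, so comparisons are made on the version-stripped
#' accession.
#'
#' @param accession character vector of Pfam accessions.
#' @return character vector with any trailing \code{.NN} removed.
#' @examples
#' stripPfamVersion(c("PF05635.13", "PF00570"))
#' @export
stripPfamVersion <- function(accession) {
  sub("\\.[0-9]+$", "", accession)
}

.isPfamAccession <- function(accession) {
  grepl("^PF[0-9]{5}(\\.[0-9]+)?$", accession)
}

# A cluster key is a version-stripped Pfam accession, with VR-containing
# proteins segregated from their non-VR peers by a ":VR" suffix.
clusterKey <- function(accession, vrFlag) {
  paste0(stripPfamVersion(accession), ifelse(vrFlag, ":VR", ""))
}

clusterKeyAccession <- function(key) sub(":VR$", "", key)
clusterKeyIsVr <- function(key) grepl(":VR$", key)

# length of overlap between [a1,a2) and [b1,b2); vectorised
.overlapLen <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}

# Does each gene [gs,ge) overlap window [ws,we) by >= 1 bp on a contig of
# length L?  On circular contigs the window may run off either end (ws < 0
# or we > L) and genes are compared modulo L.
intervalsOverlapWindow <- function(ws, we, gs, ge, contigLength, circular) {
  if (!circular) {
    ws <- max(0, ws)
    we <- min(contigLength, we)
    return(.overlapLen(ws, we, gs, ge) > 0)
  }
  span <- we - ws
  if (span >= contigLength) {
    return(rep(TRUE, length(gs)))
  }
  ws0 <- ws %% contigLength
  we0 <- ws0 + span
  hit <- rep(FALSE, length(gs))
  for (k in c(-1, 0, 1)) {
    hit <- hit | .overlapLen(ws0, we0, gs + k * contigLength,
                             ge + k * contigLength) > 0
  }
  hit
}

# Is each gene [gs,ge) fully contained in region [rs,re) (re may exceed L
# on circular contigs)?
intervalsWithinRegion <- function(rs, re, gs, ge, contigLength, circular) {
  if (!circular) {
    return(gs >= rs & ge <= re)
  }
  rs0 <- rs %% contigLength
  re0 <- rs0 + (re - rs)
  inside <- rep(FALSE, length(gs))
  for (k in c(0, 1)) {
    inside <- inside | (gs + k * contigLength >= rs0 &
                        ge + k * contigLength <= re0)
  }
  inside
}

# --- genetic code ---------------------------------------------------------

# synonymous codon families of the standard code, stops excluded;
# names are one-letter amino acids, values are codon character vectors
.codonFamilies <- function() {
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  split(names(sense), unname(sense))
}

.senseCodons <- function() {
  gc <- Biostrings::GENETIC_CODE
  sort(names(gc)[gc != "*"])
}

#' Synonymous codon usage table
#'
#' Builds a per-amino-acid synonymous codon probability table for the
#' standard genetic code. With \code{delta = 0} usage is uniform within each
#' synonymous family; increasing \code{delta} concentrates mass on one codon
#' per family (at \code{delta = 1} each family uses a single codon, the
#' maximal-bias limit at which the effective number of codons is 20).
#'
#' @param delta skew magnitude in [0, 1].
#' @return named list (one-letter amino acid) of named probability vectors
#'   over that amino acid's codons, each summing to 1.
#' @examples
#' u <- codonUsageTable(0)
#' sum(u[["L"]])
#' @export
codonUsageTable <- function(delta = 0) {
  stopifnot(is.numeric(delta), length(delta) == 1, delta >= 0, delta <= 1)
  fams <- .codonFamilies()
  lapply(fams, function(cs) {
    k <- length(cs)
    p <- rep(1 / k, k)
    if (k > 1 && delta > 0) {
      p <- rep((1 - delta) / k, k)
      p[1] <- p[1] + delta
    }
    names(p) <- cs
    p
  })
}

# count codons of an in-frame coding sequence over the 61 sense codons;
# codons containing ambiguity characters are dropped, stop codons excluded
codonCounts <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq) %/% 3L
  if (n == 0L) {
    cod <- character(0)
  } else {
    starts <- 3L * (seq_len(n) - 1L) + 1L
    cod <- substring(seq, starts, starts + 2L)
  }
  sense <- .senseCodons()
  cod <- cod[cod %in% sense]
  counts <- table(factor(cod, levels = sense))
  stats::setNames(as.integer(counts), sense)
}

# reverse complement of a plain character DNA string
revComp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# deterministic TSV writers/readers used by every stage output
#' Write a stage table to TSV
#'
#' Writes a data.frame with a header row, tab separators, no quoting and no
#' row names, so that every stage output round-trips through
#' \code{\link{readTable}}.
#'
#' @param records data.frame to write.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeTable <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.table(records, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a stage table written by \code{writeTable}
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
readTable <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
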