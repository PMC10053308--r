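# Readers/writers for the pipeline's external formats: GFF3 gene calls,
# FASTA contig sequences, hmmscan --domtblout Pfam assignments, and the TSV
# tables used for contig metadata, DGR components and stage outputs.
# GFF3 is 1-based inclusive; conversion to the internal 0-based half-open
# convention happens here and only here.

#' Read gene features and contig metadata
#'
#' Reads gene/CDS records from a GFF3 file together with a contig metadata
#' TSV (columns \code{contig_id}, \code{length}, \code{topology}, optional
#' \code{residence}, \code{taxon}). GFF3 1-based inclusive coordinates are
#' converted to 0-based half-open. Every feature must reference a contig
#' present in the metadata table.
#'
#' @param gff3Path path to a GFF3 file with gene or CDS records.
#' @param contigTablePath path to the contig metadata TSV.
#' @return list with elements \code{contigs} and \code{genes} (data.frames
#'   in the \code{\link{DgrDataset}} slot schemas, minus \code{contains_vr},
#'   which is supplied by the DGR component table).
#' @export
readFeatures <- function(gff3Path, contigTablePath) {
  contigs <- readTable(contigTablePath)
  req <- c("contig_id", "length", "topology")
  if (!all(req %in% names(contigs)))
    stop("contig table must have columns: ", paste(req, collapse = ", "))
  if (is.null(contigs$residence)) contigs$residence <- "unknown"
  if (is.null(contigs$taxon)) contigs$taxon <- "unknown"

  gr <- rtracklayer::import(gff3Path, format = "gff3")
  if (length(gr)) {
    keep <- as.character(gr$type) %in% c("gene", "CDS")
    gr <- gr[keep]
  }
  if (length(gr) == 0L) {
    genes <- data.frame(gene_id = character(0), contig_id = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
    return(list(contigs = contigs, genes = genes))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("malformed strand in GFF3 (expected '+' or '-')")
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) stop("every GFF3 record needs an ID attribute")
  genes <- data.frame(
    gene_id = as.character(ids),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE)
  genes <- genes[!duplicated(genes$gene_id), , drop = FALSE]
  unknown <- setdiff(genes$contig_id, contigs$contig_id)
  if (length(unknown))
    stop("features reference contig(s) absent from the contig table: ",
         paste(unknown, collapse = ", "))
  rownames(genes) <- NULL
  list(contigs = contigs, genes = genes)
}

#' Read per-protein Pfam domain assignments
#'
#' Accepts either the hmmscan \code{--domtblout} dialect (whitespace
#' delimited, \code{#} comment lines; the query is the protein/gene id and
#' the target the Pfam model) or a simple TSV with columns \code{gene_id},
#' \code{accession}, \code{evalue}. Duplicate (gene, accession) rows are
#' retained; deduplication happens downstream at scoring time.
#'
#' @param path input file.
#' @param format \code{"domtblout"} or \code{"tsv"}.
#' @return data.frame with columns \code{gene_id}, \code{accession},
#'   \code{evalue}, \code{start_aa}, \code{end_aa}.
#' @export
readPfamHits <- function(path, format = c("domtblout", "tsv")) {
  format <- match.arg(format)
  empty <- data.frame(gene_id = character(0), accession = character(0),
                      evalue = numeric(0), start_aa = integer(0),
                      end_aa = integer(0), stringsAsFactors = FALSE)
  if (format == "tsv") {
    hits <- readTable(path)
    if (!nrow(hits)) return(empty)
    req <- c("gene_id", "accession", "evalue")
    if (!all(req %in% names(hits)))
      stop("pfam TSV must have columns: ", paste(req, collapse = ", "))
    if (is.null(hits$start_aa)) hits$start_aa <- NA_integer_
    if (is.null(hits$end_aa)) hits$end_aa <- NA_integer_
    return(hits[, c("gene_id", "accession", "evalue", "start_aa", "end_aa")])
  }
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(keep)) return(empty)
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 19L)
      stop("unparsable domtblout row at line ", i, ": expected >= 19 fields")
    ev <- suppressWarnings(as.numeric(f[7]))
    from <- suppressWarnings(as.integer(f[18]))
    to <- suppressWarnings(as.integer(f[19]))
    if (is.na(ev)) stop("unparsable E-value in domtblout at line ", i)
    data.frame(gene_id = f[4], accession = f[2], evalue = ev,
               start_aa = from, end_aa = to, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read the DGR component tables
#'
#' @param systemsPath TSV with columns \code{system_id}, \code{contig_id},
#'   \code{rt_gene_id}, \code{tr_start}, \code{tr_end}, \code{clade}
#'   (1-6, \code{NA} for unknown).
#' @param vrPath TSV with columns \code{system_id}, \code{start},
#'   \code{end}, \code{host_gene_id} (one row per VR interval).
#' @return list with data.frames \code{systems} and \code{vr}.
#' @export
readDgrSystems <- function(systemsPath, vrPath) {
  systems <- readTable(systemsPath)
  vr <- readTable(vrPath)
  req <- c("system_id", "contig_id", "rt_gene_id", "tr_start", "tr_end",
           "clade")
  if (!all(req %in% names(systems)))
    stop("DGR system table must have columns: ", paste(req, collapse = ", "))
  reqv <- c("system_id", "start", "end", "host_gene_id")
  if (!all(reqv %in% names(vr)))
    stop("VR interval table must have columns: ",
         paste(reqv, collapse = ", "))
  list(systems = systems, vr = vr)
}

#' Read an immune-Pfam catalog
#'
#' One Pfam accession per line; \code{#} starts a comment. Matching against
#' the catalog is version-agnostic, so accessions are stored with versions
#' stripped.
#'
#' @param path catalog file.
#' @return character vector of version-stripped accessions.
#' @export
readImmuneCatalog <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  acc <- trimws(lines)
  acc <- acc[nzchar(acc)]
  if (!length(acc)) stop("immune catalog is empty")
  bad <- !.isPfamAccession(acc)
  if (any(bad))
    stop("malformed accession(s) in immune catalog: ",
         paste(acc[bad], collapse = ", "))
  unique(stripPfamVersion(acc))
}

#' Assemble a DgrDataset from its on-disk inputs
#'
#' @param dir directory holding \code{contigs.tsv}, \code{genes.gff3},
#'   \code{pfam_hits.tsv}, \code{dgr_systems.tsv}, \code{vr_intervals.tsv}
#'   and optionally \code{contigs.fasta} (the layout written by
#'   \code{\link{writeDataset}}).
#' @return a \code{DgrDataset}.
#' @export
readDataset <- function(dir) {
  feat <- readFeatures(file.path(dir, "genes.gff3"),
                       file.path(dir, "contigs.tsv"))
  hits <- readPfamHits(file.path(dir, "pfam_hits.tsv"), format = "tsv")
  dgr <- readDgrSystems(file.path(dir, "dgr_systems.tsv"),
                        file.path(dir, "vr_intervals.tsv"))
  fa <- file.path(dir, "contigs.fasta")
  seqs <- if (file.exists(fa)) Biostrings::readDNAStringSet(fa) else NULL
  if (!is.null(seqs)) names(seqs) <- sub("\\s.*$", "", names(seqs))
  DgrDataset(feat$contigs, feat$genes, hits, dgr$systems, dgr$vr,
             sequences = seqs)
}

#' Write a DgrDataset to a directory
#'
#' Emits \code{contigs.tsv}, \code{genes.gff3} (1-based inclusive
#' coordinates), \code{pfam_hits.tsv}, \code{dgr_systems.tsv},
#' \code{vr_intervals.tsv} and, when sequences are present,
#' \code{contigs.fasta}. Output is deterministic so that reruns under a
#' fixed seed are byte-identical.
#'
#' @param x a \code{DgrDataset}.
#' @param dir output directory (created if absent).
#' @return invisibly, \code{dir}.
#' @export
writeDataset <- function(x, dir) {
  stopifnot(is(x, "DgrDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTable(x@contigs, file.path(dir, "contigs.tsv"))
  ge <- x@genes
  gff <- c("##gff-version 3",
           paste("##sequence-region", x@contigs$contig_id, 1,
                 x@contigs$length))
  if (nrow(ge)) {
    gff <- c(gff, paste(ge$contig_id, "dgrscan", "CDS", ge$start + 1L,
                        ge$end, ".", ge$strand, "0",
                        paste0("ID=", ge$gene_id), sep = "\t"))
  }
  writeLines(gff, file.path(dir, "genes.gff3"))
  hits <- x@pfamHits
  if (is.null(hits$start_aa)) hits$start_aa <- NA_integer_
  if (is.null(hits$end_aa)) hits$end_aa <- NA_integer_
  writeTable(hits, file.path(dir, "pfam_hits.tsv"))
  writeTable(x@dgrSystems, file.path(dir, "dgr_systems.tsv"))
  writeTable(x@vrIntervals, file.path(dir, "vr_intervals.tsv"))
  if (length(x@sequences)) {
    Biostrings::writeXStringSet(x@sequences, file.path(dir, "contigs.fasta"),
                                width = 80L)
  }
  invisible(dir)
}

#' Write an immune-Pfam catalog
#'
#' @param accessions character vector of Pfam accessions.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeImmuneCatalog <- function(accessions, path) {
  writeLines(c("# immune Pfam catalog", accessions), path)
  invisible(path)
}
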