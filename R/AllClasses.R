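#' @import methods
NULL

#' DgrDataset: annotated contigs with DGR components
#'
#' Central container for one analysis: contig metadata, gene features, Pfam
#' domain assignments, DGR component annotations (RT gene, TR interval, VR
#' intervals with their host genes, RT clade) and, optionally, the contig
#' nucleotide sequences. All coordinates are 0-based half-open. On circular
#' contigs a feature may wrap the origin and is then stored with
#' \code{start < length} and \code{end > length}.
#'
#' @slot contigs data.frame with columns \code{contig_id}, \code{length},
#'   \code{topology} (\code{linear}/\code{circular}), \code{residence}
#'   (\code{cellular}/\code{viral}/\code{unknown}), \code{taxon}.
#' @slot genes data.frame with columns \code{gene_id}, \code{contig_id},
#'   \code{start}, \code{end}, \code{strand} (\code{+}/\code{-}),
#'   \code{contains_vr} (logical; VR-containing proteins are scored apart
#'   from their non-VR peers of the same Pfam family).
#' @slot pfamHits data.frame with columns \code{gene_id}, \code{accession},
#'   \code{evalue} and optional \code{start_aa}, \code{end_aa}.
#' @slot dgrSystems data.frame with columns \code{system_id},
#'   \code{contig_id}, \code{rt_gene_id}, \code{tr_start}, \code{tr_end},
#'   \code{clade} (integer 1-6, NA for unknown).
#' @slot vrIntervals data.frame with columns \code{system_id}, \code{start},
#'   \code{end}, \code{host_gene_id}.
#' @slot sequences \code{DNAStringSet} of contig sequences (may be empty;
#'   names are contig ids).
#'
#' @export
setClass("DgrDataset",
  slots = c(
    contigs     = "data.frame",
    genes       = "data.frame",
    pfamHits    = "data.frame",
    dgrSystems  = "data.frame",
    vrIntervals = "data.frame",
    sequences   = "DNAStringSet"
  )
)

.validDgrDataset <- function(object) {
  msg <- character(0)
  co <- object@contigs
  ge <- object@genes
  ph <- object@pfamHits
  sy <- object@dgrSystems
  vr <- object@vrIntervals

  need <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      paste0(what, " lacks column(s): ", paste(missing, collapse = ", "))
    } else character(0)
  }
  msg <- c(msg,
    need(co, c("contig_id", "length", "topology", "residence", "taxon"),
         "contigs"),
    need(ge, c("gene_id", "contig_id", "start", "end", "strand",
               "contains_vr"), "genes"),
    need(ph, c("gene_id", "accession", "evalue"), "pfamHits"),
    need(sy, c("system_id", "contig_id", "rt_gene_id", "tr_start", "tr_end",
               "clade"), "dgrSystems"),
    need(vr, c("system_id", "start", "end", "host_gene_id"), "vrIntervals"))
  if (length(msg)) return(msg)

  if (anyDuplicated(co$contig_id)) msg <- c(msg, "duplicated contig ids")
  if (any(co$length < 1)) msg <- c(msg, "contig length must be >= 1")
  if (!all(co$topology %in% c("linear", "circular")))
    msg <- c(msg, "topology must be 'linear' or 'circular'")
  if (!all(co$residence %in% c("cellular", "viral", "unknown")))
    msg <- c(msg, "residence must be cellular/viral/unknown")

  if (nrow(ge)) {
    if (anyDuplicated(ge$gene_id)) msg <- c(msg, "duplicated gene ids")
    bad <- !(ge$contig_id %in% co$contig_id)
    if (any(bad))
      msg <- c(msg, paste0("genes on unknown contig(s): ",
                           paste(unique(ge$contig_id[bad]), collapse = ", ")))
    if (!all(ge$strand %in% c("+", "-")))
      msg <- c(msg, "gene strand must be '+' or '-'")
    len <- co$length[match(ge$contig_id, co$contig_id)]
    circ <- co$topology[match(ge$contig_id, co$contig_id)] == "circular"
    if (any(ge$start < 0 | ge$start >= ge$end))
      msg <- c(msg, "gene intervals must satisfy 0 <= start < end")
    overrun <- !is.na(len) & ge$end > len & !(circ & ge$start < len)
    if (any(overrun))
      msg <- c(msg, "gene end exceeds contig length on a linear contig")
  }
  if (nrow(ph)) {
    if (!all(.isPfamAccession(ph$accession)))
      msg <- c(msg, "malformed Pfam accession in pfamHits")
    if (any(ph$evalue < 0)) msg <- c(msg, "negative e-value in pfamHits")
    if (!all(ph$gene_id %in% ge$gene_id))
      msg <- c(msg, "pfamHits reference unknown gene ids")
  }
  if (nrow(sy)) {
    if (!all(sy$rt_gene_id %in% ge$gene_id))
      msg <- c(msg, "dgrSystems rt_gene_id not among genes")
    badClade <- !is.na(sy$clade) & !(sy$clade %in% 1:6)
    if (any(badClade)) msg <- c(msg, "clade must be 1-6 or NA")
  }
  if (nrow(vr)) {
    if (!all(vr$system_id %in% sy$system_id))
      msg <- c(msg, "vrIntervals reference unknown system ids")
    if (!all(vr$host_gene_id %in% ge$gene_id))
      msg <- c(msg, "VR host gene not among genes")
    hg <- match(vr$host_gene_id, ge$gene_id)
    inside <- vr$start >= ge$start[hg] & vr$end <= ge$end[hg] &
      vr$start < vr$end
    if (!all(inside))
      msg <- c(msg, "each VR interval must lie inside its host gene")
  }
  if (length(object@sequences)) {
    sn <- names(object@sequences)
    if (!all(sn %in% co$contig_id))
      msg <- c(msg, "sequence names not among contig ids")
    w <- Biostrings::width(object@sequences)
    expect <- co$length[match(sn, co$contig_id)]
    if (any(w != expect))
      msg <- c(msg, "sequence width disagrees with contig length")
  }
  if (length(msg)) msg else TRUE
}

setValidity("DgrDataset", .validDgrDataset)

#' Construct a DgrDataset
#'
#' @param contigs,genes,pfamHits,dgrSystems,vrIntervals data.frames as
#'   described for the class slots; missing optional metadata columns
#'   (\code{residence}, \code{taxon}) default to \code{"unknown"}, and a
#'   missing \code{contains_vr} column is derived from \code{vrIntervals}.
#' @param sequences optional \code{DNAStringSet} named by contig id.
#' @return a validated \code{DgrDataset}.
#' @examples
#' co <- data.frame(contig_id = "c1", length = 5000, topology = "linear")
#' ge <- data.frame(gene_id = "g1", contig_id = "c1", start = 0, end = 300,
#'                  strand = "+")
#' ds <- DgrDataset(co, ge)
#' nContigs(ds)
#' @export
DgrDataset <- function(contigs, genes = NULL, pfamHits = NULL,
                       dgrSystems = NULL, vrIntervals = NULL,
                       sequences = NULL) {
  contigs <- as.data.frame(contigs, stringsAsFactors = FALSE)
  if (is.null(contigs$residence)) contigs$residence <- "unknown"
  if (is.null(contigs$taxon)) contigs$taxon <- "unknown"
  contigs$residence[is.na(contigs$residence)] <- "unknown"
  contigs$taxon[is.na(contigs$taxon)] <- "unknown"
  contigs$length <- as.integer(contigs$length)

  emptyGenes <- data.frame(gene_id = character(0), contig_id = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0), contains_vr = logical(0),
                           stringsAsFactors = FALSE)
  genes <- if (is.null(genes) || !nrow(as.data.frame(genes))) emptyGenes
           else as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes)) {
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
  }

  emptyHits <- data.frame(gene_id = character(0), accession = character(0),
                          evalue = numeric(0), stringsAsFactors = FALSE)
  pfamHits <- if (is.null(pfamHits) || !nrow(as.data.frame(pfamHits)))
    emptyHits else as.data.frame(pfamHits, stringsAsFactors = FALSE)

  emptySys <- data.frame(system_id = character(0), contig_id = character(0),
                         rt_gene_id = character(0), tr_start = integer(0),
                         tr_end = integer(0), clade = integer(0),
                         stringsAsFactors = FALSE)
  dgrSystems <- if (is.null(dgrSystems) || !nrow(as.data.frame(dgrSystems)))
    emptySys else as.data.frame(dgrSystems, stringsAsFactors = FALSE)
  if (nrow(dgrSystems)) dgrSystems$clade <- as.integer(dgrSystems$clade)

  emptyVr <- data.frame(system_id = character(0), start = integer(0),
                        end = integer(0), host_gene_id = character(0),
                        stringsAsFactors = FALSE)
  vrIntervals <- if (is.null(vrIntervals) ||
                     !nrow(as.data.frame(vrIntervals)))
    emptyVr else as.data.frame(vrIntervals, stringsAsFactors = FALSE)

  if (is.null(genes$contains_vr)) {
    genes$contains_vr <- genes$gene_id %in% vrIntervals$host_gene_id
  }
  if (is.null(sequences)) sequences <- Biostrings::DNAStringSet()
  new("DgrDataset", contigs = contigs, genes = genes, pfamHits = pfamHits,
      dgrSystems = dgrSystems, vrIntervals = vrIntervals,
      sequences = sequences)
}

#' @describeIn DgrDataset-class number of contigs
#' @param x a \code{DgrDataset}
#' @export
nContigs <- function(x) nrow(x@contigs)

#' Accessors for DgrDataset slots
#'
#' @param x a \code{DgrDataset}.
#' @return the corresponding data.frame (or \code{DNAStringSet}).
#' @name dgr-accessors
NULL

#' @rdname dgr-accessors
#' @export
setGeneric("contigTable", function(x) standardGeneric("contigTable"))
#' @rdname dgr-accessors
#' @export
setMethod("contigTable", "DgrDataset", function(x) x@contigs)

#' @rdname dgr-accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname dgr-accessors
#' @export
setMethod("geneTable", "DgrDataset", function(x) x@genes)

#' @rdname dgr-accessors
#' @export
setGeneric("pfamHitTable", function(x) standardGeneric("pfamHitTable"))
#' @rdname dgr-accessors
#' @export
setMethod("pfamHitTable", "DgrDataset", function(x) x@pfamHits)

#' @rdname dgr-accessors
#' @export
setGeneric("dgrSystemTable", function(x) standardGeneric("dgrSystemTable"))
#' @rdname dgr-accessors
#' @export
setMethod("dgrSystemTable", "DgrDataset", function(x) x@dgrSystems)

#' @rdname dgr-accessors
#' @export
setGeneric("vrIntervalTable", function(x) standardGeneric("vrIntervalTable"))
#' @rdname dgr-accessors
#' @export
setMethod("vrIntervalTable", "DgrDataset", function(x) x@vrIntervals)

#' @rdname dgr-accessors
#' @export
setGeneric("contigSequences", function(x) standardGeneric("contigSequences"))
#' @rdname dgr-accessors
#' @export
setMethod("contigSequences", "DgrDataset", function(x) x@sequences)

setMethod("show", "DgrDataset", function(object) {
  cat("DgrDataset with", nrow(object@contigs), "contig(s),",
      nrow(object@genes), "gene(s),",
      nrow(object@pfamHits), "Pfam hit(s),",
      nrow(object@dgrSystems), "DGR system(s)\n")
  if (nrow(object@contigs)) {
    cat("  contig length range:", min(object@contigs$length), "-",
        max(object@contigs$length), "bp;",
        sum(object@contigs$topology == "circular"), "circular\n")
  }
  cat("  sequences:",
      if (length(object@sequences)) "present" else "absent", "\n")
})

#' Subset a DgrDataset to a set of contigs
#'
#' Keeps the given contigs and every gene, Pfam hit, DGR system and VR
#' interval on them. Used by the multi-run Icity protocol's per-run contig
#' subsampling.
#'
#' @param x a \code{DgrDataset}.
#' @param contigIds character vector of contig ids to keep.
#' @return a \code{DgrDataset}.
#' @export
subsetContigs <- function(x, contigIds) {
  stopifnot(is(x, "DgrDataset"))
  co <- x@contigs[x@contigs$contig_id %in% contigIds, , drop = FALSE]
  ge <- x@genes[x@genes$contig_id %in% contigIds, , drop = FALSE]
  ph <- x@pfamHits[x@pfamHits$gene_id %in% ge$gene_id, , drop = FALSE]
  sy <- x@dgrSystems[x@dgrSystems$contig_id %in% contigIds, , drop = FALSE]
  vr <- x@vrIntervals[x@vrIntervals$system_id %in% sy$system_id, ,
                      drop = FALSE]
  sq <- x@sequences[names(x@sequences) %in% contigIds]
  rownames(co) <- rownames(ge) <- rownames(ph) <- rownames(sy) <-
    rownames(vr) <- NULL
  new("DgrDataset", contigs = co, genes = ge, pfamHits = ph,
      dgrSystems = sy, vrIntervals = vr, sequences = sq)
}
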