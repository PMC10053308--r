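# Pfam composition assignment and gene-arrangement conservation.
#
# A composition is the set of selected (high-Icity) cluster keys found in
# one DGR locus's neighborhood; only loci carrying at least one immune Pfam
# are kept. Compositions encoded in more than 20 loci, at least four of
# which lie on contigs longer than 20 kbp, pass the selection filter.
# Arrangement analysis canonicalizes the ordered (Pfam, strand) signature
# of each locus for whole-locus orientation reversal: n Pfams admit
# 2^(n-1) * n! distinct arrangements.

#' CompositionSet: immune-Pfam compositions and their member loci
#'
#' @slot loci data.frame with columns \code{composition}, \code{system_id},
#'   \code{contig_id}, \code{long_contig} and list-column
#'   \code{member_gene_ids} (the locus neighborhood genes).
#' @slot summary data.frame with columns \code{composition}, \code{n_pfams},
#'   \code{n_occurrences}, \code{n_long_contigs}.
#' @slot keys named list: composition id -> character vector of cluster
#'   keys.
#' @slot immuneCatalog version-stripped immune accessions used.
#' @export
setClass("CompositionSet",
  slots = c(loci = "data.frame", summary = "data.frame", keys = "list",
            immuneCatalog = "character"))

setMethod("show", "CompositionSet", function(object) {
  cat("CompositionSet:", nrow(object@summary), "composition(s) over",
      nrow(object@loci), "DGR locus/loci\n")
  if (nrow(object@summary)) {
    cat("  occurrences per composition:",
        paste(range(object@summary$n_occurrences), collapse = "-"), "\n")
  }
})

#' @rdname CompositionSet-class
#' @param x a \code{CompositionSet}
#' @export
setGeneric("compositionSummary",
           function(x) standardGeneric("compositionSummary"))
#' @rdname CompositionSet-class
#' @export
setMethod("compositionSummary", "CompositionSet", function(x) x@summary)

#' @rdname CompositionSet-class
#' @export
setGeneric("compositionLoci", function(x) standardGeneric("compositionLoci"))
#' @rdname CompositionSet-class
#' @export
setMethod("compositionLoci", "CompositionSet", function(x) x@loci)

#' @rdname CompositionSet-class
#' @export
setGeneric("compositionKeys", function(x) standardGeneric("compositionKeys"))
#' @rdname CompositionSet-class
#' @export
setMethod("compositionKeys", "CompositionSet", function(x) x@keys)

#' Assign immune-Pfam compositions to DGR loci
#'
#' For every DGR system, collects the selected cluster keys carried by the
#' genes of its RT and VR neighborhoods; loci whose key set contains no
#' immune Pfam (version-agnostic catalog match) are dropped; identical key
#' sets are merged into one composition with occurrence and long-contig
#' counts.
#'
#' @param dataset a \code{DgrDataset}.
#' @param selectedKeys character vector of cluster keys that passed Icity
#'   selection (see \code{\link{selectPfams}}).
#' @param immuneCatalog character vector of immune Pfam accessions
#'   (versions ignored).
#' @param D neighborhood flank in bp.
#' @param lLong contig length above which a contig counts as long
#'   (default 20000, strict inequality).
#' @return a \code{\link{CompositionSet-class}} object.
#' @export
assignCompositions <- function(dataset, selectedKeys, immuneCatalog,
                               D = 10000, lLong = 20000) {
  stopifnot(is(dataset, "DgrDataset"), length(immuneCatalog) >= 1)
  immuneCatalog <- stripPfamVersion(immuneCatalog)
  nb <- extractNeighborhoods(dataset, D = D)
  gk <- geneClusterKeys(dataset)
  keyByGene <- split(gk$key, gk$gene_id)
  sy <- dataset@dgrSystems
  co <- dataset@contigs

  lociList <- list()
  keysBySystem <- list()
  for (i in seq_len(nrow(sy))) {
    sid <- sy$system_id[i]
    rows <- which(nb$system_id == sid)
    members <- unique(unlist(nb$member_gene_ids[rows]))
    keys <- sort(intersect(
      unique(unlist(keyByGene[members], use.names = FALSE)), selectedKeys))
    if (!length(keys)) next
    if (!any(clusterKeyAccession(keys) %in% immuneCatalog)) next
    compId <- paste(keys, collapse = "+")
    keysBySystem[[compId]] <- keys
    lociList[[length(lociList) + 1L]] <- data.frame(
      composition = compId, system_id = sid, contig_id = sy$contig_id[i],
      stringsAsFactors = FALSE)
    lociList[[length(lociList)]]$member_gene_ids <- list(members)
  }
  if (!length(lociList)) {
    loci <- data.frame(composition = character(0), system_id = character(0),
                       contig_id = character(0), long_contig = logical(0),
                       stringsAsFactors = FALSE)
    loci$member_gene_ids <- list()
    summary <- data.frame(composition = character(0), n_pfams = integer(0),
                          n_occurrences = integer(0),
                          n_long_contigs = integer(0),
                          stringsAsFactors = FALSE)
    return(new("CompositionSet", loci = loci, summary = summary,
               keys = list(), immuneCatalog = immuneCatalog))
  }
  loci <- do.call(rbind, lociList)
  loci$long_contig <-
    co$length[match(loci$contig_id, co$contig_id)] > lLong
  loci <- loci[order(loci$composition, loci$system_id), , drop = FALSE]
  rownames(loci) <- NULL

  summary <- do.call(rbind, lapply(split(loci, loci$composition),
    function(d) data.frame(
      composition = d$composition[1],
      n_pfams = length(keysBySystem[[d$composition[1]]]),
      n_occurrences = nrow(d),
      n_long_contigs = length(unique(d$contig_id[d$long_contig])),
      stringsAsFactors = FALSE)))
  summary <- summary[order(-summary$n_occurrences, summary$composition), ,
                     drop = FALSE]
  rownames(summary) <- NULL
  new("CompositionSet", loci = loci, summary = summary,
      keys = keysBySystem[summary$composition],
      immuneCatalog = immuneCatalog)
}

#' Filter compositions on occurrence and long-contig support
#'
#' Keeps compositions encoded in strictly more than \code{minOccurrences}
#' DGR loci, among which at least \code{minLong} distinct contigs are
#' longer than the long-contig cutoff.
#'
#' @param compositions a \code{CompositionSet}.
#' @param minOccurrences occurrence cutoff (strict >, default 20).
#' @param minLong minimum number of long member contigs (>=, default 4).
#' @return the filtered \code{CompositionSet}.
#' @export
selectCompositions <- function(compositions, minOccurrences = 20,
                               minLong = 4) {
  stopifnot(is(compositions, "CompositionSet"))
  s <- compositions@summary
  keep <- s$composition[s$n_occurrences > minOccurrences &
                        s$n_long_contigs >= minLong]
  loci <- compositions@loci[compositions@loci$composition %in% keep, ,
                            drop = FALSE]
  rownames(loci) <- NULL
  new("CompositionSet", loci = loci,
      summary = s[s$composition %in% keep, , drop = FALSE],
      keys = compositions@keys[keep],
      immuneCatalog = compositions@immuneCatalog)
}

#' Number of possible gene arrangements
#'
#' A system of n Pfams can be permuted n! ways with 2^n strand choices;
#' reading direction of the whole locus is arbitrary, so the total is
#' divided by two: 2^(n-1) * n! distinct arrangements (4 for n = 2, 24 for
#' n = 3).
#'
#' @param n number of Pfams (>= 1).
#' @return numeric count of distinct arrangements.
#' @examples
#' possibleArrangements(2)  # 4
#' possibleArrangements(3)  # 24
#' @export
possibleArrangements <- function(n) {
  if (any(n < 1) || any(n != round(n))) stop("n must be an integer >= 1")
  2^(n - 1) * factorial(n)
}

#' Canonical arrangement signature
#'
#' Reads gene labels and strands left-to-right along the locus and
#' normalizes for whole-locus orientation: the canonical form is the
#' lexicographic minimum of the signature and its reversal with all
#' strands flipped, so reverse-complementing the contig leaves it
#' unchanged.
#'
#' @param labels character vector of gene labels (cluster keys) in
#'   positional order.
#' @param strands character vector of \code{"+"}/\code{"-"}, same length.
#' @return single canonical signature string, elements joined by
#'   \code{"|"}.
#' @examples
#' canonicalSignature(c("A", "B"), c("+", "-"))
#' canonicalSignature(c("B", "A"), c("+", "-"))  # the flipped locus
#' @export
canonicalSignature <- function(labels, strands) {
  stopifnot(length(labels) == length(strands),
            all(strands %in% c("+", "-")))
  fwd <- paste(paste0(labels, strands), collapse = "|")
  flip <- ifelse(strands == "-", "+", "-")
  rev_ <- paste(paste0(rev(labels), rev(flip)), collapse = "|")
  min(fwd, rev_)
}

# signature of one locus: neighborhood genes restricted to the
# composition's keys, ordered along the contig; circular loci are
# linearized by breaking at the largest inter-gene gap
.locusSignature <- function(dataset, memberGeneIds, keys) {
  ge <- dataset@genes
  co <- dataset@contigs
  gk <- geneClusterKeys(dataset)
  keyByGene <- split(gk$key, gk$gene_id)
  lab <- vapply(memberGeneIds, function(g) {
    k <- sort(intersect(keyByGene[[g]], keys))
    if (length(k)) paste(k, collapse = ",") else NA_character_
  }, character(1))
  ids <- memberGeneIds[!is.na(lab)]
  lab <- lab[!is.na(lab)]
  if (!length(ids)) return(NA_character_)
  idx <- match(ids, ge$gene_id)
  ord <- order(ge$start[idx], ge$gene_id[idx])
  ids <- ids[ord]; lab <- lab[ord]; idx <- idx[ord]
  ci <- ge$contig_id[idx[1]]
  m <- match(ci, co$contig_id)
  if (co$topology[m] == "circular" && length(ids) > 1) {
    L <- co$length[m]
    starts <- ge$start[idx]; ends <- ge$end[idx]
    gaps <- c(starts[-1] - ends[-length(ends)],
              starts[1] + L - ends[length(ends)])
    cut <- which.max(gaps)
    if (cut < length(ids)) {
      rot <- c((cut + 1):length(ids), 1:cut)
      ids <- ids[rot]; lab <- lab[rot]; idx <- idx[rot]
    }
  }
  canonicalSignature(lab, ge$strand[idx])
}

#' Arrangement conservation profile per composition
#'
#' Tallies the canonical arrangement signatures of every member locus of
#' each composition. \code{modal_fraction} is the share of loci carrying
#' the most frequent signature (ties broken lexicographically);
#' \code{possible_count} is 2^(n-1) * n! for the composition's n Pfams.
#'
#' @param compositions a \code{CompositionSet}.
#' @param dataset the \code{DgrDataset} the compositions came from.
#' @return list with data.frames \code{arrangements} (composition,
#'   signature, count, fraction) and \code{modal} (composition,
#'   modal_signature, modal_fraction, n_loci, n_distinct, possible_count).
#' @export
arrangementProfile <- function(compositions, dataset) {
  stopifnot(is(compositions, "CompositionSet"), is(dataset, "DgrDataset"))
  loci <- compositions@loci
  arrRows <- list(); modRows <- list()
  for (comp in compositions@summary$composition) {
    d <- loci[loci$composition == comp, , drop = FALSE]
    keys <- compositions@keys[[comp]]
    sigs <- vapply(d$member_gene_ids, .locusSignature, character(1),
                   dataset = dataset, keys = keys)
    sigs <- sigs[!is.na(sigs)]
    if (!length(sigs)) next
    tab <- sort(table(sigs), decreasing = TRUE)
    sigNames <- names(tab)
    # deterministic tie-break: among max-count signatures pick lexicographic
    top <- sigNames[tab == max(tab)]
    modal <- min(top)
    arrRows[[comp]] <- data.frame(
      composition = comp, signature = sigNames,
      count = as.integer(tab), fraction = as.numeric(tab) / length(sigs),
      stringsAsFactors = FALSE)
    modRows[[comp]] <- data.frame(
      composition = comp, modal_signature = modal,
      modal_fraction = as.numeric(tab[[modal]]) / length(sigs),
      n_loci = length(sigs), n_distinct = length(tab),
      possible_count = possibleArrangements(length(keys)),
      stringsAsFactors = FALSE)
  }
  arrangements <- if (length(arrRows)) do.call(rbind, arrRows) else
    data.frame(composition = character(0), signature = character(0),
               count = integer(0), fraction = numeric(0))
  modal <- if (length(modRows)) do.call(rbind, modRows) else
    data.frame(composition = character(0), modal_signature = character(0),
               modal_fraction = numeric(0), n_loci = integer(0),
               n_distinct = integer(0), possible_count = numeric(0))
  rownames(arrangements) <- rownames(modal) <- NULL
  list(arrangements = arrangements, modal = modal)
}

#' Composition-by-Pfam membership matrix
#'
#' Upset-style 0/1 membership table: one row per composition, one column
#' per cluster key, plus the occurrence count.
#'
#' @param compositions a \code{CompositionSet}.
#' @return data.frame.
#' @export
upsetMatrix <- function(compositions) {
  stopifnot(is(compositions, "CompositionSet"))
  s <- compositions@summary
  allKeys <- sort(unique(unlist(compositions@keys)))
  m <- vapply(allKeys, function(k) {
    as.integer(vapply(s$composition,
                      function(cmp) k %in% compositions@keys[[cmp]],
                      logical(1)))
  }, integer(nrow(s)))
  out <- data.frame(composition = s$composition,
                    n_occurrences = s$n_occurrences,
                    stringsAsFactors = FALSE)
  if (nrow(s) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, allKeys))
  cbind(out, as.data.frame(m, optional = TRUE))
}
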