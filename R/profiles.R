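# Residence, RT-clade and taxon profiling of selected compositions, plus
# SVG gene-map export. Unknown labels are excluded from denominators and
# reported separately.

#' Residence profile per composition
#'
#' Counts cellular vs viral member loci of each composition and reports
#' the minority fraction min(cellular, viral)/(cellular + viral); unknowns
#' are excluded from the fraction and counted separately. A strongly
#' skewed minority fraction (well below the even 0.5) marks a composition
#' as predominantly cellular or predominantly viral.
#'
#' @param compositions a \code{CompositionSet}.
#' @param dataset the \code{DgrDataset}.
#' @return data.frame with columns \code{composition}, \code{n_cellular},
#'   \code{n_viral}, \code{n_unknown}, \code{minority_fraction} (\code{NA}
#'   when no labeled member exists).
#' @export
residenceProfile <- function(compositions, dataset) {
  stopifnot(is(compositions, "CompositionSet"), is(dataset, "DgrDataset"))
  loci <- compositions@loci
  co <- dataset@contigs
  res <- co$residence[match(loci$contig_id, co$contig_id)]
  out <- do.call(rbind, lapply(split(res, loci$composition), function(r) {
    nc <- sum(r == "cellular"); nv <- sum(r == "viral")
    data.frame(n_cellular = nc, n_viral = nv,
               n_unknown = sum(r == "unknown"),
               minority_fraction = if (nc + nv > 0) min(nc, nv) / (nc + nv)
                                   else NA_real_)
  }))
  out <- cbind(data.frame(composition = rownames(out),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out[match(compositions@summary$composition, out$composition), ,
      drop = FALSE]
}

#' RT-clade profile per composition
#'
#' @param compositions a \code{CompositionSet}.
#' @param dataset the \code{DgrDataset}.
#' @return data.frame with per-composition clade counts
#'   (\code{clade1..clade6}, \code{clade_unknown}), the modal clade, its
#'   fraction over known labels, and \code{single_clade} (TRUE iff all
#'   known-clade members share one clade).
#' @export
cladeProfile <- function(compositions, dataset) {
  stopifnot(is(compositions, "CompositionSet"), is(dataset, "DgrDataset"))
  loci <- compositions@loci
  sy <- dataset@dgrSystems
  clade <- sy$clade[match(loci$system_id, sy$system_id)]
  out <- do.call(rbind, lapply(split(clade, loci$composition),
    function(cl) {
      counts <- vapply(1:6, function(k) sum(!is.na(cl) & cl == k),
                       integer(1))
      known <- sum(counts)
      modal <- if (known) which.max(counts) else NA_integer_
      data.frame(t(stats::setNames(counts, paste0("clade", 1:6))),
                 clade_unknown = sum(is.na(cl)),
                 modal_clade = modal,
                 modal_clade_fraction = if (known) max(counts) / known
                                        else NA_real_,
                 single_clade = known > 0 && max(counts) == known)
    }))
  out <- cbind(data.frame(composition = rownames(out),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out[match(compositions@summary$composition, out$composition), ,
      drop = FALSE]
}

#' Taxon counts and clade-by-taxon matrix
#'
#' Tallies member loci per taxon across the given compositions and builds
#' the taxon x clade proportion matrix (rows sum to 1 over known clades).
#' Loci with unknown taxon are excluded from the matrix with a warning.
#'
#' @param compositions a \code{CompositionSet}.
#' @param dataset the \code{DgrDataset}.
#' @return list with \code{taxonCounts} (data.frame taxon, n) and
#'   \code{cladeByTaxon} (numeric matrix, taxa x clades 1-6).
#' @export
taxonProfile <- function(compositions, dataset) {
  stopifnot(is(compositions, "CompositionSet"), is(dataset, "DgrDataset"))
  loci <- compositions@loci
  co <- dataset@contigs
  sy <- dataset@dgrSystems
  taxon <- co$taxon[match(loci$contig_id, co$contig_id)]
  clade <- sy$clade[match(loci$system_id, sy$system_id)]
  keep <- taxon != "unknown"
  if (!all(keep) || !length(taxon))
    warning("loci with unknown taxon excluded from the clade-by-taxon matrix")
  taxonCounts <- as.data.frame(table(taxon = taxon),
                               stringsAsFactors = FALSE)
  names(taxonCounts) <- c("taxon", "n")
  tk <- taxon[keep & !is.na(clade)]
  ck <- clade[keep & !is.na(clade)]
  taxa <- sort(unique(tk))
  m <- matrix(0, length(taxa), 6,
              dimnames = list(taxa, paste0("clade", 1:6)))
  for (i in seq_along(tk)) m[tk[i], ck[i]] <- m[tk[i], ck[i]] + 1
  rs <- rowSums(m)
  m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  list(taxonCounts = taxonCounts, cladeByTaxon = m)
}

# deterministic color for a gene label within a composition
.mapPalette <- c("#4e79a7", "#f28e2b", "#59a14f", "#e15759", "#b07aa1",
                 "#76b7b2", "#edc948", "#9c755f", "#bab0ac", "#86bcb6")

# one gene arrow as an SVG polygon; minus-strand genes point left
.svgArrow <- function(x0, x1, y, h, fill, label, vrFlag, strand) {
  head <- min(10, (x1 - x0) / 2)
  pts <- if (strand == "+") {
    sprintf("%.1f,%.1f %.1f,%.1f %.1f,%.1f %.1f,%.1f %.1f,%.1f",
            x0, y - h / 2, x1 - head, y - h / 2, x1, y,
            x1 - head, y + h / 2, x0, y + h / 2)
  } else {
    sprintf("%.1f,%.1f %.1f,%.1f %.1f,%.1f %.1f,%.1f %.1f,%.1f",
            x1, y - h / 2, x0 + head, y - h / 2, x0, y,
            x0 + head, y + h / 2, x1, y + h / 2)
  }
  tag <- c(sprintf(
    '<polygon points="%s" fill="%s" stroke="black" stroke-width="0.5"/>',
    pts, fill))
  mid <- (x0 + x1) / 2
  if (nzchar(label))
    tag <- c(tag, sprintf(
      '<text x="%.1f" y="%.1f" font-size="7" text-anchor="middle">%s</text>',
      mid, y - h / 2 - 2, label))
  if (vrFlag)
    tag <- c(tag, sprintf(
      '<text x="%.1f" y="%.1f" font-size="7" font-weight="bold" text-anchor="middle">VR</text>',
      mid, y + h / 2 + 9))
  tag
}

#' Export per-composition gene maps as SVG
#'
#' Draws up to \code{maxLoci} member loci per composition: one row per
#' locus, genes as strand-oriented arrows in coordinate order. RT genes
#' are drawn white, genes of the same Pfam family share a color, and
#' VR-containing genes are flagged with a \code{VR} label. Layout is
#' deterministic.
#'
#' @param compositions a \code{CompositionSet}.
#' @param dataset the \code{DgrDataset}.
#' @param dir output directory for \code{map_<k>.svg} files.
#' @param maxLoci loci drawn per composition (default 5).
#' @return invisibly, character vector of written file paths.
#' @export
exportGeneMaps <- function(compositions, dataset, dir, maxLoci = 5) {
  stopifnot(is(compositions, "CompositionSet"), is(dataset, "DgrDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ge <- dataset@genes
  sy <- dataset@dgrSystems
  gk <- geneClusterKeys(dataset)
  keyByGene <- split(gk$key, gk$gene_id)
  paths <- character(0)
  comps <- compositions@summary$composition
  for (k in seq_along(comps)) {
    comp <- comps[k]
    keys <- compositions@keys[[comp]]
    fill <- stats::setNames(
      .mapPalette[((seq_along(keys) - 1) %% length(.mapPalette)) + 1], keys)
    d <- compositions@loci[compositions@loci$composition == comp, ,
                           drop = FALSE]
    d <- utils::head(d, maxLoci)
    rowH <- 46; width <- 760
    body <- character(0)
    for (j in seq_len(nrow(d))) {
      ids <- d$member_gene_ids[[j]]
      idx <- match(ids, ge$gene_id)
      idx <- idx[order(ge$start[idx], ge$gene_id[idx])]
      x0 <- min(ge$start[idx]); x1 <- max(ge$end[idx])
      scale <- (width - 120) / max(1, x1 - x0)
      y <- 30 + (j - 1) * rowH
      rtIds <- sy$rt_gene_id[sy$system_id == d$system_id[j]]
      body <- c(body, sprintf(
        '<text x="4" y="%.1f" font-size="8">%s</text>', y + 3,
        d$contig_id[j]))
      for (i in idx) {
        gx0 <- 110 + (ge$start[i] - x0) * scale
        gx1 <- 110 + (ge$end[i] - x0) * scale
        gkeys <- intersect(keyByGene[[ge$gene_id[i]]], keys)
        col <- if (ge$gene_id[i] %in% rtIds) "#ffffff"
               else if (length(gkeys)) fill[[sort(gkeys)[1]]]
               else "#d9d9d9"
        lab <- if (length(gkeys)) sort(gkeys)[1] else ""
        body <- c(body, .svgArrow(gx0, gx1, y, 14, col, lab,
                                  ge$contains_vr[i], ge$strand[i]))
      }
    }
    height <- 30 + nrow(d) * rowH
    svg <- c(sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
      width, height),
      sprintf('<text x="4" y="12" font-size="9">%s</text>', comp),
      body, "</svg>")
    path <- file.path(dir, sprintf("map_%02d.svg", k))
    writeLines(svg, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
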