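# Icity co-localization scoring around DGR baits.
#
# Proteins are clustered by version-stripped Pfam family, with VR-containing
# proteins segregated from their non-VR peers (cluster keys "PFxxxxx" vs
# "PFxxxxx:VR"). For each bait class (RT genes; VR host genes) a
# neighborhood is the bait gene span extended by D bp on each side (modular
# on circular contigs). The Icity score of a cluster is w'/w: the
# redundancy-weighted fraction of the cluster's members that fall inside at
# least one neighborhood. Redundancy weights dereplicate near-identical
# loci: neighborhoods sharing an identical ordered cluster-content
# fingerprint each contribute 1/(number of neighborhoods with that
# fingerprint) to their member genes.

# per-gene cluster keys, deduplicated (a gene carrying the same family
# twice counts once)
geneClusterKeys <- function(dataset) {
  ph <- dataset@pfamHits
  if (!nrow(ph)) {
    return(data.frame(gene_id = character(0), key = character(0),
                      stringsAsFactors = FALSE))
  }
  vr <- dataset@genes$contains_vr[match(ph$gene_id, dataset@genes$gene_id)]
  out <- data.frame(gene_id = ph$gene_id,
                    key = clusterKey(ph$accession, vr),
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Extract bait neighborhoods around DGR components
#'
#' One neighborhood per bait: each DGR system's RT gene and each VR host
#' gene. The window is the bait gene span extended by \code{D} bp on each
#' side; a gene is a member iff its interval overlaps the window by at
#' least 1 bp (window arithmetic is modular on circular contigs). The bait
#' gene is always a member of its own neighborhood.
#'
#' @param dataset a \code{DgrDataset}.
#' @param D flank size in bp (default 10000).
#' @return data.frame with columns \code{bait_kind} (\code{RT}/\code{VR}),
#'   \code{bait_gene_id}, \code{system_id}, \code{contig_id},
#'   \code{win_start}, \code{win_end} and list-column
#'   \code{member_gene_ids}.
#' @export
extractNeighborhoods <- function(dataset, D = 10000) {
  stopifnot(is(dataset, "DgrDataset"), D > 0)
  sy <- dataset@dgrSystems
  vr <- dataset@vrIntervals
  baits <- rbind(
    if (nrow(sy)) data.frame(bait_kind = "RT", bait_gene_id = sy$rt_gene_id,
                             system_id = sy$system_id,
                             stringsAsFactors = FALSE),
    if (nrow(vr)) unique(data.frame(bait_kind = "VR",
                                    bait_gene_id = vr$host_gene_id,
                                    system_id = vr$system_id,
                                    stringsAsFactors = FALSE)))
  empty <- data.frame(bait_kind = character(0), bait_gene_id = character(0),
                      system_id = character(0), contig_id = character(0),
                      win_start = numeric(0), win_end = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(baits) || !nrow(baits)) {
    empty$member_gene_ids <- list()
    return(empty)
  }
  ge <- dataset@genes
  co <- dataset@contigs
  gi <- match(baits$bait_gene_id, ge$gene_id)
  baits$contig_id <- ge$contig_id[gi]
  baits$win_start <- ge$start[gi] - D
  baits$win_end <- ge$end[gi] + D
  baits <- baits[order(baits$contig_id, baits$bait_kind,
                       baits$bait_gene_id, baits$system_id), , drop = FALSE]
  rownames(baits) <- NULL
  geneByContig <- split(seq_len(nrow(ge)), ge$contig_id)
  members <- vector("list", nrow(baits))
  for (i in seq_len(nrow(baits))) {
    ci <- baits$contig_id[i]
    idx <- geneByContig[[ci]]
    if (is.null(idx)) {
      members[[i]] <- character(0)
      next
    }
    m <- match(ci, co$contig_id)
    hit <- intervalsOverlapWindow(baits$win_start[i], baits$win_end[i],
                                  ge$start[idx], ge$end[idx],
                                  co$length[m],
                                  co$topology[m] == "circular")
    members[[i]] <- ge$gene_id[idx][hit]
  }
  baits$member_gene_ids <- members
  baits
}

# ordered cluster-content fingerprint of one neighborhood
.neighborhoodFingerprint <- function(memberIds, dataset, gkByGene) {
  ge <- dataset@genes
  idx <- match(memberIds, ge$gene_id)
  ord <- order(ge$start[idx], ge$gene_id[idx])
  ids <- memberIds[ord]
  elems <- vapply(ids, function(g) {
    keys <- gkByGene[[g]]
    if (is.null(keys)) "" else paste(sort(keys), collapse = ",")
  }, character(1))
  paste(elems, collapse = "|")
}

#' Redundancy weights from neighborhood fingerprints
#'
#' Groups neighborhoods by identical ordered cluster-content fingerprint;
#' every gene whose home neighborhood (the first neighborhood containing
#' it, in the deterministic neighborhood order) belongs to a group of
#' \code{k} neighborhoods receives weight \code{1/k}. Genes outside every
#' neighborhood get weight 1. This dereplicates overrepresented identical
#' loci before co-localization counting.
#'
#' @param neighborhoods output of \code{\link{extractNeighborhoods}}
#'   (possibly filtered to one bait kind).
#' @param dataset the \code{DgrDataset} the neighborhoods came from.
#' @return named numeric vector of weights in (0, 1], one per gene.
#' @export
redundancyWeights <- function(neighborhoods, dataset) {
  ge <- dataset@genes
  w <- stats::setNames(rep(1, nrow(ge)), ge$gene_id)
  if (!nrow(neighborhoods)) return(w)
  gk <- geneClusterKeys(dataset)
  gkByGene <- split(gk$key, gk$gene_id)
  fps <- vapply(neighborhoods$member_gene_ids, .neighborhoodFingerprint,
                character(1), dataset = dataset, gkByGene = gkByGene)
  fpCount <- table(fps)
  assigned <- character(0)
  for (i in seq_along(fps)) {
    ids <- setdiff(neighborhoods$member_gene_ids[[i]], assigned)
    if (!length(ids)) next
    w[ids] <- 1 / as.numeric(fpCount[[fps[i]]])
    assigned <- c(assigned, ids)
  }
  w
}

#' Icity score of one cluster
#'
#' Computes w'/w for a cluster key, where w is the summed redundancy weight
#' of every gene carrying the cluster and w' the summed weight of those of
#' its genes that are members of at least one neighborhood.
#'
#' @param key cluster key string (\code{"PFxxxxx"} or \code{"PFxxxxx:VR"}).
#' @param weights named weight vector from \code{\link{redundancyWeights}}.
#' @param neighborhoods neighborhoods data.frame.
#' @param dataset a \code{DgrDataset}.
#' @return score in [0, 1].
#' @export
icityScore <- function(key, weights, neighborhoods, dataset) {
  gk <- geneClusterKeys(dataset)
  ids <- unique(gk$gene_id[gk$key == key])
  if (!length(ids)) stop("cluster '", key, "' has no members in the dataset")
  inNb <- ids %in% unique(unlist(neighborhoods$member_gene_ids))
  w <- sum(weights[ids])
  wp <- sum(weights[ids][inNb])
  wp / w
}

# score every cluster key once against one bait kind's neighborhoods;
# returns data.frame(key, score, w, wp)
.scoreKind <- function(dataset, neighborhoods, kind) {
  nb <- neighborhoods[neighborhoods$bait_kind == kind, , drop = FALSE]
  gk <- geneClusterKeys(dataset)
  if (!nrow(gk)) {
    return(data.frame(key = character(0), score = numeric(0),
                      w = numeric(0), wp = numeric(0),
                      stringsAsFactors = FALSE))
  }
  weights <- redundancyWeights(nb, dataset)
  members <- unique(unlist(nb$member_gene_ids))
  gw <- weights[gk$gene_id]
  inNb <- gk$gene_id %in% members
  w <- tapply(gw, gk$key, sum)
  wp <- tapply(gw * inNb, gk$key, sum)
  data.frame(key = names(w), score = as.numeric(wp / w),
             w = as.numeric(w), wp = as.numeric(wp),
             stringsAsFactors = FALSE)
}

#' IcityTable: per-cluster multi-run Icity scores
#'
#' @slot keys data.frame with columns \code{key}, \code{accession},
#'   \code{vr_flag}.
#' @slot runScores numeric matrix, clusters x runs (NA when a cluster had
#'   no member in a run's contig subsample).
#' @slot meanScore per-cluster mean over runs (NA runs dropped).
#' @slot w,wPrime per-cluster mean weighted member count and weighted
#'   co-localized count over runs, taken from the bait kind that achieved
#'   the per-run maximum.
#' @slot nRuns number of runs performed.
#' @slot runSeeds integer seed used per run.
#' @slot threshold discovery threshold used for convergence.
#' @export
setClass("IcityTable",
  slots = c(keys = "data.frame", runScores = "matrix",
            meanScore = "numeric", w = "numeric", wPrime = "numeric",
            nRuns = "integer", runSeeds = "integer", threshold = "numeric"))

setMethod("show", "IcityTable", function(object) {
  cat("IcityTable:", nrow(object@keys), "cluster(s),", object@nRuns,
      "run(s), threshold", object@threshold, "\n")
  cat("  clusters with mean score > threshold:",
      sum(object@meanScore > object@threshold, na.rm = TRUE), "\n")
})

#' @rdname IcityTable-class
#' @param x an \code{IcityTable}
#' @export
setGeneric("meanScores", function(x) standardGeneric("meanScores"))
#' @rdname IcityTable-class
#' @export
setMethod("meanScores", "IcityTable",
          function(x) stats::setNames(x@meanScore, x@keys$key))

#' @rdname IcityTable-class
#' @export
setGeneric("runScores", function(x) standardGeneric("runScores"))
#' @rdname IcityTable-class
#' @export
setMethod("runScores", "IcityTable", function(x) x@runScores)

#' Flatten an IcityTable for TSV export
#'
#' @param x an \code{IcityTable}.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns \code{pfam}, \code{vr_flag},
#'   \code{run1..runK}, \code{mean}, \code{w}, \code{w_prime}.
#' @export
as.data.frame.IcityTable <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  runs <- x@runScores
  colnames(runs) <- paste0("run", seq_len(ncol(runs)))
  out <- data.frame(pfam = x@keys$accession, vr_flag = x@keys$vr_flag,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(runs))
  out$mean <- x@meanScore
  out$w <- x@w
  out$w_prime <- x@wPrime
  rownames(out) <- NULL
  out
}

#' Multi-run Icity protocol
#'
#' Runs the Icity scoring repeatedly on seeded contig subsamples. Each run
#' scores every cluster against RT baits and VR baits separately and takes
#' the maximum of the two. Runs continue until a run reveals no new cluster
#' exceeding \code{threshold} relative to the previous runs (comparison
#' across two consecutive runs), with a minimum of \code{minRuns} runs and
#' a hard cap of \code{maxRuns}. With \code{subsampleFraction = 1} every
#' run is identical and the protocol stops after exactly \code{minRuns}
#' runs.
#'
#' @param dataset a \code{DgrDataset} with at least one DGR system.
#' @param D neighborhood flank in bp.
#' @param threshold discovery threshold on the per-run score.
#' @param subsampleFraction fraction of contigs drawn (without
#'   replacement) per run; 1 disables stochasticity.
#' @param seed integer seed; run r uses seed + r.
#' @param minRuns,maxRuns convergence floor and cap.
#' @return an \code{\link{IcityTable-class}} object.
#' @export
runIcity <- function(dataset, D = 10000, threshold = 0.7,
                     subsampleFraction = 0.8, seed = 1L, minRuns = 2L,
                     maxRuns = 25L) {
  stopifnot(is(dataset, "DgrDataset"))
  if (!nrow(dataset@dgrSystems))
    stop("dataset has no DGR system to bait on")
  allKeys <- sort(unique(geneClusterKeys(dataset)$key))
  if (!length(allKeys)) stop("dataset has no Pfam-annotated gene")
  nC <- nrow(dataset@contigs)
  nDraw <- max(1L, ceiling(subsampleFraction * nC))

  runsRT <- list(); runsVR <- list()
  discovered <- character(0)
  runSeeds <- integer(0)
  r <- 0L
  repeat {
    r <- r + 1L
    runSeed <- as.integer(seed + r)
    runSeeds <- c(runSeeds, runSeed)
    if (subsampleFraction >= 1) {
      sub <- dataset
    } else {
      set.seed(runSeed)
      for (try in 1:100) {
        ids <- sample(dataset@contigs$contig_id, nDraw)
        sub <- subsetContigs(dataset, ids)
        if (nrow(sub@dgrSystems)) break
        if (try == 100)
          stop("could not draw a subsample containing a DGR system")
        warning("subsample without DGR systems; resampling")
      }
    }
    nb <- extractNeighborhoods(sub, D = D)
    runsRT[[r]] <- .scoreKind(sub, nb, "RT")
    runsVR[[r]] <- .scoreKind(sub, nb, "VR")
    sRT <- stats::setNames(rep(NA_real_, length(allKeys)), allKeys)
    sVR <- sRT
    sRT[runsRT[[r]]$key] <- runsRT[[r]]$score
    sVR[runsVR[[r]]$key] <- runsVR[[r]]$score
    runMax <- pmax(sRT, sVR, na.rm = TRUE)
    runMax[is.na(sRT) & is.na(sVR)] <- NA_real_
    above <- allKeys[!is.na(runMax) & runMax > threshold]
    newKeys <- setdiff(above, discovered)
    discovered <- union(discovered, above)
    if (r >= minRuns && !length(newKeys)) break
    if (r >= maxRuns) {
      warning("Icity protocol hit the run cap (", maxRuns,
              ") before convergence")
      break
    }
  }

  nRuns <- r
  mats <- function(runs) {
    m <- matrix(NA_real_, length(allKeys), nRuns,
                dimnames = list(allKeys, NULL))
    for (i in seq_len(nRuns)) m[runs[[i]]$key, i] <- runs[[i]]$score
    m
  }
  mRT <- mats(runsRT); mVR <- mats(runsVR)
  scores <- pmax(mRT, mVR, na.rm = TRUE)
  scores[is.na(mRT) & is.na(mVR)] <- NA_real_
  # w/w' from the kind achieving the per-run max
  wRT <- matrix(NA_real_, length(allKeys), nRuns,
                dimnames = list(allKeys, NULL))
  wpRT <- wRT; wVR <- wRT; wpVR <- wRT
  for (i in seq_len(nRuns)) {
    wRT[runsRT[[i]]$key, i] <- runsRT[[i]]$w
    wpRT[runsRT[[i]]$key, i] <- runsRT[[i]]$wp
    wVR[runsVR[[i]]$key, i] <- runsVR[[i]]$w
    wpVR[runsVR[[i]]$key, i] <- runsVR[[i]]$wp
  }
  useRT <- !is.na(mRT) & (is.na(mVR) | mRT >= mVR)
  wSel <- ifelse(useRT, wRT, wVR)
  wpSel <- ifelse(useRT, wpRT, wpVR)

  keys <- data.frame(key = allKeys,
                     accession = clusterKeyAccession(allKeys),
                     vr_flag = clusterKeyIsVr(allKeys),
                     stringsAsFactors = FALSE)
  new("IcityTable", keys = keys, runScores = scores,
      meanScore = rowMeans(scores, na.rm = TRUE),
      w = rowMeans(wSel, na.rm = TRUE),
      wPrime = rowMeans(wpSel, na.rm = TRUE),
      nRuns = as.integer(nRuns), runSeeds = runSeeds,
      threshold = threshold)
}

#' Select clusters from an IcityTable
#'
#' Strict mode (\code{all_runs}) keeps a cluster only if its score exceeds
#' the threshold in every run (a run where the cluster was absent from the
#' subsample counts as a failure); lenient mode (\code{any_run}) requires
#' one run above threshold. The inequality is strict, so a score exactly at
#' the threshold never qualifies.
#'
#' @param table an \code{IcityTable}.
#' @param mode \code{"all_runs"} or \code{"any_run"}.
#' @param threshold score threshold.
#' @return character vector of selected cluster keys.
#' @export
selectPfams <- function(table, mode = c("all_runs", "any_run"),
                        threshold = 0.7) {
  mode <- match.arg(mode)
  s <- table@runScores
  ok <- if (mode == "all_runs") {
    apply(s, 1, function(v) all(!is.na(v)) && all(v > threshold))
  } else {
    apply(s, 1, function(v) any(!is.na(v) & v > threshold))
  }
  table@keys$key[ok]
}
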