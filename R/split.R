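.UNIT_TO_MOLAR <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12,
                    fM = 1e-15)

#' Build affinity records
#'
#' @param entry_id entry identifiers.
#' @param measure affinity measure: Kd, Ki or IC50.
#' @param qualifier one of "=", "~", ">", "<".
#' @param value numeric value in \code{unit}.
#' @param unit concentration unit (M, mM, uM, nM, pM, fM).
#' @return data.frame with the molar value and pk = -log10(molar), the pK
#'   conversion applied uniformly to Kd, Ki and IC50.
#' @export
affinityRecords <- function(entry_id, measure, qualifier, value, unit) {
  stopifnot(all(measure %in% c("Kd", "Ki", "IC50")))
  bad <- !(qualifier %in% c("=", "~", ">", "<"))
  if (any(bad))
    stop("input error: unknown qualifier '", qualifier[bad][1],
         "' for entry ", entry_id[bad][1])
  if (any(!(unit %in% names(.UNIT_TO_MOLAR))))
    stop("input error: unknown concentration unit")
  molar <- value * .UNIT_TO_MOLAR[unit]
  if (any(molar <= 0)) stop("input error: non-positive affinity value")
  data.frame(entry_id = as.character(entry_id), measure = measure,
             qualifier = qualifier, value = value, unit = unit,
             molar = unname(molar), pk = unname(-log10(molar)),
             stringsAsFactors = FALSE)
}

#' Read an affinity table (TSV)
#'
#' Columns: entry_id, measure, qualifier, value, unit.
#' @param path TSV path.
#' @return affinity record data.frame (see \code{\link{affinityRecords}}).
#' @export
readAffinityTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  affinityRecords(df$entry_id, df$measure, df$qualifier, df$value, df$unit)
}

#' Filter affinity records by measurement qualifier
#'
#' Retains precisely ("=") and approximately ("~") defined affinities,
#' drops lower bounds (">", affinity only known to be weaker), and keeps
#' upper bounds ("<", known to be stronger) only when the bound is at most
#' 1 micromolar. Order-independent and idempotent. Retained "<" entries are
#' treated downstream as exact values.
#'
#' @param records affinity record data.frame.
#' @param strongBound molar cutoff for "<" entries (default 1e-6).
#' @return the retained subset, with a \code{dropReason} attribute table.
#' @export
filterAffinities <- function(records, strongBound = 1e-6) {
  bad <- !(records$qualifier %in% c("=", "~", ">", "<"))
  if (any(bad))
    stop("input error: unknown qualifier for entry ",
         records$entry_id[bad][1])
  keep <- records$qualifier %in% c("=", "~") |
          (records$qualifier == "<" & records$molar <= strongBound)
  out <- records[keep, , drop = FALSE]
  dropped <- records[!keep, c("entry_id", "qualifier"), drop = FALSE]
  dropped$reason <- ifelse(dropped$qualifier == ">", "weaker-than bound",
                           "stronger-than bound above 1 uM")
  attr(out, "dropped") <- dropped
  out
}

#' Read a chain-level sequence-cluster table (TSV)
#'
#' Columns: entry_id, chain, cluster (the weekly-clustering layout: one row
#' per chain).
#' @param path TSV path.
#' @return data.frame entry_id, chain, cluster.
#' @export
readClusterTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("entry_id", "cluster") %in% names(df)))
  df
}

#' Remove entries whose chains span several sequence clusters
#'
#' Multichain entries mapping to two or more distinct clusters are
#' ambiguous for cluster-aware splitting and are removed; entries absent
#' from the cluster table are removed with reason "unclustered".
#'
#' @param entries character vector of entry ids.
#' @param clusterTable chain-level table from \code{\link{readClusterTable}}.
#' @return list with \code{retained} (entry ids), \code{clusterOfEntry}
#'   (named vector) and \code{removed} (data.frame entry_id, reason).
#' @export
removeAmbiguousClusterEntries <- function(entries, clusterTable) {
  removed <- data.frame(entry_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  clusterOf <- character(0)
  retained <- character(0)
  for (e in entries) {
    cl <- unique(clusterTable$cluster[clusterTable$entry_id == e])
    if (length(cl) == 0L) {
      removed <- rbind(removed, data.frame(entry_id = e,
                                           reason = "unclustered"))
    } else if (length(cl) > 1L) {
      removed <- rbind(removed,
                       data.frame(entry_id = e,
                                  reason = "chains in multiple clusters"))
    } else {
      retained <- c(retained, e)
      clusterOf[e] <- cl
    }
  }
  list(retained = retained, clusterOfEntry = clusterOf, removed = removed)
}

#' Cluster-aware k-fold split
#'
#' Assigns whole sequence clusters to folds so no cluster ever straddles a
#' fold boundary, balancing fold sizes greedily: clusters are taken largest
#' first (ties broken deterministically by a seed-driven shuffle) and each
#' goes to the currently smallest fold.
#'
#' @param entries character vector of entry ids.
#' @param clusterOfEntry cluster id named by entry id, covering all entries.
#' @param k number of folds (>= 2).
#' @param seed RNG seed for tie-breaking.
#' @param removed optional data.frame of already-removed entries to record.
#' @return a \linkS4class{SplitPlan}.
#' @export
clusteredKFold <- function(entries, clusterOfEntry, k = 3L, seed = 1L,
                           removed = NULL) {
  stopifnot(k >= 2L)
  if (!all(entries %in% names(clusterOfEntry)))
    stop("input error: entries without a cluster assignment")
  cl <- clusterOfEntry[entries]
  sizes <- table(cl)
  if (length(sizes) < k)
    stop("input error: fewer clusters (", length(sizes),
         ") than folds (", k, ")")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(as.integer(seed))
  ids <- sample(names(sizes))            # seed-driven tie-break order
  ids <- ids[order(-as.integer(sizes[ids]))]   # stable: largest first
  foldSize <- integer(k)
  foldOfCluster <- integer(0)
  for (cid in ids) {
    f <- which.min(foldSize)             # ties -> lowest fold index
    foldOfCluster[cid] <- f - 1L
    foldSize[f] <- foldSize[f] + as.integer(sizes[[cid]])
  }
  fold <- foldOfCluster[cl]
  names(fold) <- entries
  if (is.null(removed))
    removed <- data.frame(entry_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  new("SplitPlan", foldOfEntry = fold,
      clusterOfEntry = stats::setNames(as.character(cl), entries),
      removedEntries = removed, k = as.integer(k))
}

#' Persist / load a split plan as JSON
#' @param plan a \linkS4class{SplitPlan}.
#' @param path JSON path.
#' @export
writeSplitPlan <- function(plan, path) {
  jsonlite::write_json(
    list(k = plan@k,
         foldOfEntry = as.list(plan@foldOfEntry),
         clusterOfEntry = as.list(plan@clusterOfEntry),
         removed = plan@removedEntries),
    path, auto_unbox = TRUE, digits = NA)
  invisible(plan)
}

#' @rdname writeSplitPlan
#' @export
readSplitPlan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  removed <- if (length(obj$removed)) as.data.frame(obj$removed)
             else data.frame(entry_id = character(), reason = character())
  new("SplitPlan",
      foldOfEntry = vapply(obj$foldOfEntry, as.integer, 0L),
      clusterOfEntry = vapply(obj$clusterOfEntry, as.character, ""),
      removedEntries = removed, k = as.integer(obj$k))
}

#' Fold membership helpers
#' @param plan a \linkS4class{SplitPlan}.
#' @param fold 0-based fold index.
#' @return entry ids in (or out of) the fold.
#' @export
foldEntries <- function(plan, fold) {
  names(plan@foldOfEntry)[plan@foldOfEntry == fold]
}

#' @rdname foldEntries
#' @export
foldComplement <- function(plan, fold) {
  names(plan@foldOfEntry)[plan@foldOfEntry != fold]
}
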