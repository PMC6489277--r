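# Incremental peptide-based clustering of a protein family.
#
# The engine alternates peptide pruning, outlier removal, a pairwise
# dissimilarity built from shared peptide start positions, Ward
# clustering of proteins, conserved-peptide extraction per group and a
# complete-linkage merge of sister groups, over rounds with tightening
# conservation floors (10/20/30/40%) and minimum group sizes (2/3/4/5),
# followed by a final pass on the 40%-conserved peptides.

#' Clustering parameters
#'
#' @param peptide_params a [peptide_params()] object (default 8x2).
#' @param c_clust clustering coefficient, a positive integer exponent
#'   amplifying the dissimilarity signal; larger values yield fewer
#'   groups. Default 9.
#' @param min_coverage_abs absolute outlier floor: proteins with fewer
#'   residue positions covered by surviving peptides are removed.
#'   Default 20.
#' @param min_coverage_median_frac relative outlier floor as a fraction
#'   of the family-median covered-position count. Default 0.10.
#' @param conservation_schedule per-round conservation floors for
#'   conserved-peptide extraction. Default `c(0.10, 0.20, 0.30, 0.40)`.
#' @param min_group_size_schedule per-round minimum group sizes.
#'   Default `c(2, 3, 4, 5)`.
#' @param protein_cluster_threshold flat-cut height on the Ward tree of
#'   proteins. Default 1.
#' @param group_merge_threshold flat-cut height on the complete-linkage
#'   tree of groups. Default 0.7.
#' @param final_min_group_size minimum size of a finalized group.
#'   Default 5.
#' @param retain_conservation finalization keeps peptides with raw
#'   conservation strictly above this. Default 0.20.
#' @param reduced logical; the fallback for sparse families: final
#'   minimum group size 3 (representatives and domain ranges are then
#'   typically omitted upstream as well).
#' @return Object of class `cupp_clustering_params`.
#' @export
clustering_params <- function(peptide_params = cupp::peptide_params(),
                              c_clust = 9L,
                              min_coverage_abs = 20L,
                              min_coverage_median_frac = 0.10,
                              conservation_schedule = c(0.10, 0.20, 0.30, 0.40),
                              min_group_size_schedule = c(2L, 3L, 4L, 5L),
                              protein_cluster_threshold = 1.0,
                              group_merge_threshold = 0.7,
                              final_min_group_size = 5L,
                              retain_conservation = 0.20,
                              reduced = FALSE) {
  stopifnot(inherits(peptide_params, "cupp_peptide_params"))
  c_clust <- as.integer(c_clust)
  if (c_clust < 1L) stop("c_clust must be a positive integer")
  if (length(conservation_schedule) != length(min_group_size_schedule))
    stop("conservation and group-size schedules must have equal length")
  if (any(conservation_schedule <= 0) || any(conservation_schedule > 1))
    stop("conservation floors must lie in (0, 1]")
  if (reduced) final_min_group_size <- 3L
  # the per-round minimum never exceeds the final minimum, so smaller
  # target groups (reduced settings) survive the tightening rounds
  min_group_size_schedule <- pmin(as.integer(min_group_size_schedule),
                                  as.integer(final_min_group_size))
  structure(list(peptide_params = peptide_params,
                 c_clust = c_clust,
                 min_coverage_abs = as.integer(min_coverage_abs),
                 min_coverage_median_frac = min_coverage_median_frac,
                 conservation_schedule = conservation_schedule,
                 min_group_size_schedule = as.integer(min_group_size_schedule),
                 protein_cluster_threshold = protein_cluster_threshold,
                 group_merge_threshold = group_merge_threshold,
                 final_min_group_size = as.integer(final_min_group_size),
                 retain_conservation = retain_conservation,
                 reduced = reduced),
            class = "cupp_clustering_params")
}

#' Remove unshared and non-carried peptides from a set of pools
#'
#' Peptides found in only a single protein are removed (within-protein
#' multiplicity counts as presence only, though start sets are kept for
#' coverage). From the second round on, peptides outside the previous
#' round's conserved set (`carried`) are removed first.
#'
#' @param pools named list of `cupp_pool` objects (names = protein ids).
#' @param carried optional character vector of peptides to keep.
#' @return The pools with filtered `entries`.
#' @export
prune_peptides <- function(pools, carried = NULL) {
  stopifnot(is.list(pools), !is.null(names(pools)))
  if (!is.null(carried)) {
    pools <- lapply(pools, function(p) {
      p$entries <- p$entries[peptide %chin% carried]
      p
    })
  }
  tab <- data.table::rbindlist(lapply(pools, function(p)
    data.table::data.table(protein_id = p$protein_id,
                           peptide = unique(p$entries$peptide))))
  if (nrow(tab)) {
    counts <- tab[, .N, by = peptide]
    keep <- counts$peptide[counts$N >= 2L]
  } else keep <- character()
  lapply(pools, function(p) {
    p$entries <- p$entries[peptide %chin% keep]
    p
  })
}

#' Remove outlier proteins by peptide coverage
#'
#' A protein is an outlier when the residue positions covered by its
#' surviving peptides number fewer than `min_coverage_abs` (default 20),
#' or fewer than `min_coverage_median_frac` (default 10%) of the median
#' covered-position count across the family; both rules apply and their
#' removals are united.
#'
#' @param pools named list of pruned `cupp_pool` objects.
#' @param params a [clustering_params()] object.
#' @return List with `kept` (pools) and `removed` (data.table of
#'   `protein_id`, `coverage`, `reason`).
#' @export
remove_outliers <- function(pools, params = clustering_params()) {
  N <- params$peptide_params$N
  cov <- vapply(pools, coverage_count, integer(1L), N = N)
  med <- stats::median(cov)
  low_abs <- cov < params$min_coverage_abs
  low_rel <- cov < params$min_coverage_median_frac * med
  out <- low_abs | low_rel
  removed <- data.table::data.table(
    protein_id = names(pools)[out],
    coverage = unname(cov[out]),
    reason = ifelse(low_abs[out], "coverage_below_minimum",
                    "coverage_below_median_fraction"))
  if (all(out))
    stop("all proteins removed as outliers; consider reduced settings")
  list(kept = pools[!out], removed = removed)
}

#' Pairwise dissimilarity between two peptide pools
#'
#' Shared peptides are found by exact string equality of variant
#' strings. `shared_positions` is the number of distinct start positions
#' of shared peptides in the first protein plus the same count in the
#' second; `max_positions` is the larger of the two proteins' distinct
#' conserved-peptide start counts. The score is
#' `(1 - shared_positions / (2 * max_positions))^c_clust`, so identical
#' pools score 0 and disjoint pools score 1, with the exponent
#' sharpening the separation.
#'
#' @param poolA,poolB `cupp_pool` objects (pruned).
#' @param c_clust positive integer exponent.
#' @return List with `shared_positions`, `max_positions`, `score`.
#' @export
eq1_distance <- function(poolA, poolB, c_clust = 9L) {
  eA <- poolA$entries; eB <- poolB$entries
  if (nrow(eA) == 0L || nrow(eB) == 0L) {
    return(list(shared_positions = 0L,
                max_positions = max(data.table::uniqueN(eA$start),
                                    data.table::uniqueN(eB$start), 1L),
                score = 1))
  }
  shared <- intersect(unique(eA$peptide), unique(eB$peptide))
  spA <- data.table::uniqueN(eA$start[eA$peptide %chin% shared])
  spB <- data.table::uniqueN(eB$start[eB$peptide %chin% shared])
  mp <- max(data.table::uniqueN(eA$start), data.table::uniqueN(eB$start))
  sp <- spA + spB
  list(shared_positions = sp, max_positions = mp,
       score = (1 - sp / (2 * mp))^c_clust)
}

# full symmetric dissimilarity matrix over a named list of pools,
# proteins ordered lexicographically for determinism; all pairs are
# computed at once via a self-join on the peptide index
.distance_matrix <- function(pools, c_clust) {
  ids <- sort(names(pools))
  n <- length(ids)
  D <- matrix(1, n, n, dimnames = list(ids, ids))   # no sharing -> score 1
  diag(D) <- 0
  if (n < 2L) return(D)
  big <- data.table::rbindlist(lapply(seq_along(ids), function(i) {
    e <- pools[[ids[i]]]$entries
    data.table::data.table(peptide = e$peptide, pid = i, start = e$start)
  }))
  npos <- big[, data.table::uniqueN(start), by = pid][order(pid)]
  npv <- integer(n); npv[npos$pid] <- npos$V1
  J <- big[big, on = "peptide", allow.cartesian = TRUE]
  J <- J[pid < i.pid]
  if (nrow(J)) {
    sp <- J[, .(sp = data.table::uniqueN(start) + data.table::uniqueN(i.start)),
            by = .(pid, i.pid)]
    mp <- pmax(npv[sp$pid], npv[sp$i.pid])
    sc <- (1 - sp$sp / (2 * mp))^c_clust
    D[cbind(sp$pid, sp$i.pid)] <- sc
    D[cbind(sp$i.pid, sp$pid)] <- sc
  }
  D
}

#' Ward clustering of proteins with a flat cut
#'
#' The dissimilarity matrix is subjected to agglomerative hierarchical
#' clustering with Ward linkage and flat groups are formed by cutting
#' the tree at a fixed height (default 1). Group numbering is stabilized
#' by relabeling in order of each group's lexicographically smallest
#' member.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal and
#'   dimnames.
#' @param threshold cophenetic cut height.
#' @return List with `membership` (named integer vector) and `hclust`.
#' @export
cluster_proteins <- function(D, threshold = 1.0) {
  if (any(is.na(D))) stop("dissimilarity matrix contains NA/NaN")
  ids <- rownames(D)
  if (length(ids) == 1L)
    return(list(membership = stats::setNames(1L, ids), hclust = NULL))
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  lab <- stats::cutree(hc, h = threshold)
  first <- vapply(split(names(lab), lab), min, character(1L))
  newlab <- match(lab, as.integer(names(first))[order(first)])
  names(newlab) <- names(lab)
  list(membership = newlab, hclust = hc)
}

#' Extract the conserved peptides of a protein group
#'
#' A peptide is conserved when the fraction of group members whose pool
#' contains it reaches the floor; the fraction itself (the peptide
#' conservation) is stored.
#'
#' @param pools named list of the members' pools.
#' @param floor conservation floor in (0, 1]; `0` keeps every peptide
#'   present in at least one member.
#' @return Object of class `cupp_provisional_group`: list with
#'   `member_ids` and `conserved` (named numeric vector of fractions).
#' @export
extract_conserved <- function(pools, floor = 0.10) {
  ids <- sort(names(pools))
  n <- length(ids)
  tab <- data.table::rbindlist(lapply(pools[ids], function(p)
    data.table::data.table(peptide = unique(p$entries$peptide))))
  if (nrow(tab) == 0L) {
    cons <- stats::setNames(numeric(), character())
  } else {
    counts <- tab[, .N, by = peptide][order(peptide)]
    frac <- counts$N / n
    sel <- frac >= floor & frac > 0
    cons <- stats::setNames(frac[sel], counts$peptide[sel])
  }
  structure(list(member_ids = ids, conserved = cons),
            class = "cupp_provisional_group")
}

#' @export
print.cupp_provisional_group <- function(x, ...) {
  cat(sprintf("provisional group: %d members, %d conserved peptides\n",
              length(x$member_ids), length(x$conserved)))
  invisible(x)
}

# group-to-group dissimilarity: 1 - shared/individual conservation,
# where shared sums the per-peptide mean of the two conservations over
# peptides present in both groups, and individual is the larger of the
# two groups' total conservation mass; 0 for identical groups, 1 for
# peptide-disjoint ones
.group_dissimilarity <- function(gA, gB) {
  cA <- gA$conserved; cB <- gB$conserved
  ind <- max(sum(cA), sum(cB))
  if (ind == 0) return(1)
  shared_peps <- intersect(names(cA), names(cB))
  shared <- sum((cA[shared_peps] + cB[shared_peps]) / 2)
  1 - shared / ind
}

#' Merge sister groups sharing their most conserved peptides
#'
#' Groups are compared pairwise on their conserved-peptide profiles;
#' complete-linkage clustering of the resulting dissimilarity matrix is
#' cut at `threshold` (default 0.7) and groups falling in one flat
#' cluster are merged, pooling their members and recomputing peptide
#' conservations at the given floor.
#'
#' @param groups list of `cupp_provisional_group`.
#' @param pools named list of all members' pools (for recomputation).
#' @param floor conservation floor used after merging.
#' @param threshold flat-cut height.
#' @return List with `groups` (possibly merged) and `hclust` (the group
#'   tree, `NULL` for fewer than 2 groups).
#' @export
merge_sister_groups <- function(groups, pools, floor = 0.10,
                                threshold = 0.7) {
  X <- length(groups)
  if (X < 2L) return(list(groups = groups, hclust = NULL))
  lab <- vapply(groups, function(g) min(g$member_ids), character(1L))
  ord <- order(lab)
  groups <- groups[ord]; lab <- lab[ord]
  D <- matrix(0, X, X, dimnames = list(lab, lab))
  for (i in seq_len(X - 1L))
    for (j in (i + 1L):X)
      D[i, j] <- D[j, i] <- .group_dissimilarity(groups[[i]], groups[[j]])
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  cl <- stats::cutree(hc, h = threshold)
  merged <- lapply(split(seq_len(X), cl), function(idx) {
    if (length(idx) == 1L) return(groups[[idx]])
    ids <- sort(unique(unlist(lapply(groups[idx], `[[`, "member_ids"))))
    extract_conserved(pools[ids], floor)
  })
  first <- vapply(merged, function(g) min(g$member_ids), character(1L))
  list(groups = unname(merged[order(first)]), hclust = hc)
}

# build domain-restricted pools for every record; starts are in full
# protein coordinates and windows never cross a domain boundary
.build_family_pools <- function(records, pp) {
  ids <- sort(records$seq$protein_id)
  seqs <- stats::setNames(records$seq$sequence, records$seq$protein_id)
  pools <- vector("list", length(ids)); names(pools) <- ids
  for (id in ids) {
    s <- seqs[[id]]
    dom <- if (!is.null(records$domains))
      records$domains[protein_id == id] else NULL
    if (!is.null(dom) && nrow(dom)) {
      parts <- lapply(seq_len(nrow(dom)), function(k) {
        sub <- substr(s, dom$start[k] + 1L, dom$end[k])
        p <- suppressWarnings(build_pool(sub, pp, id))
        p$entries[, start := start + dom$start[k]]
        p$entries
      })
      entries <- unique(data.table::rbindlist(parts))
      data.table::setkey(entries, peptide)
      pools[[id]] <- structure(list(protein_id = id, entries = entries,
                                    sequence_length = nchar(s)),
                               class = "cupp_pool")
    } else {
      pools[[id]] <- suppressWarnings(build_pool(s, pp, id))
    }
  }
  pools
}

#' Run the incremental clustering of a protein family
#'
#' Executes the full schedule: an initial round at conservation floor
#' 10% and minimum group size 2, three further rounds tightening to
#' 40% and size 5, carrying only each round's conserved peptides into
#' the next round, then a final clustering pass on the 40%-conserved
#' peptides whose groups (of at least `final_min_group_size` members)
#' are the family's peptide-defined groups.
#'
#' @param records a `cupp_records` object (one family).
#' @param params a [clustering_params()] object.
#' @return Object of class `cupp_clustering`: list with `groups` (list
#'   of `cupp_provisional_group` carrying final conservations),
#'   `outliers` (data.table of id, round, reason), `protein_hclust` and
#'   `group_hclust` (final-pass trees), `round_log` (data.table),
#'   `final_pools` (pruned pools of grouped proteins), `params`,
#'   `family`.
#' @export
run_incremental <- function(records, params = clustering_params()) {
  pp <- params$peptide_params
  fam <- unique(records$meta$family)
  if (length(fam) != 1L)
    stop("records span ", length(fam), " families; cluster one family at a time")
  pools <- .build_family_pools(records, pp)
  active <- sort(names(pools))
  outliers <- list()
  round_log <- list()
  carried <- NULL
  n_rounds <- length(params$conservation_schedule)
  schedule <- c(params$conservation_schedule, NA_real_)   # NA = final pass
  min_sizes <- c(params$min_group_size_schedule, params$final_min_group_size)
  groups <- list()
  final_pools <- NULL
  protein_hc <- NULL; group_hc <- NULL
  for (r in seq_len(n_rounds + 1L)) {
    final_pass <- is.na(schedule[r])
    floor <- if (final_pass) 0 else schedule[r]
    min_size <- min_sizes[r]
    if (length(active) < 2L)
      stop("fewer than 2 proteins survive into round ", r)
    pruned <- prune_peptides(pools[active], carried)
    ro <- remove_outliers(pruned, params)
    if (nrow(ro$removed)) {
      rm <- data.table::copy(ro$removed)[, round := r]
      outliers[[length(outliers) + 1L]] <- rm
    }
    kept <- ro$kept
    if (length(kept) < 2L)
      stop("fewer than 2 proteins survive outlier removal in round ", r)
    D <- .distance_matrix(kept, params$c_clust)
    cl <- cluster_proteins(D, params$protein_cluster_threshold)
    memb <- split(names(cl$membership), cl$membership)
    sizes <- lengths(memb)
    small_ids <- unlist(memb[sizes < min_size], use.names = FALSE)
    if (length(small_ids))
      outliers[[length(outliers) + 1L]] <- data.table::data.table(
        protein_id = small_ids, coverage = NA_integer_, round = r,
        reason = sprintf("group_below_min_size_%d", min_size))
    memb <- memb[sizes >= min_size]
    if (!length(memb))
      stop("no group reaches the minimum size in round ", r,
           "; consider reduced settings")
    gs <- lapply(memb, function(ids) extract_conserved(kept[ids], floor))
    mg <- merge_sister_groups(gs, kept, floor, params$group_merge_threshold)
    groups <- mg$groups
    carried <- unique(unlist(lapply(groups, function(g) names(g$conserved)),
                             use.names = FALSE))
    active <- sort(unlist(lapply(groups, `[[`, "member_ids"),
                          use.names = FALSE))
    round_log[[r]] <- data.table::data.table(
      round = r, final_pass = final_pass,
      conservation_floor = floor, min_group_size = min_size,
      n_proteins = length(kept), n_groups = length(groups),
      n_outliers = length(setdiff(names(pruned), names(kept))) +
        length(small_ids),
      n_peptides = length(carried))
    if (final_pass) {
      final_pools <- kept[active]
      protein_hc <- cl$hclust
      group_hc <- mg$hclust
    }
  }
  all_ids <- sort(names(pools))
  grouped <- active
  out_dt <- if (length(outliers)) data.table::rbindlist(outliers, fill = TRUE)
            else data.table::data.table(protein_id = character(),
                                        coverage = integer(),
                                        round = integer(),
                                        reason = character())
  structure(list(groups = groups,
                 outliers = out_dt,
                 protein_hclust = protein_hc,
                 group_hclust = group_hc,
                 round_log = data.table::rbindlist(round_log),
                 final_pools = final_pools,
                 params = params,
                 family = fam,
                 input_ids = all_ids,
                 grouped_ids = grouped),
            class = "cupp_clustering")
}

#' @export
print.cupp_clustering <- function(x, ...) {
  cat(sprintf("peptide clustering of family %s: %d groups over %d of %d proteins\n",
              x$family, length(x$groups), length(x$grouped_ids),
              length(x$input_ids)))
  sizes <- vapply(x$groups, function(g) length(g$member_ids), integer(1L))
  cat("  group sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}
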