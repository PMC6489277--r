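# Benchmarking framework: sensitivity / precision / F-score at the
# family, subfamily and EC levels, and cluster-aware N-fold
# cross-validation partitioning.

.split_ec_tokens <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  unique(unlist(strsplit(x, "[;&-]")))
}

# per-protein label sets at a given level
.truth_labels <- function(meta, level) {
  switch(level,
    family = meta[, .(labels = list(unique(family))), by = protein_id],
    subfamily = meta[!is.na(subfamily),
                     .(labels = list(unique(paste0(family, "_", subfamily)))),
                     by = protein_id],
    ec = meta[, .(labels = list(.split_ec_tokens(ec))), by = protein_id])
}

.pred_labels <- function(pred, level) {
  switch(level,
    family = pred[!is.na(family),
                  .(labels = list(unique(family))), by = query_id],
    subfamily = pred[!is.na(subfamily),
                     .(labels = list(unique(paste0(family, "_", subfamily)))),
                     by = query_id],
    ec = pred[, .(labels = list(.split_ec_tokens(ec))), by = query_id])
}

#' Score predictions against truth at a given annotation level
#'
#' Labels are compared per protein as sets (a multimodular protein may
#' carry several). True positives are predicted labels present in the
#' truth, false negatives truth labels missed, false positives
#' predicted labels absent from the truth. Sensitivity is
#' `tp / (tp + fn)`, precision `tp / (tp + fp)` and the F-score their
#' harmonic mean; a zero denominator yields `NA` rather than 0. At the
#' EC level, a truth function absent from `known_ec` (e.g. excluded
#' from training by the fold split) that is predicted as unknown counts
#' as correct.
#'
#' @param pred annotation data.table from [cupp_predict()].
#' @param truth metadata data.table (columns as [read_meta()]); several
#'   rows per protein allowed.
#' @param level `"family"`, `"subfamily"` or `"ec"`.
#' @param known_ec optional character vector of EC tokens available at
#'   training time.
#' @return List with `tp`, `fp`, `fn`, `sensitivity`, `precision`,
#'   `f_score`, `level`.
#' @export
score_annotations <- function(pred, truth,
                              level = c("family", "subfamily", "ec"),
                              known_ec = NULL) {
  level <- match.arg(level)
  tl <- .truth_labels(data.table::as.data.table(truth), level)
  pl <- .pred_labels(data.table::as.data.table(pred), level)
  pmap <- stats::setNames(pl$labels, pl$query_id)
  tp <- fp <- fn <- 0L
  for (i in seq_len(nrow(tl))) {
    id <- tl$protein_id[i]
    ts <- tl$labels[[i]]
    ps <- if (id %in% names(pmap)) pmap[[id]] else character()
    hit <- intersect(ps, ts)
    missed <- setdiff(ts, ps)
    if (level == "ec" && !is.null(known_ec) && !length(ps)) {
      # function unknowable from training, predicted unknown: correct
      rescued <- setdiff(missed, known_ec)
      tp <- tp + length(rescued)
      missed <- intersect(missed, known_ec)
    }
    tp <- tp + length(hit)
    fn <- fn + length(missed)
    fp <- fp + length(setdiff(ps, ts))
  }
  # predictions for proteins absent from the truth are false positives
  extra <- setdiff(pl$query_id, tl$protein_id)
  fp <- fp + sum(lengths(pmap[extra]))
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  f <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  list(tp = tp, fp = fp, fn = fn,
       sensitivity = sens, precision = prec, f_score = f, level = level)
}

#' Partition proteins into folds along similarity clusters
#'
#' High-similarity clusters are atomic: a cluster never straddles
#' folds. Clusters are taken largest first (ties by smallest member id)
#' and dealt into the current fold until it holds at least `1/k` of the
#' proteins, then the next fold opens; leftovers land in the last fold.
#'
#' @param ids character vector of all protein ids.
#' @param cluster_map named list mapping representative id to member
#'   ids (as from [read_clstr()]); ids absent from the map form
#'   singleton clusters.
#' @param k fold count (default 10).
#' @return Object of class `cupp_fold_plan`: list with `k`,
#'   `assignments` (named integer vector over `ids`) and `clusters`.
#' @export
make_folds <- function(ids, cluster_map = NULL, k = 10L) {
  k <- as.integer(k)
  clusters <- if (is.null(cluster_map)) list() else
    lapply(cluster_map, function(cl) intersect(cl, ids))
  clusters <- Filter(length, clusters)
  rest <- setdiff(ids, unlist(clusters, use.names = FALSE))
  clusters <- c(clusters, lapply(rest, identity))
  if (k > length(clusters))
    stop(sprintf("k = %d exceeds the %d available similarity clusters",
                 k, length(clusters)))
  firsts <- vapply(clusters, min, character(1L))
  ord <- order(-lengths(clusters), firsts)
  clusters <- clusters[ord]
  total <- length(ids)
  target <- total / k
  fold <- 1L
  placed <- 0L
  assign <- integer(0)
  for (cl in clusters) {
    assign[cl] <- fold
    placed <- placed + length(cl)
    if (placed >= target && fold < k) { fold <- fold + 1L; placed <- 0L }
  }
  structure(list(k = k, assignments = assign[ids], clusters = clusters),
            class = "cupp_fold_plan")
}

#' Train on all folds but one and score the held-out fold
#'
#' The training folds are clustered, finalized and compiled into a
#' library; the held-out fold is annotated with full-filtering and
#' scored at the family, subfamily and EC levels against its metadata
#' (EC scoring uses the training folds' EC set as `known_ec`).
#'
#' @param records a `cupp_records` object.
#' @param plan a `cupp_fold_plan` over the records' ids.
#' @param fold index of the held-out fold.
#' @param params [clustering_params()].
#' @return List with `metrics` (list per level), `annotations`,
#'   `library`, `degenerate` (TRUE when training yields no group).
#' @export
holdout_run <- function(records, plan, fold,
                        params = clustering_params()) {
  ids <- records$seq$protein_id
  test_ids <- ids[plan$assignments[ids] == fold]
  train_ids <- setdiff(ids, test_ids)
  if (!length(test_ids)) stop("fold ", fold, " holds no protein")
  train <- structure(list(
    seq = records$seq[protein_id %in% train_ids],
    meta = records$meta[protein_id %in% train_ids],
    domains = if (is.null(records$domains)) NULL else
      records$domains[protein_id %in% train_ids],
    dropped = records$dropped), class = "cupp_records")
  cl <- tryCatch(run_incremental(train, params), error = function(e) NULL)
  groups <- if (is.null(cl)) list() else finalize_family(cl, train)
  if (!length(groups))
    return(list(metrics = NULL, annotations = NULL, library = NULL,
                degenerate = TRUE))
  lib <- compile_library(groups, params$peptide_params)
  test <- records$seq[protein_id %in% test_ids]
  ann <- cupp_predict(test, lib, mode = "full")
  truth <- records$meta[protein_id %in% test_ids]
  known_ec <- .split_ec_tokens(train$meta$ec)
  metrics <- list(
    family = score_annotations(ann, truth, "family"),
    subfamily = score_annotations(ann, truth, "subfamily"),
    ec = score_annotations(ann, truth, "ec", known_ec = known_ec))
  list(metrics = metrics, annotations = ann, library = lib,
       degenerate = FALSE)
}
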