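# Finalizing peptide-defined groups into weighted models and compiling
# the cross-family peptide library used for prediction.

#' Group-finalization weight transform
#'
#' The stored weight of a retained peptide is its raw within-group
#' conservation squared, favoring the more conserved peptides: a raw
#' conservation of 0.9 is stored as 0.81, one of 0.2 as 0.04.
#'
#' @param conservation raw conservation fraction(s) in (0, 1].
#' @return Numeric weight(s).
#' @export
conservation_weight <- function(conservation) {
  conservation^2
}

#' Finalize a provisional group into a weighted peptide model
#'
#' Peptides with raw conservation at or below `retain` (default 20%) are
#' dropped; surviving conservations are squared to favor the more
#' conserved peptides (0.9 becomes 0.81, 0.25 becomes 0.0625). Member
#' metadata is aggregated into evidence counts and the average number of
#' residue positions covered per member under the retained peptides is
#' recorded (it later sets the gap-bridging threshold of range
#' inference).
#'
#' @param group a `cupp_provisional_group` from [run_incremental()].
#' @param pools named list of the members' (pruned) pools.
#' @param meta data.table of metadata rows for the members (several rows
#'   per member allowed, e.g. after representative selection).
#' @param label family-qualified group label, e.g. `"GH30:1"`.
#' @param retain conservation retention threshold (exclusive).
#' @return Object of class `cupp_group`, or `NULL` (with a warning) when
#'   no peptide survives.
#' @export
finalize_group <- function(group, pools, meta, label, retain = 0.20) {
  cons <- group$conserved[group$conserved > retain]
  if (!length(cons)) {
    warning("group ", label, " retains no peptide above ", retain,
            " conservation; discarded")
    return(NULL)
  }
  cons <- cons[order(names(cons))]
  weights <- conservation_weight(cons)
  members <- group$member_ids
  mm <- meta[protein_id %in% members]
  count_tab <- function(x) {
    x <- x[!is.na(x) & nzchar(as.character(x))]
    if (!length(x)) return(stats::setNames(integer(), character()))
    tab <- table(as.character(x))
    stats::setNames(as.integer(tab), names(tab))
  }
  ec_tokens <- unlist(strsplit(mm$ec[!is.na(mm$ec) & nzchar(mm$ec)], ";",
                               fixed = TRUE))
  meta_summary <- list(subfamily = count_tab(mm$subfamily),
                       ec = count_tab(ec_tokens),
                       tax_class = count_tab(mm$tax_class))
  pepnames <- names(weights)
  covs <- vapply(members, function(id) {
    e <- pools[[id]]$entries
    length(.covered_positions(e$start[e$peptide %chin% pepnames],
                              nchar(pepnames[1L])))
  }, integer(1L))
  structure(list(label = label,
                 family = sub(":.*$", "", label),
                 peptides = weights,
                 members = members,
                 meta_summary = meta_summary,
                 avg_covered_positions = mean(covs),
                 theoretical_max = sum(weights)),
            class = "cupp_group")
}

#' @export
print.cupp_group <- function(x, ...) {
  cat(sprintf("group %s: %d members, %d peptides, theoretical max %.2f, avg covered %.1f\n",
              x$label, length(x$members), length(x$peptides),
              x$theoretical_max, x$avg_covered_positions))
  invisible(x)
}

#' Finalize every group of a clustering run
#'
#' Assigns family-qualified labels in order of each group's smallest
#' member id and applies [finalize_group()] to each.
#'
#' @param clustering a `cupp_clustering` object.
#' @param records the `cupp_records` the clustering was run on.
#' @param retain conservation retention threshold.
#' @return List of `cupp_group` objects (discarded groups omitted).
#' @export
finalize_family <- function(clustering, records,
                            retain = clustering$params$retain_conservation) {
  fam <- clustering$family
  out <- list()
  for (k in seq_along(clustering$groups)) {
    g <- finalize_group(clustering$groups[[k]], clustering$final_pools,
                        records$meta, sprintf("%s:%d", fam, k), retain)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  out
}

#' Is a peptide banned from the library?
#'
#' Peptides consisting solely of the abundant aliphatic residues
#' (G, A, V, L, I) or proline are excluded from the library to avoid a
#' bias toward linkers and polyproline regions. Wildcard positions are
#' ignored, the most conservative reading of the ban.
#'
#' @param peptide peptide string(s), possibly containing the wildcard.
#' @return Logical vector.
#' @export
is_banned <- function(peptide) {
  !grepl("[^GAVLIPX]", peptide)
}

#' Compile groups from one or more families into a peptide library
#'
#' All groups' peptides are merged into one inverted index. A peptide
#' occurring in groups of several families has each of its weights
#' divided by the number of distinct families carrying it; banned
#' peptides are removed; each group's theoretical maximum is recomputed
#' from the adjusted weights so prediction-time filtering stays
#' consistent with the lookup weights.
#'
#' @param groups list of `cupp_group` objects (any number of families).
#' @param params the [peptide_params()] the groups were built with.
#' @return Object of class `cupp_library`.
#' @export
compile_library <- function(groups, params = peptide_params()) {
  labels <- vapply(groups, `[[`, character(1L), "label")
  if (anyDuplicated(labels))
    stop("duplicate group labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  ord <- order(labels)
  groups <- groups[ord]; labels <- labels[ord]
  idx <- data.table::rbindlist(lapply(groups, function(g)
    data.table::data.table(peptide = names(g$peptides),
                           label = g$label,
                           family = g$family,
                           weight = unname(g$peptides))))
  idx <- idx[!is_banned(peptide)]
  if (nrow(idx)) {
    idx[, n_families := data.table::uniqueN(family), by = peptide]
    idx[, weight := weight / n_families]
    idx[, n_families := NULL]
  }
  data.table::setkey(idx, peptide)
  summaries <- lapply(groups, function(g) {
    w <- idx[label == g$label]
    list(label = g$label,
         family = g$family,
         n_members = length(g$members),
         members = g$members,
         meta_summary = g$meta_summary,
         avg_covered_positions = g$avg_covered_positions,
         theoretical_max = sum(w$weight))
  })
  names(summaries) <- labels
  structure(list(format = "cupp-library", version = 1L,
                 params = params, index = idx, groups = summaries),
            class = "cupp_library")
}

#' @export
print.cupp_library <- function(x, ...) {
  cat(sprintf("peptide library: %d groups across %d families, %d index entries (%dx%d peptides)\n",
              length(x$groups),
              data.table::uniqueN(x$index$family),
              nrow(x$index), x$params$N, x$params$A))
  invisible(x)
}

#' Save a peptide library to a self-describing JSON archive
#'
#' The archive embeds the format name, version and peptide parameters;
#' numeric weights are written at full precision so a reload reproduces
#' the library bit-exactly.
#'
#' @param lib a `cupp_library`.
#' @param path output path.
#' @export
save_library <- function(lib, path) {
  stopifnot(inherits(lib, "cupp_library"))
  num <- function(x) sprintf("%.17g", x)   # doubles survive the round trip
  obj <- list(format = lib$format, version = lib$version,
              params = list(N = lib$params$N, A = lib$params$A),
              index = list(peptide = lib$index$peptide,
                           label = lib$index$label,
                           family = lib$index$family,
                           weight = num(lib$index$weight)),
              groups = lapply(lib$groups, function(g) list(
                label = g$label, family = g$family,
                n_members = g$n_members, members = g$members,
                meta_summary = lapply(g$meta_summary, as.list),
                avg_covered_positions = num(g$avg_covered_positions),
                theoretical_max = num(g$theoretical_max))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a peptide library saved by [save_library()]
#'
#' @param path archive path.
#' @param expect_params optional [peptide_params()]; loading is refused
#'   when the archive's windowing parameters differ.
#' @return A `cupp_library`.
#' @export
load_library <- function(path, expect_params = NULL) {
  if (!file.exists(path)) stop("library archive not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("corrupt or truncated library archive: ",
                         conditionMessage(e)))
  if (!identical(obj$format, "cupp-library"))
    stop("not a peptide library archive: ", path)
  if (!identical(as.integer(obj$version), 1L))
    stop("unsupported library format version: ", obj$version)
  params <- peptide_params(obj$params$N, obj$params$A)
  if (!is.null(expect_params) &&
      !(identical(params$N, expect_params$N) &&
        identical(params$A, expect_params$A)))
    stop(sprintf("library windowing %dx%d does not match requested %dx%d",
                 params$N, params$A, expect_params$N, expect_params$A))
  idx <- data.table::data.table(
    peptide = as.character(unlist(obj$index$peptide)),
    label = as.character(unlist(obj$index$label)),
    family = as.character(unlist(obj$index$family)),
    weight = as.numeric(unlist(obj$index$weight)))
  if (length(obj$index$peptide) == 0L)
    idx <- data.table::data.table(peptide = character(), label = character(),
                                  family = character(), weight = numeric())
  data.table::setkey(idx, peptide)
  groups <- lapply(obj$groups, function(g) {
    ms <- lapply(g$meta_summary, function(m)
      stats::setNames(as.integer(unlist(m)), names(m)))
    list(label = g$label, family = g$family,
         n_members = as.integer(g$n_members),
         members = as.character(unlist(g$members)),
         meta_summary = ms,
         avg_covered_positions = as.numeric(g$avg_covered_positions),
         theoretical_max = as.numeric(g$theoretical_max))
  })
  names(groups) <- vapply(groups, `[[`, character(1L), "label")
  structure(list(format = "cupp-library", version = 1L, params = params,
                 index = idx, groups = groups),
            class = "cupp_library")
}
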