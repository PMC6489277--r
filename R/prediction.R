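# Annotation of query proteins against a compiled peptide library:
# index lookup, candidate filtering, position-accumulation scoring,
# overlap resolution, domain-range inference and label assignment.

#' Look up a query's peptides in a library
#'
#' The query is windowed and expanded exactly as at build time; every
#' variant present in the library index is recorded with its group,
#' adjusted weight and 0-based query start position.
#'
#' @param seq query residue string.
#' @param lib a `cupp_library`.
#' @return data.table with columns `peptide`, `start`, `label`,
#'   `family`, `weight` (one row per peptide occurrence and owning
#'   group); zero rows when nothing matches or the query is shorter
#'   than the window.
#' @export
lookup_peptides <- function(seq, lib) {
  pool <- build_pool(seq, lib$params)
  if (nrow(pool$entries) == 0L)
    return(data.table::data.table(peptide = character(), start = integer(),
                                  label = character(), family = character(),
                                  weight = numeric()))
  m <- lib$index[pool$entries, on = "peptide", nomatch = NULL]
  data.table::setorder(m, label, start, peptide)
  m[, .(peptide, start, label, family, weight)]
}

# per-group unique-peptide score and distinct start count;
# a peptide found at several query positions counts once here
.group_sums <- function(matches) {
  matches[, .(sum_unique = sum(weight[!duplicated(peptide)]),
              n_starts = data.table::uniqueN(start)),
          by = .(label, family)]
}

#' Initial candidate filter
#'
#' A group survives when the sum of its matched peptides' weights
#' (each peptide counted once) is at least `min_sum` (default 5) and at
#' least 1% of the group's theoretical maximum. In fast mode the
#' matched peptides must additionally occupy at least eight distinct
#' query start positions.
#'
#' @param matches lookup table from [lookup_peptides()].
#' @param lib the library.
#' @param mode `"full"` or `"fast"`.
#' @param min_sum absolute score floor.
#' @return data.table of surviving groups with `label`, `family`,
#'   `sum_unique`, `theoretical_max`, `frac_of_max`.
#' @export
initial_filter <- function(matches, lib, mode = c("full", "fast"),
                           min_sum = 5) {
  mode <- match.arg(mode)
  gs <- .group_sums(matches)
  if (nrow(gs) == 0L) {
    gs[, `:=`(theoretical_max = numeric(), frac_of_max = numeric())]
    return(gs[, .(label, family, sum_unique, theoretical_max, frac_of_max)])
  }
  gs[, theoretical_max := vapply(label, function(l)
    lib$groups[[l]]$theoretical_max, numeric(1L))]
  gs <- gs[sum_unique >= min_sum & sum_unique >= 0.01 * theoretical_max]
  if (mode == "fast") gs <- gs[n_starts >= 8L]
  gs[, frac_of_max := sum_unique / theoretical_max]
  data.table::setorder(gs, -frac_of_max, label)
  gs[, .(label, family, sum_unique, theoretical_max, frac_of_max)]
}

# per-residue accumulated weight for one group's matches; every
# occurrence of a peptide contributes (tandem repeats accumulate)
.accumulation <- function(matches_one, query_length, N) {
  acc <- numeric(query_length)
  if (nrow(matches_one) == 0L) return(acc)
  pos <- as.vector(outer(seq_len(N), matches_one$start, `+`))
  w <- rep(matches_one$weight, each = N)
  agg <- rowsum(w, pos)
  acc[as.integer(rownames(agg))] <- agg[, 1L]
  acc
}

#' Minimum-domain-length filter on the accumulation profile
#'
#' @param acc per-residue accumulated weights.
#' @param min_positions minimum number of residues (default 20, the
#'   minimum domain length).
#' @param floor accumulation value a position must exceed (default 0.2).
#' @return `TRUE` when at least `min_positions` positions exceed
#'   `floor`.
#' @export
position_filter <- function(acc, min_positions = 20L, floor = 0.2) {
  sum(acc > floor) >= min_positions
}

#' Resolve overlapping candidate domains
#'
#' Profiles are processed in decreasing fraction of their theoretical
#' maximum (ties broken by label). The first claims its covered
#' positions; each later profile is kept only when at least half of its
#' accumulation mass lies outside positions already occupied, in which
#' case its positions join the occupied set.
#'
#' @param profiles list of profiles, each a list with `label`,
#'   `frac_of_max` and `acc` (accumulation vector).
#' @return Character vector of kept labels, in processing order.
#' @export
resolve_overlaps <- function(profiles) {
  if (!length(profiles)) return(character())
  fr <- vapply(profiles, `[[`, numeric(1L), "frac_of_max")
  lb <- vapply(profiles, `[[`, character(1L), "label")
  ord <- order(-fr, lb)
  occupied <- logical(length(profiles[[1L]]$acc))
  kept <- character()
  for (i in ord) {
    acc <- profiles[[i]]$acc
    total <- sum(acc)
    if (total <= 0) next
    free <- sum(acc[!occupied])
    if (length(kept) == 0L || free / total >= 0.5) {
      kept <- c(kept, lb[i])
      occupied <- occupied | (acc > 0)
    }
  }
  kept
}

#' Infer domain ranges from an accumulation profile
#'
#' Positions with any accumulated weight are merged into runs; gaps no
#' larger than the group's average covered-position count (clamped to
#' [50, 200] residues) are bridged, larger gaps split the hit into
#' separate domains (e.g. tandem repeats far apart).
#'
#' @param acc accumulation vector.
#' @param avg_covered_positions the group's recorded average.
#' @return data.table with 0-based half-open `start`, `end` columns.
#' @export
infer_ranges <- function(acc, avg_covered_positions) {
  covered <- which(acc > 0)
  if (!length(covered))
    return(data.table::data.table(start = integer(), end = integer()))
  gap_max <- max(50, min(200, avg_covered_positions))
  brk <- which(diff(covered) - 1L > gap_max)
  run_start <- covered[c(1L, brk + 1L)]
  run_end <- covered[c(brk, length(covered))]
  data.table::data.table(start = run_start - 1L, end = run_end)
}

.format_ranges <- function(rng) {
  if (nrow(rng) == 0L) return("")
  paste(sprintf("%d.%d", rng$start, rng$end), collapse = ";")
}

# majority EC among a group's member evidence, minority functions from
# other source proteins appended with "-" in decreasing abundance
.group_ec <- function(summary) {
  ec <- summary$meta_summary$ec
  if (!length(ec)) return(NA_character_)
  ord <- order(-ec, names(ec))
  paste(names(ec)[ord], collapse = "-")
}

# subfamily assignable only with at least three members' evidence
.group_subfamily <- function(summary, min_members = 3L) {
  sf <- summary$meta_summary$subfamily
  sf <- sf[sf >= min_members]
  if (!length(sf)) return(NA_integer_)
  as.integer(names(sf)[order(-sf, as.integer(names(sf)))][1L])
}

.empty_annotation <- function() {
  data.table::data.table(query_id = character(), family = character(),
                         group_label = character(), ranges = character(),
                         score = numeric(), frac_of_max = numeric(),
                         subfamily = integer(), ec = character(),
                         mode = character())
}

# reciprocal span overlap used for the "same range" collapse
.span_overlap <- function(r1, r2) {
  lo <- max(r1[1L], r2[1L]); hi <- min(r1[2L], r2[2L])
  if (hi <= lo) return(0)
  (hi - lo) / min(r1[2L] - r1[1L], r2[2L] - r2[1L])
}

# annotate one query sequence; returns annotation rows
.predict_one <- function(query_id, seq, lib, mode, min_frac = 0.05) {
  N <- lib$params$N
  if (nchar(seq) < N) {
    warning("query '", query_id, "' shorter than window length ", N,
            ": no annotation")
    return(.empty_annotation())
  }
  matches <- lookup_peptides(seq, lib)
  cand <- initial_filter(matches, lib, mode)
  if (nrow(cand) == 0L) return(.empty_annotation())
  if (mode == "fast") {
    # family-level call only: report each family's best group score
    best <- cand[, .SD[1L], by = family]
    return(data.table::data.table(
      query_id = query_id, family = best$family,
      group_label = paste0(best$family, ".0.0"), ranges = "",
      score = best$sum_unique, frac_of_max = best$frac_of_max,
      subfamily = NA_integer_, ec = NA_character_, mode = "fast"))
  }
  profiles <- lapply(seq_len(nrow(cand)), function(i) {
    lab <- cand$label[i]
    acc <- .accumulation(matches[label == lab], nchar(seq), N)
    list(label = lab, family = cand$family[i],
         sum_unique = cand$sum_unique[i],
         frac_of_max = cand$frac_of_max[i], acc = acc)
  })
  names(profiles) <- cand$label
  profiles <- Filter(function(p) position_filter(p$acc), profiles)
  if (!length(profiles)) return(.empty_annotation())
  kept <- resolve_overlaps(profiles)
  if (!length(kept)) return(.empty_annotation())
  calls <- lapply(kept, function(lab) {
    p <- profiles[[lab]]
    rng <- infer_ranges(p$acc, lib$groups[[lab]]$avg_covered_positions)
    span <- c(min(rng$start), max(rng$end))
    c(p[c("label", "family", "sum_unique", "frac_of_max")],
      list(ranges = rng, span = span))
  })
  # two groups assigned on essentially the same range collapse to the
  # family's 0.2 sentinel
  drop <- rep(FALSE, length(calls)); same_range <- rep(FALSE, length(calls))
  if (length(calls) > 1L) {
    for (i in seq_along(calls)[-1L]) {
      for (j in seq_len(i - 1L)) {
        if (!drop[j] && calls[[i]]$family == calls[[j]]$family &&
            .span_overlap(calls[[i]]$span, calls[[j]]$span) >= 0.5) {
          same_range[j] <- TRUE
          drop[i] <- TRUE
        }
      }
    }
  }
  rows <- lapply(seq_along(calls)[!drop], function(i) {
    cl <- calls[[i]]
    g <- lib$groups[[cl$label]]
    k <- sub("^.*:", "", cl$label)
    if (same_range[i]) {
      glab <- paste0(cl$family, ".0.2"); sf <- NA_integer_; ec <- NA_character_
    } else if (cl$frac_of_max >= min_frac) {
      glab <- paste0(cl$family, ".", k)
      sf <- .group_subfamily(g)
      ec <- .group_ec(g)
    } else {
      glab <- paste0(cl$family, ".0.1"); sf <- NA_integer_; ec <- NA_character_
    }
    data.table::data.table(query_id = query_id, family = cl$family,
                           group_label = glab,
                           ranges = .format_ranges(cl$ranges),
                           score = cl$sum_unique,
                           frac_of_max = cl$frac_of_max,
                           subfamily = sf, ec = ec, mode = "full")
  })
  data.table::rbindlist(rows)
}

#' Annotate query proteins against a peptide library
#'
#' Full-filtering applies the accumulation, minimum-domain-length and
#' overlap filters and assigns group, subfamily and EC function (group
#' sentinels: `FAM.0.1` for a family hit below 5% of the group's
#' theoretical maximum, `FAM.0.2` when two groups land on the same
#' range). Fast-filtering applies only the sum thresholds plus an
#' eight-start-position rule and assigns the family-level `FAM.0.0`
#' label.
#'
#' @param queries data.table with `protein_id`, `sequence` (e.g. from
#'   [read_fasta()]), or a `cupp_records` object.
#' @param lib a `cupp_library`.
#' @param mode `"full"` (default) or `"fast"`.
#' @return Annotation data.table with one row per domain call: columns
#'   `query_id`, `family`, `group_label`, `ranges` ("start.end",
#'   ";"-joined, 0-based half-open), `score`, `frac_of_max`,
#'   `subfamily`, `ec`, `mode`.
#' @export
cupp_predict <- function(queries, lib, mode = c("full", "fast")) {
  mode <- match.arg(mode)
  stopifnot(inherits(lib, "cupp_library"))
  if (inherits(queries, "cupp_records")) queries <- queries$seq
  queries <- data.table::as.data.table(queries)
  ord <- order(queries$protein_id)
  rows <- lapply(ord, function(i)
    .predict_one(queries$protein_id[i], queries$sequence[i], lib, mode))
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L) return(.empty_annotation())
  out[]
}
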