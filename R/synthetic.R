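# Synthetic protein families with known group structure, so that
# clustering, library compilation, prediction and evaluation are
# testable without any external database. A family is modelled as a
# star phylogeny per group: each group has a random ancestor and its
# members are point-mutated copies of it.

# run code under a fixed seed without disturbing the caller's RNG state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.pairwise_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  mean(ca == cb)
}

#' Specification of a synthetic protein family
#'
#' @param n_groups number of ancestral groups. Default 5.
#' @param members_per_group members per group. Default 12.
#' @param ancestor_length residue length of each ancestor. Default 300.
#' @param within_mutation_rate per-residue substitution probability of
#'   a member relative to its ancestor; substitutions always change the
#'   residue, so expected member-to-ancestor identity is exactly
#'   `1 - rate`. Default 0.03.
#' @param between_identity maximum tolerated pairwise identity between
#'   ancestors. Default 0.5 (random ancestors sit near 0.05).
#' @param subfamily_map integer vector per group (default: the group
#'   index).
#' @param ec_map character vector of EC strings per group (default:
#'   `3.2.1.<group>`).
#' @param tax_map character vector per group (default alternates
#'   Bacteria / Eukaryota).
#' @param fragment_fraction fraction of members flagged as fragments.
#'   Default 0.
#' @param family family name. Default `"GHX"`.
#' @param seed RNG seed; a fixed seed makes the output byte-identical.
#' @return Object of class `cupp_synthetic_spec`.
#' @export
synthetic_family_spec <- function(n_groups = 5L, members_per_group = 12L,
                                  ancestor_length = 300L,
                                  within_mutation_rate = 0.03,
                                  between_identity = 0.5,
                                  subfamily_map = NULL, ec_map = NULL,
                                  tax_map = NULL, fragment_fraction = 0,
                                  family = "GHX", seed = 1L) {
  n_groups <- as.integer(n_groups)
  if (is.null(subfamily_map)) subfamily_map <- seq_len(n_groups)
  if (is.null(ec_map)) ec_map <- sprintf("3.2.1.%d", seq_len(n_groups))
  if (is.null(tax_map))
    tax_map <- rep(c("Bacteria", "Eukaryota"), length.out = n_groups)
  stopifnot(within_mutation_rate >= 0, within_mutation_rate <= 1,
            between_identity > 0, between_identity <= 1,
            fragment_fraction >= 0, fragment_fraction < 1,
            length(subfamily_map) == n_groups,
            length(ec_map) == n_groups, length(tax_map) == n_groups)
  structure(list(n_groups = n_groups,
                 members_per_group = as.integer(members_per_group),
                 ancestor_length = as.integer(ancestor_length),
                 within_mutation_rate = within_mutation_rate,
                 between_identity = between_identity,
                 subfamily_map = subfamily_map, ec_map = ec_map,
                 tax_map = tax_map,
                 fragment_fraction = fragment_fraction,
                 family = family, seed = as.integer(seed)),
            class = "cupp_synthetic_spec")
}

.random_protein <- function(L) {
  paste(sample(STANDARD_AA, L, replace = TRUE), collapse = "")
}

.mutate <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit)
    chars[i] <- sample(setdiff(STANDARD_AA, chars[i]), 1L)
  paste(chars, collapse = "")
}

# greedy single-linkage components at a given identity threshold
.identity_clusters <- function(ids, seqs, threshold = 0.70) {
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      if (.pairwise_identity(seqs[i], seqs[j]) >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
  root <- vapply(seq_len(n), find, integer(1L))
  comps <- split(ids, root)
  out <- lapply(comps, sort)
  names(out) <- vapply(out, `[[`, character(1L), 1L)
  out[order(names(out))]
}

#' Generate a synthetic protein family
#'
#' Group ancestors are drawn i.i.d. over the 20 standard residues and
#' redrawn while any pair exceeds the allowed between-group identity.
#' Members are ancestor copies with i.i.d. substitutions (never silent)
#' at the within-group rate. Metadata (subfamily, EC, taxonomy,
#' fragment flags) follows the per-group maps, and single-linkage
#' similarity clusters at 70% identity are computed as fold atoms.
#'
#' @param spec a [synthetic_family_spec()].
#' @return List with `seq` (data.table `protein_id`, `sequence`),
#'   `meta` (metadata data.table as [read_meta()]), `truth`
#'   (`protein_id`, `group`), `clusters` (named list as
#'   [read_clstr()]), `ancestors`, and `spec`.
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "cupp_synthetic_spec"))
  .with_seed(spec$seed, {
    anc <- character(spec$n_groups)
    for (g in seq_len(spec$n_groups)) {
      ok <- FALSE
      for (try in 1:100) {
        cand <- .random_protein(spec$ancestor_length)
        if (g == 1L || all(vapply(anc[seq_len(g - 1L)], .pairwise_identity,
                                  numeric(1L), b = cand) <=
                           spec$between_identity)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not draw ancestors below identity ",
                    spec$between_identity, " in 100 attempts")
      anc[g] <- cand
    }
    rows <- list(); meta <- list(); truth <- list()
    for (g in seq_len(spec$n_groups)) {
      for (m in seq_len(spec$members_per_group)) {
        id <- sprintf("%s_g%02d_m%02d", spec$family, g, m)
        rows[[id]] <- data.table::data.table(
          protein_id = id, sequence = .mutate(anc[g], spec$within_mutation_rate))
        truth[[id]] <- data.table::data.table(protein_id = id, group = g)
      }
    }
    seqdt <- data.table::rbindlist(rows)
    truthdt <- data.table::rbindlist(truth)
    n <- nrow(seqdt)
    frag <- rep(FALSE, n)
    n_frag <- floor(spec$fragment_fraction * n)
    if (n_frag > 0L) frag[sample.int(n, n_frag)] <- TRUE
    g_of <- truthdt$group
    metadt <- data.table::data.table(
      protein_id = seqdt$protein_id,
      family = spec$family,
      subfamily = as.integer(spec$subfamily_map[g_of]),
      ec = spec$ec_map[g_of],
      tax_class = spec$tax_map[g_of],
      fragment = as.integer(frag))
    clusters <- .identity_clusters(seqdt$protein_id, seqdt$sequence)
    list(seq = seqdt, meta = metadt, truth = truthdt, clusters = clusters,
         ancestors = anc, spec = spec)
  })
}

#' Generate multidomain proteins from two family specs
#'
#' Members of the two generated families are paired one-to-one and
#' concatenated with a poly-glycine linker; all-glycine windows are
#' banned from libraries, so the linker can never score. The truth
#' table carries both families and both construction ranges (0-based
#' half-open).
#'
#' @param specA,specB two [synthetic_family_spec()] objects.
#' @param linker_length poly-G linker length in residues. Default 20.
#' @return List with `seq`, `truth` (columns `protein_id`, `family`,
#'   `start`, `end`), and the two generated families `famA`, `famB`.
#' @export
generate_multidomain <- function(specA, specB, linker_length = 20L) {
  famA <- generate_family(specA)
  famB <- generate_family(specB)
  n <- min(nrow(famA$seq), nrow(famB$seq))
  linker <- strrep("G", linker_length)
  rows <- list(); truth <- list()
  for (i in seq_len(n)) {
    sa <- famA$seq$sequence[i]; sb <- famB$seq$sequence[i]
    id <- sprintf("md_%03d", i)
    rows[[id]] <- data.table::data.table(
      protein_id = id, sequence = paste0(sa, linker, sb))
    truth[[id]] <- data.table::data.table(
      protein_id = id,
      family = c(specA$family, specB$family),
      start = c(0L, nchar(sa) + linker_length),
      end = c(nchar(sa), nchar(sa) + linker_length + nchar(sb)))
  }
  list(seq = data.table::rbindlist(rows),
       truth = data.table::rbindlist(truth),
       famA = famA, famB = famB)
}
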