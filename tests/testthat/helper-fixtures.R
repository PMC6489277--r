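# Shared fixtures and independent oracles for the test suite.
# Heavy synthetic pipelines are memoised so several test files can reuse
# one computation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

random_protein <- function(L, alphabet = cupp:::STANDARD_AA) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# --- independent oracles -------------------------------------------------

# brute-force variant expansion: enumerate every A-subset of positions
brute_expand <- function(window, A) {
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  N <- length(chars)
  if (A == 0L) return(window)
  combos <- utils::combn(N, A)
  out <- apply(combos, 2L, function(ix) {
    v <- chars; v[ix] <- "X"; paste(v, collapse = "")
  })
  unique(out)
}

hamming <- function(u, v) {
  sum(strsplit(u, "")[[1L]] != strsplit(v, "")[[1L]])
}

# explicit set-arithmetic recomputation of the pairwise dissimilarity
brute_eq1 <- function(poolA, poolB, c_clust) {
  setsA <- split(poolA$entries$start, poolA$entries$peptide)
  setsB <- split(poolB$entries$start, poolB$entries$peptide)
  shared <- intersect(names(setsA), names(setsB))
  spA <- length(unique(unlist(setsA[shared])))
  spB <- length(unique(unlist(setsB[shared])))
  mp <- max(length(unique(unlist(setsA))), length(unique(unlist(setsB))))
  (1 - (spA + spB) / (2 * mp))^c_clust
}

# naive Ward (Lance-Williams update) agglomeration over a dissimilarity
# matrix, cut at height h; mirrors hclust(method = "ward.D2") on squared
# distances tracked explicitly
naive_ward_cut <- function(D, h) {
  n <- nrow(D)
  active <- as.list(seq_len(n))
  S <- D^2                       # squared dissimilarities
  sizes <- rep(1, n)
  heights <- c()
  repeat {
    m <- length(active)
    if (m == 1L) break
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
      if (S[i, j] < best[1L]) best <- c(S[i, j], i, j)
    d_merge <- sqrt(best[1L])
    if (d_merge > h) break
    i <- best[2L]; j <- best[3L]
    ni <- sizes[i]; nj <- sizes[j]
    new_S <- numeric(m)
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      new_S[k] <- ((ni + nk) * S[i, k] + (nj + nk) * S[j, k] -
                     nk * S[i, j]) / (ni + nj + nk)
    }
    keep <- setdiff(seq_len(m), c(i, j))
    S2 <- rbind(cbind(S[keep, keep, drop = FALSE], new_S[keep]),
                c(new_S[keep], 0))
    S <- S2
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
    sizes <- c(sizes[keep], ni + nj)
  }
  lab <- integer(n)
  for (g in seq_along(active)) lab[active[[g]]] <- g
  lab
}

# --- tiny deterministic families ----------------------------------------

tiny_family <- function(seed = 101, n_groups = 3, members = 6, len = 150,
                        rate = 0.02, family = "GHT") {
  generate_family(synthetic_family_spec(
    n_groups = n_groups, members_per_group = members, ancestor_length = len,
    within_mutation_rate = rate, family = family, seed = seed))
}

tiny_pipeline <- function(key = "tiny", ...) {
  memo(key, {
    fam <- tiny_family(...)
    rec <- family_records(fam$seq, fam$meta)
    cl <- run_incremental(rec)
    groups <- finalize_family(cl, rec)
    lib <- compile_library(groups)
    list(fam = fam, rec = rec, cl = cl, groups = groups, lib = lib)
  })
}

# the study-condition family used by the acceptance suite
accept_family <- function(seed) {
  memo(paste0("accept_fam_", seed),
       generate_family(synthetic_family_spec(seed = seed)))
}

accept_pipeline <- function(seed) {
  memo(paste0("accept_pipe_", seed), {
    fam <- accept_family(seed)
    rec <- family_records(fam$seq, fam$meta)
    cl <- run_incremental(rec)
    groups <- finalize_family(cl, rec)
    lib <- compile_library(groups)
    list(fam = fam, rec = rec, cl = cl, groups = groups, lib = lib)
  })
}

# adjusted Rand index between recovered groups and generative labels
group_ari <- function(clustering, truth) {
  memb <- lapply(clustering$groups, `[[`, "member_ids")
  lab <- rep(seq_along(memb), lengths(memb))
  names(lab) <- unlist(memb)
  mclust::adjustedRandIndex(lab, truth$group[match(names(lab),
                                                   truth$protein_id)])
}
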