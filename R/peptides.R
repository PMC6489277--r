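# Sliding-window peptide pools with ambiguous positions.
#
# A protein is reduced to every window of length N; for each window all
# C(N, A) variants with exactly A positions replaced by the wildcard "X"
# are generated, so two windows within Hamming distance A of each other
# always share at least one variant string and approximate matching
# reduces to exact string equality.

#' Amino-acid alphabet used throughout
#'
#' The 20 standard residues. "X" is reserved as the wildcard of peptide
#' variants, so an input "X" (or any other nonstandard letter: B, Z, J,
#' U, O, "*", gap characters) invalidates the windows containing it.
#' @keywords internal
STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Wildcard character marking an ambiguous position
#' @keywords internal
WILDCARD <- "X"

#' Peptide windowing parameters
#'
#' @param N window (peptide) length in residues. Default 8.
#' @param A number of ambiguous (wildcard) positions per variant,
#'   `0 <= A < N`. Default 2. The defaults give the 8x2 peptides that
#'   perform best for CAZyme families.
#' @return An object of class `cupp_peptide_params`.
#' @examples
#' peptide_params()       # 8x2
#' peptide_params(9, 3)
#' @export
peptide_params <- function(N = 8L, A = 2L) {
  N <- as.integer(N); A <- as.integer(A)
  stopifnot(length(N) == 1L, length(A) == 1L, !is.na(N), !is.na(A))
  if (N < 2L) stop("peptide length N must be >= 2")
  if (A < 0L || A >= N) stop("ambiguity count A must satisfy 0 <= A < N")
  structure(list(N = N, A = A), class = "cupp_peptide_params")
}

#' @export
print.cupp_peptide_params <- function(x, ...) {
  cat(sprintf("peptide parameters: %dx%d (length %d, %d ambiguous)\n",
              x$N, x$A, x$N, x$A))
  invisible(x)
}

#' Expand a window into its ambiguous peptide variants
#'
#' Every choice of `A` positions out of `N` is replaced by the wildcard
#' "X", yielding exactly `choose(N, A)` distinct variant strings for a
#' window of distinct residues (fewer are impossible; the count is exact
#' because the wildcard never occurs in the input window).
#'
#' @param window a single string of length `N` over the standard
#'   amino-acid alphabet.
#' @param A number of wildcard positions.
#' @return Character vector of distinct variant strings.
#' @examples
#' length(expand_variants("MKLVTAGH", 2))  # 28
#' expand_variants("ACDEFGHI", 0)          # the window itself
#' @export
expand_variants <- function(window, A = 2L) {
  stopifnot(is.character(window), length(window) == 1L)
  N <- nchar(window)
  A <- as.integer(A)
  if (A < 0L || A >= N) stop("ambiguity count A must satisfy 0 <= A < N")
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% STANDARD_AA)
  if (any(bad))
    stop(sprintf("window '%s' contains nonstandard residue(s): %s",
                 window, paste(unique(chars[bad]), collapse = ", ")))
  if (A == 0L) return(window)
  combos <- utils::combn(N, A)
  out <- character(ncol(combos))
  for (k in seq_len(ncol(combos))) {
    v <- chars
    v[combos[, k]] <- WILDCARD
    out[k] <- paste(v, collapse = "")
  }
  unique(out)
}

# Vectorised variant expansion for many same-length windows at once.
# Returns a data.table(peptide, start) of unique rows; `starts` aligns
# with `windows`. Windows are assumed pre-screened for standard residues.
.expand_windows_dt <- function(windows, starts, N, A) {
  if (length(windows) == 0L)
    return(data.table::data.table(peptide = character(), start = integer()))
  if (A == 0L) {
    dt <- data.table::data.table(peptide = windows, start = starts)
    return(unique(dt))
  }
  m <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
              nrow = N)
  combos <- utils::combn(N, A)
  nW <- length(windows)
  nC <- ncol(combos)
  peps <- vector("list", nC)
  for (k in seq_len(nC)) {
    mk <- m
    mk[combos[, k], ] <- WILDCARD
    peps[[k]] <- do.call(paste0, lapply(seq_len(N), function(i) mk[i, ]))
  }
  dt <- data.table::data.table(
    peptide = unlist(peps, use.names = FALSE),
    start = rep(starts, times = nC))
  unique(dt)
}

#' Build the peptide pool of a protein sequence
#'
#' Slides a window of length `N` across the sequence one residue at a
#' time; each window made solely of standard residues contributes all its
#' `choose(N, A)` variants, recorded together with the 0-based window
#' start. Windows containing nonstandard characters contribute nothing,
#' leaving the rest of the protein intact. A variant occurring at several
#' starts keeps every start.
#'
#' @param seq residue string (uppercased internally).
#' @param params a [peptide_params()] object.
#' @param protein_id identifier stored with the pool.
#' @return An object of class `cupp_pool`: list with `protein_id`,
#'   `entries` (data.table with columns `peptide`, `start`, unique rows),
#'   and `sequence_length`. A sequence shorter than `N` yields an empty
#'   pool with a warning.
#' @examples
#' p <- build_pool("AAAAAAAAA", peptide_params())  # 28 peptides, starts 0,1
#' nrow(p$entries)
#' @export
build_pool <- function(seq, params = peptide_params(), protein_id = "query") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  N <- params$N; A <- params$A
  L <- nchar(seq)
  empty <- data.table::data.table(peptide = character(), start = integer())
  if (L < N) {
    warning(sprintf("sequence '%s' shorter than window length %d: empty pool",
                    protein_id, N))
    return(structure(list(protein_id = protein_id, entries = empty,
                          sequence_length = L), class = "cupp_pool"))
  }
  starts <- 0:(L - N)
  windows <- substring(seq, starts + 1L, starts + N)
  clean <- !grepl(sprintf("[^%s]", paste(STANDARD_AA, collapse = "")), windows)
  dt <- .expand_windows_dt(windows[clean], starts[clean], N, A)
  data.table::setkey(dt, peptide)
  structure(list(protein_id = protein_id, entries = dt, sequence_length = L),
            class = "cupp_pool")
}

#' @export
print.cupp_pool <- function(x, ...) {
  cat(sprintf("peptide pool '%s': %d variant/start pairs (%d distinct peptides) over %d residues\n",
              x$protein_id, nrow(x$entries),
              data.table::uniqueN(x$entries$peptide), x$sequence_length))
  invisible(x)
}

#' Do two windows share a peptide variant?
#'
#' Two equal-length windows share an expanded variant exactly when their
#' Hamming distance is at most `A`; this predicate is the matching
#' semantics that variant expansion implements through exact string
#' equality.
#'
#' @param u,v residue strings of equal length.
#' @param A ambiguity count.
#' @return `TRUE` or `FALSE`.
#' @export
windows_share_variant <- function(u, v, A = 2L) {
  stopifnot(is.character(u), is.character(v),
            length(u) == 1L, length(v) == 1L)
  if (nchar(u) != nchar(v)) stop("windows must have equal length")
  cu <- strsplit(u, "", fixed = TRUE)[[1L]]
  cv <- strsplit(v, "", fixed = TRUE)[[1L]]
  sum(cu != cv) <= A
}

# residue positions covered by a set of (peptide, start) entries:
# union of [start, start + N) as 0-based indices
.covered_positions <- function(starts, N) {
  if (length(starts) == 0L) return(integer())
  s <- unique(starts)
  unique(as.vector(outer(0:(N - 1L), s, `+`)))
}

#' Number of residue positions covered by a pool's peptides
#' @param pool a `cupp_pool`.
#' @param N window length used to build it.
#' @return Count of distinct residue indices lying under at least one
#'   retained window start.
#' @keywords internal
coverage_count <- function(pool, N) {
  length(.covered_positions(pool$entries$start, N))
}
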