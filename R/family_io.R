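# Readers and writers for every external artifact: FASTA (plain or
# gzipped), per-protein metadata TSV, domain-range TSV, CD-HIT .clstr
# files, annotation tables and Newick trees.
#
# Metadata TSV schema: protein_id, family, subfamily (empty allowed),
# ec (";"-separated tokens, each possibly "&"/"-"-joined), tax_class,
# fragment (0/1). Domain TSV schema: protein_id, family, start, end
# (0-based half-open). These are the smallest schemas carrying every
# field the algorithms consume; upstream databases are out of scope.

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file, optionally gzip-compressed. Identifiers are
#'   the first whitespace-delimited token of each header; sequences are
#'   uppercased.
#' @return data.table with columns `protein_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA identifiers: ", paste(dup, collapse = ", "))
  data.table::data.table(protein_id = ids,
                         sequence = toupper(as.character(aa)))
}

#' Write sequences to FASTA
#' @param seqs data.table with `protein_id`, `sequence`.
#' @param path output file path.
#' @export
write_fasta <- function(seqs, path) {
  aa <- Biostrings::AAStringSet(seqs$sequence)
  names(aa) <- seqs$protein_id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

.ec_token_re <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|\\*)$"

# one EC string may join co-occurring functions of one protein with "&"
# and functions from distinct source proteins with "-"
.validate_ec <- function(ec) {
  toks <- unlist(strsplit(ec[nzchar(ec)], "[;&-]"))
  bad <- toks[!grepl(.ec_token_re, toks)]
  if (length(bad))
    stop("malformed EC token(s): ", paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

#' Read per-protein metadata
#'
#' @param path TSV with columns `protein_id`, `family`, `subfamily`,
#'   `ec`, `tax_class`, `fragment`.
#' @return data.table with typed columns; `subfamily` integer (NA when
#'   absent), `fragment` logical.
#' @export
read_meta <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  m <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("protein_id", "family", "ec", "tax_class")))
  need <- c("protein_id", "family", "subfamily", "ec", "tax_class", "fragment")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  m[, `:=`(subfamily = suppressWarnings(as.integer(subfamily)),
           fragment = as.integer(fragment) != 0L)]
  if (any(!is.na(m$subfamily) & m$subfamily < 1L))
    stop("subfamily must be a positive integer when present")
  .validate_ec(m$ec[!is.na(m$ec)])
  m[]
}

#' Read precomputed domain ranges
#'
#' Stand-in for an external domain predictor's output. Coordinates are
#' 0-based half-open on the protein.
#' @param path TSV with columns `protein_id`, `family`, `start`, `end`.
#' @return data.table.
#' @export
read_domains <- function(path) {
  if (!file.exists(path)) stop("domain file not found: ", path)
  d <- data.table::fread(path, sep = "\t",
                         colClasses = list(character = c("protein_id", "family"),
                                           integer = c("start", "end")))
  if (any(d$start < 0L) || any(d$end <= d$start))
    stop("domain ranges must satisfy 0 <= start < end")
  d[]
}

#' Assemble a protein family from its artifacts
#'
#' Binds sequences, metadata and optional domain ranges into the record
#' collection the clustering engine consumes. Proteins flagged as
#' fragments are dropped here (with a logged reason), mirroring the
#' exclusion of fragment entries from model building.
#'
#' @param seqs data.table from [read_fasta()] (or equivalent).
#' @param meta data.table from [read_meta()]; may hold several rows per
#'   protein after representative selection.
#' @param domains optional data.table from [read_domains()].
#' @return Object of class `cupp_records`: list with `seq`, `meta`,
#'   `domains`, `dropped` data.tables.
#' @export
family_records <- function(seqs, meta, domains = NULL) {
  stopifnot(all(c("protein_id", "sequence") %in% names(seqs)))
  seqs <- data.table::as.data.table(seqs)
  meta <- data.table::as.data.table(meta)
  frag_ids <- unique(meta$protein_id[isTRUE_vec(meta$fragment)])
  dropped <- data.table::data.table(protein_id = frag_ids,
                                    reason = rep("fragment", length(frag_ids)))
  keep <- !(seqs$protein_id %in% frag_ids)
  nometa <- setdiff(seqs$protein_id[keep], meta$protein_id)
  if (length(nometa))
    stop("sequences without metadata: ", paste(nometa, collapse = ", "))
  if (!is.null(domains)) {
    domains <- data.table::as.data.table(domains)
    lens <- nchar(seqs$sequence)[match(domains$protein_id, seqs$protein_id)]
    if (any(is.na(lens)))
      stop("domain ranges for unknown protein(s)")
    if (any(domains$end > lens))
      stop("domain range exceeds sequence length")
  }
  structure(list(seq = seqs[keep],
                 meta = meta[protein_id %in% seqs$protein_id[keep]],
                 domains = domains,
                 dropped = dropped),
            class = "cupp_records")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.cupp_records <- function(x, ...) {
  cat(sprintf("protein family records: %d sequences, %d metadata rows%s, %d dropped\n",
              nrow(x$seq), nrow(x$meta),
              if (is.null(x$domains)) "" else
                sprintf(", %d domain ranges", nrow(x$domains)),
              nrow(x$dropped)))
  invisible(x)
}

#' Parse a CD-HIT cluster file
#'
#' @param path a `.clstr` file: ">Cluster k" headed blocks, one entry per
#'   line, the representative marked with a trailing "*".
#' @return Named list mapping representative id to the character vector
#'   of member ids (representative included).
#' @export
read_clstr <- function(path) {
  if (!file.exists(path)) stop("cluster file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character()))
  heads <- grepl("^>Cluster", lines)
  if (!heads[1L]) stop("cluster file does not start with a '>Cluster' header")
  block <- cumsum(heads)
  out <- list()
  for (b in unique(block)) {
    entries <- lines[block == b & !heads]
    if (!length(entries)) next
    ids <- sub("^[^>]*>(.*)\\.\\.\\..*$", "\\1", entries)
    is_rep <- grepl("\\*\\s*$", entries)
    if (sum(is_rep) != 1L)
      stop(sprintf("cluster block %d has %d representatives (expected 1)",
                   b - 1L, sum(is_rep)))
    out[[ids[is_rep]]] <- ids
  }
  out
}

#' Collapse high-similarity clusters onto representative sequences
#'
#' Each cluster of near-identical proteins is replaced by its
#' representative sequence, which inherits the metadata of every member;
#' identical metadata rows of different members collapse to one piece of
#' evidence. Fragment records have already been removed by
#' [family_records()]; a cluster whose representative was dropped as a
#' fragment falls back to its lexicographically first surviving member.
#'
#' @param records a `cupp_records` object.
#' @param repmap named list from [read_clstr()], or `NULL` for a
#'   pass-through.
#' @return A reduced `cupp_records` object.
#' @export
select_representatives <- function(records, repmap = NULL) {
  if (is.null(repmap)) return(records)
  ids <- records$seq$protein_id
  mapped <- unlist(repmap, use.names = FALSE)
  unknown <- setdiff(mapped, c(ids, records$dropped$protein_id))
  if (length(unknown))
    stop("cluster members absent from records: ",
         paste(unknown, collapse = ", "))
  keep_rows <- list(); meta_rows <- list()
  for (rep_id in names(repmap)) {
    members <- intersect(repmap[[rep_id]], ids)   # fragments already gone
    if (!length(members)) next                    # all members were fragments
    head_id <- if (rep_id %in% members) rep_id else sort(members)[1L]
    keep_rows[[head_id]] <- head_id
    # duplicate identical rows of one member collapse; identical
    # metadata of distinct members is separate evidence
    mm <- unique(records$meta[protein_id %in% members])
    mm[, protein_id := head_id]
    meta_rows[[head_id]] <- mm
  }
  unmapped <- setdiff(ids, mapped)
  seq_keep <- c(unlist(keep_rows, use.names = FALSE), unmapped)
  meta <- data.table::rbindlist(
    c(meta_rows, list(records$meta[protein_id %in% unmapped])))
  structure(list(seq = records$seq[protein_id %in% seq_keep],
                 meta = meta,
                 domains = if (is.null(records$domains)) NULL else
                   records$domains[protein_id %in% seq_keep],
                 dropped = records$dropped),
            class = "cupp_records")
}

# quote a Newick label when it contains structural characters
.newick_label <- function(x) {
  needs <- grepl("[\\s()\\[\\]:;,']", x, perl = TRUE)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Serialize a hierarchical clustering as a Newick tree
#'
#' Branch lengths are differences of merge heights, so each leaf sits at
#' depth equal to the height of its first merge and the tree is
#' ultrametric. Labels containing Newick syntax characters are quoted.
#'
#' @param hc an [stats::hclust] object over at least two leaves.
#' @param labels optional replacement leaf labels (default `hc$labels`).
#' @return Newick string, terminated by ";".
#' @export
write_newick <- function(hc, labels = hc$labels) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$order)
  if (n < 2L) stop("need at least 2 leaves for a Newick tree")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  labels <- .newick_label(as.character(labels))
  node_str <- character(nrow(hc$merge))
  node_h <- hc$height
  render <- function(idx, parent_h) {
    if (idx < 0L)                               # leaf, at height 0
      sprintf("%s:%s", labels[-idx], format(parent_h, digits = 12))
    else
      sprintf("%s:%s", node_str[idx],
              format(parent_h - node_h[idx], digits = 12))
  }
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    node_str[i] <- paste0("(", render(kids[1L], node_h[i]), ",",
                          render(kids[2L], node_h[i]), ")")
  }
  paste0(node_str[nrow(hc$merge)], ";")
}

#' Write an annotation table
#'
#' @param ann data.table of annotations (see [cupp_predict()]).
#' @param path output TSV path.
#' @export
write_annotations <- function(ann, path) {
  data.table::fwrite(ann, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Read an annotation table written by [write_annotations()]
#' @param path TSV path.
#' @return data.table.
#' @export
read_annotations <- function(path) {
  a <- data.table::fread(path, sep = "\t", na.strings = "",
                         colClasses = list(character = c(
                           "query_id", "family", "group_label", "ranges",
                           "ec", "mode")))
  if ("subfamily" %in% names(a))
    a[, subfamily := suppressWarnings(as.integer(subfamily))]
  a[]
}
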