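#' Read transcripts from a multi-FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning the
#' plain named-character representation used throughout the package:
#' a character vector of upper-case nucleotide sequences named by
#' transcript id (the first whitespace-delimited token of the FASTA
#' header).
#'
#' @param path Path to a (wrapped or unwrapped) multi-FASTA file.
#' @return Named character vector of sequences.
#' @export
read_transcripts <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(out)))
    stop("duplicate transcript ids in ", path)
  out
}

#' Write transcripts to a multi-FASTA file
#'
#' @param transcripts Named character vector of nucleotide sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(transcripts), path)
  invisible(path)
}

#' Filter transcripts by minimum length
#'
#' Assembled transcripts below a minimum length are discarded before
#' clustering; the default of 250 bp removes fragments too short to be
#' quantified reliably with 50 bp reads.
#'
#' @param transcripts Named character vector of nucleotide sequences.
#' @param min_len Minimum retained length in bp (default 250).
#' @return The retained subset, input order preserved.
#' @export
filter_transcripts <- function(transcripts, min_len = 250) {
  stopifnot(min_len >= 1)
  transcripts[nchar(transcripts) >= min_len]
}

# Reverse complement for plain character vectors; ambiguity codes other
# than N are not expected in assembled transcripts.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All k-mers of a single sequence, in order of start position.
# Windows containing N never match anything and are dropped.
seq_kmers <- function(seq, k, drop_n = TRUE) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, 1:(n - k + 1), k:n)
  if (drop_n) km[!grepl("N", km, fixed = TRUE)] else km
}

# Strand-agnostic canonical form: lexicographic min of k-mer and its
# reverse complement.
canonical_kmers <- function(kmers) {
  if (!length(kmers)) return(kmers)
  pmin(kmers, revcomp(kmers))
}

#' Group transcripts into clusters by exact sequence overlap
#'
#' Two transcripts are linked when they share an exact substring of at
#' least `min_overlap` bp (strand-agnostic by default, so a shared
#' substring on opposite strands also links them); clusters are the
#' transitive closure of this relation, so every transcript belongs to
#' exactly one cluster. A shared substring of length >= L exists if and
#' only if a shared L-mer exists, so the implementation indexes
#' canonical `min_overlap`-mers, which makes the criterion exact, not
#' heuristic. Windows containing N never match.
#'
#' @param transcripts Named character vector of (length-filtered)
#'   transcript sequences.
#' @param min_overlap Minimum exact shared-substring length in bp
#'   (default 50, the read length the clustering is designed around).
#' @param both_strands Also count reverse-complement overlaps
#'   (default `TRUE`).
#' @return A list of clusters, each a list with elements `cluster_id`
#'   (string) and `member_ids` (character vector of transcript ids).
#'   Cluster ids are `"cl1"`, `"cl2"`, ... in order of the first member's
#'   appearance in the input.
#' @export
cluster_transcripts <- function(transcripts, min_overlap = 50,
                                both_strands = TRUE) {
  stopifnot(min_overlap >= 1)
  n <- length(transcripts)
  if (!n) return(list())
  ids <- names(transcripts)
  if (is.null(ids)) stop("transcripts must be named by id")

  # union-find with path compression over transcript indices
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }

  km_list <- lapply(transcripts, function(s) {
    km <- seq_kmers(s, min_overlap)
    unique(if (both_strands) canonical_kmers(km) else km)
  })
  owner <- rep.int(seq_len(n), lengths(km_list))
  km_all <- unlist(km_list, use.names = FALSE)
  if (length(km_all)) {
    # transcripts sharing any k-mer get unioned; within each k-mer group
    # it suffices to link everyone to the first member
    grp <- split(owner, km_all)
    for (g in grp) {
      if (length(g) > 1L) for (j in g[-1L]) union(g[1L], j)
    }
  }

  roots <- vapply(seq_len(n), find, integer(1))
  comp <- split(seq_len(n), match(roots, unique(roots[order(seq_len(n))])))
  # order clusters by first member index
  comp <- comp[order(vapply(comp, min, integer(1)))]
  out <- vector("list", length(comp))
  for (i in seq_along(comp)) {
    out[[i]] <- list(cluster_id = paste0("cl", i),
                     member_ids = ids[comp[[i]]])
  }
  out
}

#' Nominal length of a transcript cluster
#'
#' The nominal ("gene") length used for expression normalization:
#' the longest member plus, for each remaining member taken in
#' decreasing length order (ties broken by id), the portions of its
#' sequence not covered by an exact overlap of at least `min_overlap` bp
#' with the growing concatenate. Equivalently, the length of the union
#' of the members' unique sequence.
#'
#' @param members Named character vector of the cluster's member
#'   sequences.
#' @param min_overlap Minimum exact overlap in bp counted as shared
#'   sequence (default 50).
#' @param both_strands Count reverse-complement overlaps (default `TRUE`).
#' @return Nominal length in bp (integer-valued numeric). Always between
#'   the longest member length and the sum of member lengths.
#' @export
nominal_length <- function(members, min_overlap = 50, both_strands = TRUE) {
  stopifnot(length(members) >= 1, min_overlap >= 1)
  ids <- names(members)
  if (is.null(ids)) ids <- as.character(seq_along(members))
  ord <- order(-nchar(members), ids)
  members <- members[ord]

  k <- min_overlap
  pool <- character(0)   # canonical k-mers of the growing concatenate
  total <- 0L
  for (m in seq_along(members)) {
    s <- members[[m]]
    n <- nchar(s)
    if (m == 1L) {
      total <- total + n
      pool <- unique(canonical_kmers(seq_kmers(s, k)))
      next
    }
    km <- seq_kmers(s, k, drop_n = FALSE)
    keep <- !grepl("N", km, fixed = TRUE)
    hit <- logical(length(km))
    hit[keep] <- (if (both_strands) canonical_kmers(km[keep]) else km[keep]) %in% pool
    covered <- logical(n)
    for (i in which(hit)) covered[i:(i + k - 1L)] <- TRUE
    total <- total + sum(!covered)
    pool <- unique(c(pool, canonical_kmers(seq_kmers(s, k))))
  }
  as.integer(total)
}

#' Build a cluster-level count table
#'
#' @param counts Nonnegative integer matrix, clusters (genes) in rows,
#'   samples in columns; both dimensions named.
#' @return An object of class `count_table`: list with `counts` and
#'   `library_sizes` (column sums).
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(list(counts = counts, library_sizes = colSums(counts)),
            class = "count_table")
}

#' Read a TSV count table
#'
#' First column gene id, one column per sample, header row required.
#'
#' @param path TSV file path.
#' @return A [count_table()] object.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  count_table(m)
}

#' Length- and depth-normalized expression values
#'
#' Converts raw counts to transcripts-per-million-style values:
#' `E[g,s] = C[g,s] / (L_g / 1000) / (N_s / 1e6)`, i.e. counts per
#' kilobase of nominal cluster length per million counted reads in the
#' sample. Library size is the column sum of the count table.
#'
#' @param counts A [count_table()] object (or plain matrix).
#' @param lengths Named numeric vector of nominal lengths in bp, one
#'   entry per gene in `counts`.
#' @return Numeric matrix of expression values, same dimnames as the
#'   counts.
#' @export
compute_expression <- function(counts, lengths) {
  if (inherits(counts, "count_table")) {
    C <- counts$counts; N <- counts$library_sizes
  } else {
    C <- as.matrix(counts); N <- colSums(C)
  }
  if (any(N <= 0)) stop("every sample must have positive library size")
  missing <- setdiff(rownames(C), names(lengths))
  if (length(missing))
    stop("no nominal length for gene(s): ", paste(missing, collapse = ", "))
  L <- lengths[rownames(C)]
  if (any(L <= 0)) stop("nominal lengths must be positive")
  sweep(C / (L / 1000), 2, N / 1e6, "/")
}

#' Expression call for one gene across replicates
#'
#' A gene counts as expressed when at least `min_reps` replicate values
#' reach `threshold` (default: >= 12 expression units in at least one
#' biological replicate, roughly the minimum level at which enrichment
#' can be detected by the differential-expression analysis).
#'
#' @param values Numeric vector of per-replicate expression values.
#' @param threshold Expression threshold (default 12).
#' @param min_reps Minimum number of replicates at or above threshold
#'   (default 1).
#' @return Logical scalar.
#' @export
is_expressed <- function(values, threshold = 12, min_reps = 1) {
  if (!length(values)) stop("is_expressed requires at least one value")
  sum(values >= threshold) >= min_reps
}

#' One-call quantification pipeline
#'
#' Filters transcripts, clusters them, computes nominal lengths, and
#' normalizes a transcript-cluster count table to expression values.
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param counts A [count_table()] whose genes are cluster ids as
#'   produced by [cluster_transcripts()], or `NULL` to stop after
#'   clustering.
#' @param min_len Minimum transcript length (default 250).
#' @param min_overlap Minimum clustering overlap (default 50).
#' @return List with `clusters` (including `nominal_length_bp` per
#'   cluster), `lengths` (named vector) and, when counts are supplied,
#'   `expression`.
#' @export
quantify <- function(transcripts, counts = NULL, min_len = 250,
                     min_overlap = 50) {
  kept <- filter_transcripts(transcripts, min_len)
  cl <- cluster_transcripts(kept, min_overlap)
  for (i in seq_along(cl)) {
    cl[[i]]$nominal_length_bp <-
      nominal_length(kept[cl[[i]]$member_ids], min_overlap)
  }
  lens <- stats::setNames(
    vapply(cl, `[[`, numeric(1), "nominal_length_bp"),
    vapply(cl, `[[`, character(1), "cluster_id"))
  out <- list(clusters = cl, lengths = lens)
  if (!is.null(counts)) out$expression <- compute_expression(counts, lens)
  out
}
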