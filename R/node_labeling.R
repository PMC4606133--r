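# Node labeling: proteins are partitioned into mutually exclusive clusters so
# that functionally similar (near-identical) sequences share a cluster label.
# The pipeline only consumes the partition, so labels can either be computed
# here (greedy longest-first identity clustering) or supplied externally as a
# TSV map (e.g. from CD-HIT).

#' Build a label map from a protein -> cluster assignment
#'
#' @param protein_id character vector of protein identifiers (no duplicates).
#' @param cluster_label character vector of cluster labels, same length.
#' @return An object of class `label_map`: `label_of` (named character,
#'   protein -> label) and `members` (list label -> member proteins, in
#'   within-cluster index order a1, a2, ...).
#' @export
label_map <- function(protein_id, cluster_label) {
  protein_id <- as.character(protein_id)
  cluster_label <- as.character(cluster_label)
  stopifnot(length(protein_id) == length(cluster_label))
  if (anyDuplicated(protein_id))
    stop("duplicate protein id(s): ",
         paste(head(unique(protein_id[duplicated(protein_id)]), 5),
               collapse = ", "))
  if (length(protein_id) == 0)
    warning("empty label map")
  label_of <- setNames(cluster_label, protein_id)
  members <- split(protein_id, cluster_label)
  members <- members[csort(names(members))]
  structure(list(label_of = label_of, members = members),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map: %d proteins in %d clusters>\n",
              length(x$label_of), length(x$members)))
  invisible(x)
}

#' Load a protein -> cluster label map from TSV
#'
#' Two tab-separated columns `protein_id`, `cluster_label`; `#` comments are
#' skipped and an optional header row is recognized. A protein listed twice
#' is an error regardless of whether the labels agree, so conflicts can never
#' pass silently.
#'
#' @param path TSV file path.
#' @return A `label_map`.
#' @export
load_label_map <- function(path) {
  df <- tryCatch(
    read.table(path, sep = "\t", comment.char = "#", header = FALSE,
               colClasses = "character", quote = "",
               stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) return(label_map(character(), character()))
  if (ncol(df) < 2) stop("label map needs two tab-separated columns: ", path)
  if (tolower(df[1, 1]) %in% c("protein_id", "protein"))
    df <- df[-1, , drop = FALSE]
  label_map(df[, 1], df[, 2])
}

#' Write a label map as TSV
#'
#' @param lm a `label_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(lm, path) {
  stopifnot(inherits(lm, "label_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("protein_id\tcluster_label", con)
  ids <- csort(names(lm$label_of))
  if (length(ids) > 0)
    writeLines(paste(ids, unname(lm$label_of[ids]), sep = "\t"), con)
  invisible(path)
}

# identity/coverage of one global pairwise alignment under unit scores
alignment_stats <- function(p, s) {
  alphabet <- unique(c(strsplit(p, "")[[1]], strsplit(s, "")[[1]], LETTERS))
  mat <- matrix(-1, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(p), Biostrings::BString(s), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1)
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  au <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- ap != "-" & au != "-"
  n_both <- sum(both)
  list(identity = if (n_both == 0) 0 else sum(ap[both] == au[both]) / n_both,
       coverage_p = n_both / nchar(p),
       coverage_s = n_both / nchar(s))
}

#' Cluster protein sequences by pairwise identity
#'
#' Greedy longest-first clustering in the CD-HIT style: sequences are sorted
#' by descending length and each joins the first existing cluster whose
#' representative (its founding, longest sequence) aligns at
#' `>= identity_threshold` identity over `>= coverage_threshold` of the
#' length of *both* sequences, under a global alignment with unit
#' match/mismatch/gap scores; otherwise it founds a new cluster.
#'
#' @param sequences named character vector of protein sequences, a named
#'   `Biostrings::AAStringSet`, or a path to a FASTA file.
#' @param identity_threshold minimum fractional identity over the aligned
#'   (both-residue) columns; default 0.90.
#' @param coverage_threshold minimum fraction of each sequence's length that
#'   those columns must span; default 0.95.
#' @return A `label_map` with cluster labels `c0001`, `c0002`, ... in
#'   founding order.
#' @export
cluster_sequences <- function(sequences, identity_threshold = 0.90,
                              coverage_threshold = 0.95) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences) && is.null(names(sequences))) {
    ss <- Biostrings::readAAStringSet(sequences)
    sequences <- setNames(as.character(ss), names(ss))
  } else if (methods::is(sequences, "XStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) == 0) {
    warning("no sequences to cluster")
    return(label_map(character(), character()))
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must carry unique names")
  sequences <- toupper(sequences)
  odd <- grepl("[^ACDEFGHIKLMNPQRSTVWYBXZJUO]", sequences)
  if (any(odd))
    warning(sprintf("%d sequence(s) contain non-amino-acid characters; kept",
                    sum(odd)))
  # longest first; name order (C locale) breaks length ties deterministically
  ord <- order(-nchar(sequences),
               match(names(sequences), csort(names(sequences))))
  reps <- character()    # representative sequence per cluster, founding order
  assign <- character(length(sequences))
  names(assign) <- names(sequences)
  for (idx in ord) {
    s <- sequences[[idx]]
    placed <- NA_integer_
    for (k in seq_along(reps)) {
      st <- alignment_stats(s, reps[[k]])
      if (st$identity >= identity_threshold &&
          st$coverage_p >= coverage_threshold &&
          st$coverage_s >= coverage_threshold) {
        placed <- k
        break
      }
    }
    if (is.na(placed)) {
      reps <- c(reps, s)
      placed <- length(reps)
    }
    assign[names(sequences)[idx]] <- sprintf("c%04d", placed)
  }
  label_map(names(assign), unname(assign))
}
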