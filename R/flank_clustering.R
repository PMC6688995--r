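#' @importFrom Biostrings pairwiseAlignment pattern nmatch
NULL

# BLOSUM62 lazily loaded from Biostrings' data sets.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Extract the sequence flanking an anchored domain
#'
#' Marker-anchored proteins are clustered by the sequence C-terminal to the
#' marker; toxin-anchored proteins by the sequence N-terminal to the toxin.
#' side "C" returns residues (end+1 .. length), side "N" residues
#' (1 .. start-1). A domain abutting the terminus yields an empty flank;
#' such proteins are skipped by the clustering stage with a notice.
#'
#' @param protein protein string
#' @param hit list/row with start and end (1-based inclusive)
#' @param side "N" or "C"
#' @return list(side, sequence)
#' @export
extract_flank <- function(protein, hit, side = c("C", "N")) {
  side <- match.arg(side)
  n <- nchar(protein)
  if (hit$start < 1L || hit$end > n) stop("hit coordinates outside protein")
  seq <- if (side == "C") {
    if (hit$end >= n) "" else substr(protein, hit$end + 1L, n)
  } else {
    if (hit$start <= 1L) "" else substr(protein, 1L, hit$start - 1L)
  }
  list(side = side, sequence = seq)
}

#' Pairwise sequence identity
#'
#' Global end-gap-free alignment (BLOSUM62, gap opening 10, gap extension
#' 0.5) with identity defined as the number of identical aligned residue
#' pairs divided by the length of the shorter sequence -- the convention
#' CD-HIT's length control implies. Arguments are ordered canonically
#' before aligning, so the measure is symmetric by construction.
#'
#' @param a,b protein strings (non-empty)
#' @return identity fraction in [0, 1]
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty input sequence")
  # canonical order: longer first, ties lexicographic
  if (nchar(b) > nchar(a) || (nchar(b) == nchar(a) && b < a)) {
    tmp <- a; a <- b; b <- tmp
  }
  pa <- pairwiseAlignment(b, a, substitutionMatrix = blosum62(),
                          gapOpening = 10, gapExtension = 0.5,
                          type = "overlap")
  nmatch(pa) / min(nchar(a), nchar(b))
}

#' Greedy incremental clustering of flank sequences
#'
#' CD-HIT-style clustering: sequences are processed in canonical order
#' (length descending, protein_id ascending); each sequence is compared to
#' the representatives of all existing clusters and joins the one with
#' maximal identity among those meeting both thresholds (identity >=
#' \code{identity_threshold} and candidate length >= \code{length_ratio}
#' times the representative length), ties broken by earliest-founded
#' cluster; otherwise it founds a new cluster. Representatives are the
#' longest member of their cluster by construction. Input order does not
#' affect the result. Empty flanks are skipped with a message.
#'
#' @param flanks data.frame(protein_id, sequence)
#' @param identity_threshold minimum identity to the representative
#' @param length_ratio minimum candidate/representative length ratio
#' @return data.frame(cluster_id, protein_id, representative, identity,
#'   is_representative)
#' @export
greedy_cluster <- function(flanks, identity_threshold = 0.40,
                           length_ratio = 0.50) {
  stopifnot(is.data.frame(flanks),
            all(c("protein_id", "sequence") %in% names(flanks)))
  empty <- nchar(flanks$sequence) == 0L
  if (any(empty)) {
    message(sum(empty), " sequence(s) with empty flank skipped: ",
            paste(utils::head(flanks$protein_id[empty], 5), collapse = ", "))
    flanks <- flanks[!empty, , drop = FALSE]
  }
  if (nrow(flanks) == 0L) {
    return(data.frame(cluster_id = integer(0), protein_id = character(0),
                      representative = character(0), identity = numeric(0),
                      is_representative = logical(0)))
  }
  ord <- order(-nchar(flanks$sequence), flanks$protein_id)
  flanks <- flanks[ord, , drop = FALSE]
  rep_seq <- character(0)
  rep_id <- character(0)
  out <- vector("list", nrow(flanks))
  for (i in seq_len(nrow(flanks))) {
    s <- flanks$sequence[i]
    pid <- flanks$protein_id[i]
    best_c <- NA_integer_
    best_id <- -1
    if (length(rep_seq)) {
      # length prefilter: processing order guarantees rep >= candidate
      cand <- which(nchar(s) / nchar(rep_seq) >= length_ratio)
      for (k in cand) {
        idk <- pairwise_identity(s, rep_seq[k])
        if (idk >= identity_threshold && idk > best_id) {
          best_id <- idk
          best_c <- k
        }
      }
    }
    if (is.na(best_c)) {
      rep_seq <- c(rep_seq, s)
      rep_id <- c(rep_id, pid)
      out[[i]] <- data.frame(cluster_id = length(rep_seq), protein_id = pid,
                             representative = pid, identity = 1,
                             is_representative = TRUE,
                             stringsAsFactors = FALSE)
    } else {
      out[[i]] <- data.frame(cluster_id = best_c, protein_id = pid,
                             representative = rep_id[best_c],
                             identity = best_id, is_representative = FALSE,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$cluster_id, -res$is_representative, res$protein_id), ,
      drop = FALSE]
}
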