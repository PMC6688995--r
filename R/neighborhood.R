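#' Strand-aware adjacent locus
#'
#' The downstream neighbor of a plus-strand gene is the CDS at
#' feature_index + 1 and the upstream neighbor the CDS at feature_index -
#' 1; the directions are reversed on the minus strand. An adjacent CDS on
#' the opposite strand yields no neighbor (the strict reading of "directly
#' upstream/downstream on the same strand") unless \code{skip_opposite} is
#' set, in which case opposite-strand genes are stepped over until a
#' same-strand CDS or the contig edge is reached.
#'
#' @param feature_table validated feature table
#' @param focal one feature row (data.frame of one row, or a protein_id
#'   present exactly once)
#' @param direction "up" or "down" in gene orientation
#' @param skip_opposite step over opposite-strand genes
#' @return the neighbor's feature row plus a \code{distance} column
#'   (intergenic bp), or NULL
#' @export
adjacent_locus <- function(feature_table, focal, direction = c("down", "up"),
                           skip_opposite = FALSE) {
  direction <- match.arg(direction)
  if (is.character(focal)) {
    focal <- feature_table[feature_table$protein_id == focal, , drop = FALSE]
    if (nrow(focal) != 1L) stop("focal locus not unique in the table")
  }
  if (nrow(focal) != 1L) stop("focal must be a single feature row")
  sub <- feature_table[feature_table$assembly_id == focal$assembly_id &
                         feature_table$contig_id == focal$contig_id, ,
                       drop = FALSE]
  if (!focal$protein_id %in% sub$protein_id) stop("focal not in table")
  step <- if (focal$strand == "+") 1L else -1L
  if (direction == "up") step <- -step
  i <- focal$feature_index + step
  repeat {
    nb <- sub[sub$feature_index == i, , drop = FALSE]
    if (nrow(nb) == 0L) return(NULL)
    if (nb$strand == focal$strand) break
    if (!skip_opposite) return(NULL)
    i <- i + step
  }
  gap <- if (nb$start > focal$start) nb$start - focal$end - 1L else
    focal$start - nb$end - 1L
  nb$distance <- as.integer(gap)
  nb
}

# Vectorized same-strand immediate-neighbor lookup for a locus table.
# Returns one row per locus: the neighbor's protein_id and intergenic
# distance, NA where the neighbor is absent or on the opposite strand.
neighbor_join <- function(loci, feature_table, direction) {
  out <- data.frame(protein_id = rep(NA_character_, nrow(loci)),
                    distance = rep(NA_integer_, nrow(loci)),
                    stringsAsFactors = FALSE)
  if (nrow(loci) == 0L) return(out)
  fkey <- paste(feature_table$assembly_id, feature_table$contig_id,
                feature_table$protein_id, sep = "\r")
  lkey <- paste(loci$assembly_id, loci$contig_id, loci$protein_id,
                sep = "\r")
  if (anyDuplicated(fkey[fkey %in% lkey])) {
    stop("locus not unique in the feature table")
  }
  focal <- feature_table[match(lkey, fkey), , drop = FALSE]
  if (any(is.na(focal$protein_id))) {
    stop("locus not found in the feature table: ",
         loci$protein_id[is.na(focal$protein_id)][1])
  }
  step <- ifelse(focal$strand == "+", 1L, -1L)
  if (direction == "up") step <- -step
  ikey <- paste(feature_table$assembly_id, feature_table$contig_id,
                feature_table$feature_index, sep = "\r")
  nb <- feature_table[match(paste(focal$assembly_id, focal$contig_id,
                                  focal$feature_index + step, sep = "\r"),
                            ikey), , drop = FALSE]
  ok <- !is.na(nb$protein_id) & nb$strand == focal$strand
  out$protein_id[ok] <- nb$protein_id[ok]
  gap <- ifelse(nb$start > focal$start, nb$start - focal$end - 1L,
                focal$start - nb$end - 1L)
  out$distance[ok] <- as.integer(gap[ok])
  out
}

#' Effector/immunity pairing over toxin loci
#'
#' A toxin locus is counted paired iff its immediately downstream
#' same-strand neighbor's protein carries a DUF1911 domain annotation; a
#' secondary column flags DUF1910 co-presence on the same neighbor. The
#' percentage is reported half-up at 2 decimals (1389/1546 -> 89.84).
#'
#' @param toxin_loci data.frame(assembly_id, contig_id, protein_id) of
#'   toxin locus rows
#' @param feature_table validated feature table
#' @param annotations domain annotation table with DUF1911/DUF1910 calls
#' @return list(summary = list(n_toxin_loci, n_paired, percent_paired),
#'   loci = per-locus table with paired / duf1910 flags and the immunity
#'   neighbor's protein_id)
#' @export
pair_immunity <- function(toxin_loci, feature_table, annotations) {
  duf1911 <- unique(annotations$protein_id[
    annotations$domain_name == "DUF1911"])
  duf1910 <- unique(annotations$protein_id[
    annotations$domain_name == "DUF1910"])
  n <- nrow(toxin_loci)
  nb <- neighbor_join(toxin_loci, feature_table, "down")
  neighbor <- nb$protein_id
  paired <- !is.na(neighbor) & neighbor %in% duf1911
  with1910 <- paired & neighbor %in% duf1910
  pct <- if (n == 0L) NA_real_ else round_half_up(100 * sum(paired) / n, 2)
  list(summary = list(n_toxin_loci = n, n_paired = sum(paired),
                      percent_paired = pct),
       loci = data.frame(toxin_loci, downstream_protein = neighbor,
                         paired = paired, duf1910 = with1910,
                         stringsAsFactors = FALSE))
}

#' Upstream-domain summary for marker loci
#'
#' Over marker loci that have a same-strand immediately upstream neighbor,
#' tabulates the neighbor's domain annotations (count and percent of such
#' loci) and the share of loci whose upstream neighbor carries at least one
#' T6SS-component domain (VgrG, TssL, DUF4123 or a core COG).
#'
#' @param marker_loci data.frame(assembly_id, contig_id, protein_id)
#' @param feature_table validated feature table
#' @param annotations domain annotation table
#' @param component_domains domain names counting as T6SS components
#' @return list(table = data.frame(domain_name, count, percent),
#'   n_upstream_loci, t6ss_component_percent)
#' @export
summarize_upstream_domains <- function(marker_loci, feature_table,
                                       annotations,
                                       component_domains = c(
                                         "VgrG", "TssL", "DUF4123",
                                         T6SS_CORE_COGS, "COG3501")) {
  nb <- neighbor_join(marker_loci, feature_table, "up")
  up_ids <- nb$protein_id[!is.na(nb$protein_id)]
  n_up <- length(up_ids)
  if (n_up == 0L) {
    return(list(table = data.frame(domain_name = character(0),
                                   count = integer(0), percent = numeric(0)),
                n_upstream_loci = 0L, t6ss_component_percent = NA_real_))
  }
  ann <- annotations[annotations$protein_id %in% up_ids, , drop = FALSE]
  per_locus_domains <- lapply(up_ids, function(id) {
    unique(ann$domain_name[ann$protein_id == id])
  })
  all_domains <- sort(unique(unlist(per_locus_domains)))
  counts <- vapply(all_domains, function(d) {
    sum(vapply(per_locus_domains, function(x) d %in% x, logical(1)))
  }, integer(1))
  comp_hit <- vapply(per_locus_domains, function(x) {
    any(x %in% component_domains)
  }, logical(1))
  tab <- data.frame(domain_name = all_domains, count = counts,
                    percent = round_half_up(100 * counts / n_up, 2),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$domain_name), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, n_upstream_loci = n_up,
       t6ss_component_percent = round_half_up(100 * sum(comp_hit) / n_up, 2))
}

#' Share of marker proteins carrying PAAR-like delivery domains
#'
#' Percent of distinct marker proteins annotated with PAAR or DUF4280
#' (half-up, 2 decimals).
#'
#' @param marker_loci data.frame with protein_id
#' @param annotations domain annotation table
#' @export
marker_paar_share <- function(marker_loci, annotations) {
  ids <- unique(marker_loci$protein_id)
  if (!length(ids)) return(NA_real_)
  paar <- unique(annotations$protein_id[
    annotations$domain_name %in% c("PAAR", "DUF4280")])
  round_half_up(100 * sum(ids %in% paar) / length(ids), 2)
}

#' Two-predictor signal-peptide consensus
#'
#' A protein is considered to carry a signal peptide only if both
#' predictors call one; a missing call counts as FALSE.
#'
#' @param phobius_call,signalp_call logical flags
#' @export
signal_peptide_consensus <- function(phobius_call, signalp_call) {
  isTRUE(phobius_call) && isTRUE(signalp_call)
}

ARCHITECTURE_PRECEDENCE <- c("PAAR", "DUF4280", "LXG", "WXG100", "DUF637",
                             "Fil_haemagg_2", "VgrG", "SP")

#' Classify the domain architecture of a toxin protein
#'
#' Assigns the first matching label in the documented precedence order
#' (PAAR, DUF4280, LXG, WXG100, DUF637, Fil_haemagg_2, VgrG, SP, none). A
#' delivery-domain annotation only counts if it lies N-terminal to the
#' toxin hit (annotation start < toxin start); the SP label additionally
#' requires the two-predictor consensus, taken from annotation rows with
#' domain_name "Phobius" / "SignalP". Classification is a pure function of
#' the annotation set.
#'
#' @param protein_annotations annotation rows for one protein
#' @param toxin_start 1-based start of the toxin domain hit
#' @return list(label, evidence) where evidence is the annotation subset
#'   used
#' @export
classify_architecture <- function(protein_annotations, toxin_start) {
  ann <- protein_annotations
  nterm <- ann[!is.na(ann$start) & ann$start < toxin_start, , drop = FALSE]
  sp <- signal_peptide_consensus(
    "Phobius" %in% ann$domain_name, "SignalP" %in% ann$domain_name)
  for (label in ARCHITECTURE_PRECEDENCE) {
    if (label == "SP") {
      if (sp) {
        return(list(label = "SP",
                    evidence = ann[ann$domain_name %in%
                                     c("Phobius", "SignalP"), ,
                                   drop = FALSE]))
      }
    } else if (label %in% nterm$domain_name) {
      return(list(label = label,
                  evidence = nterm[nterm$domain_name == label, ,
                                   drop = FALSE]))
    }
  }
  list(label = "none", evidence = ann[0, , drop = FALSE])
}
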