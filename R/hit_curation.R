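#' Curation configuration
#'
#' Post-search filtering thresholds. Boundaries are inclusive: a hit at
#' expect exactly \code{report_expect} or a PoNe protein of exactly
#' \code{min_protein_len} residues is kept ("at least 80 aa").
#'
#' @param report_expect final E-value threshold (default 1e-9)
#' @param min_protein_len minimum protein length in residues, applied to
#'   toxin (PoNe) hits only (default 80)
#' @param drop_contig_ends remove hits whose CDS is first/last on a contig
#' @param dedup_multi_contig collapse assembly-duplicated loci
#' @export
curation_config <- function(report_expect = 1e-9, min_protein_len = 80L,
                            drop_contig_ends = TRUE,
                            dedup_multi_contig = TRUE) {
  stopifnot(report_expect > 0, min_protein_len > 0)
  list(report_expect = report_expect,
       min_protein_len = as.integer(min_protein_len),
       drop_contig_ends = drop_contig_ends,
       dedup_multi_contig = dedup_multi_contig)
}

curation_report <- function(kept, removed) {
  structure(list(kept = kept, removed = removed), class = "curation_report")
}

#' Expand protein-level hits to locus rows
#'
#' A profile hit identifies a protein; the contig-end and duplication rules
#' act on CDS occurrences, so each hit is joined with every CDS carrying
#' its protein_id (duplicated contigs yield one locus row per occurrence).
#'
#' @param hits data.frame with at least protein_id (plus any scan columns)
#' @param feature_table validated feature table
#' @export
hits_to_loci <- function(hits, feature_table) {
  ft <- feature_table[c("assembly_id", "contig_id", "feature_index",
                        "strand", "protein_id", "length_aa", "start",
                        "end")]
  names(ft)[names(ft) == "start"] <- "cds_start"
  names(ft)[names(ft) == "end"] <- "cds_end"
  m <- merge(hits, ft, by = "protein_id", all.x = TRUE)
  if (any(is.na(m$contig_id))) {
    stop("hit references protein absent from the feature table: ",
         m$protein_id[is.na(m$contig_id)][1])
  }
  m[order(m$assembly_id, m$contig_id, m$protein_id), , drop = FALSE]
}

#' Filter hits by E-value and protein length
#'
#' A hit is kept iff expect <= report_expect and, when
#' \code{apply_length_rule} (the toxin-domain searches), the protein length
#' is at least \code{min_protein_len}. Removal reasons: "expect", "length".
#'
#' @param loci locus rows from [hits_to_loci()] (columns expect, length_aa)
#' @param cfg a [curation_config()]
#' @param apply_length_rule enforce the minimum-length rule
#' @return a curation_report: list(kept, removed(protein_id, contig_id,
#'   reason))
#' @export
filter_expect_and_length <- function(loci, cfg = curation_config(),
                                     apply_length_rule = TRUE) {
  bad_expect <- loci$expect > cfg$report_expect
  bad_len <- apply_length_rule & loci$length_aa < cfg$min_protein_len
  reason <- ifelse(bad_expect, "expect", ifelse(bad_len, "length", NA))
  keep <- is.na(reason)
  curation_report(
    kept = loci[keep, , drop = FALSE],
    removed = data.frame(protein_id = loci$protein_id[!keep],
                         contig_id = loci$contig_id[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE))
}

#' Remove hits at contig ends
#'
#' A locus is removed iff its CDS is the first or the last feature on its
#' contig (a single-gene contig is both). Removal reason: "contig_end".
#'
#' @param loci locus rows from [hits_to_loci()]
#' @param feature_table validated feature table
#' @export
drop_contig_end_hits <- function(loci, feature_table) {
  key <- paste(feature_table$assembly_id, feature_table$contig_id,
               sep = "\r")
  max_idx <- tapply(feature_table$feature_index, key, max)
  lkey <- paste(loci$assembly_id, loci$contig_id, sep = "\r")
  if (any(!lkey %in% names(max_idx))) {
    stop("locus on contig absent from the feature table")
  }
  at_end <- loci$feature_index == 1L |
    loci$feature_index == as.integer(max_idx[lkey])
  curation_report(
    kept = loci[!at_end, , drop = FALSE],
    removed = data.frame(protein_id = loci$protein_id[at_end],
                         contig_id = loci$contig_id[at_end],
                         reason = rep("contig_end", sum(at_end)),
                         stringsAsFactors = FALSE))
}

# Same-strand downstream neighbor (gene orientation) of one locus row
# (from hits_to_loci, so CDS coordinates live in cds_start/cds_end);
# returns list(product, distance) or NULL.
downstream_of <- function(feature_table, row) {
  sub <- feature_table[feature_table$assembly_id == row$assembly_id &
                         feature_table$contig_id == row$contig_id, ,
                       drop = FALSE]
  dir <- if (row$strand == "+") 1L else -1L
  nb <- sub[sub$feature_index == row$feature_index + dir, , drop = FALSE]
  if (nrow(nb) == 0L || nb$strand != row$strand) return(NULL)
  dist <- if (row$strand == "+") nb$start - row$cds_end - 1L else
    row$cds_start - nb$end - 1L
  list(product = nb$product, distance = as.integer(dist))
}

#' Deduplicate loci repeated across contigs of one assembly
#'
#' For loci sharing (assembly_id, protein_id) on more than one contig: if
#' every occurrence has the same same-strand downstream gene (matched by
#' product label) at the same intergenic distance in bp, exactly one copy
#' is kept (lexicographically smallest contig_id) and the rest are removed
#' with reason "duplicate"; any disagreement in downstream product or
#' distance keeps all copies. Occurrences that all lack a same-strand
#' downstream gene count as agreeing.
#'
#' @param loci locus rows from [hits_to_loci()]
#' @param feature_table validated feature table
#' @export
dedup_multi_contig <- function(loci, feature_table) {
  if (nrow(loci) == 0L) {
    return(curation_report(loci, data.frame(protein_id = character(0),
                                            contig_id = character(0),
                                            reason = character(0))))
  }
  grp <- paste(loci$assembly_id, loci$protein_id, sep = "\r")
  drop <- logical(nrow(loci))
  for (g in unique(grp[duplicated(grp)])) {
    rows <- which(grp == g)
    if (length(unique(loci$contig_id[rows])) < 2L) next
    down <- lapply(rows, function(i) downstream_of(feature_table, loci[i, ]))
    sig <- vapply(down, function(d) {
      if (is.null(d)) "<none>" else paste(d$product, d$distance, sep = "@")
    }, character(1))
    if (length(unique(sig)) == 1L) {
      keep_row <- rows[order(loci$contig_id[rows])][1]
      drop[setdiff(rows, keep_row)] <- TRUE
    }
  }
  curation_report(
    kept = loci[!drop, , drop = FALSE],
    removed = data.frame(protein_id = loci$protein_id[drop],
                         contig_id = loci$contig_id[drop],
                         reason = rep("duplicate", sum(drop)),
                         stringsAsFactors = FALSE))
}

#' Apply the full curation cascade
#'
#' Expands protein hits to locus rows and applies, in order, the
#' expect/length filter, the contig-end filter and the multi-contig
#' deduplication. Each filter's predicate depends only on the locus and the
#' static feature table, so the final kept set is invariant to filter
#' order; the combined report concatenates all removals.
#'
#' @param hits scan hits (protein_id, bits, expect, ...)
#' @param feature_table validated feature table
#' @param cfg a [curation_config()]
#' @param apply_length_rule enforce the toxin minimum-length rule
#' @export
curate_hits <- function(hits, feature_table, cfg = curation_config(),
                        apply_length_rule = TRUE) {
  loci <- hits_to_loci(hits, feature_table)
  r1 <- filter_expect_and_length(loci, cfg, apply_length_rule)
  kept <- r1$kept
  removed <- r1$removed
  if (cfg$drop_contig_ends) {
    r2 <- drop_contig_end_hits(kept, feature_table)
    kept <- r2$kept
    removed <- rbind(removed, r2$removed)
  }
  if (cfg$dedup_multi_contig) {
    r3 <- dedup_multi_contig(kept, feature_table)
    kept <- r3$kept
    removed <- rbind(removed, r3$removed)
  }
  curation_report(kept, removed)
}
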