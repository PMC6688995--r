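#' The eleven T6SS core-component COG labels
#'
#' Profile labels shown to specifically predict a type VI secretion system.
#' VgrG (COG3501) is tracked separately and does not count toward the
#' nine-of-eleven rule by default.
#' @export
T6SS_CORE_COGS <- c("COG3516", "COG3517", "COG3157", "COG3521", "COG3522",
                    "COG3455", "COG3523", "COG3518", "COG3519", "COG3520",
                    "COG3515")

#' Classify assemblies as T6SS-encoding
#'
#' An assembly harbors a T6SS iff at least \code{min_components} of the 11
#' core-component COGs are present (>= 1 annotated protein each). Unknown
#' COG labels never count; COG3501 (VgrG) is reported separately and can be
#' optionally included in the count for sensitivity analysis.
#'
#' @param protein_assembly data.frame(assembly_id, protein_id) mapping (a
#'   full feature table works)
#' @param annotations domain annotation table carrying COG labels
#' @param min_components threshold (default 9)
#' @param include_vgrg count COG3501 toward the threshold
#' @return data.frame(assembly_id, n_components, vgrg_present, is_t6ss)
#'   plus a list-column components_present
#' @export
detect_components <- function(protein_assembly, annotations,
                              min_components = 9L, include_vgrg = FALSE) {
  stopifnot(all(c("assembly_id", "protein_id") %in% names(protein_assembly)))
  map <- unique(protein_assembly[c("assembly_id", "protein_id")])
  ann <- merge(annotations[c("protein_id", "domain_name")], map,
               by = "protein_id")
  assemblies <- sort(unique(map$assembly_id))
  comp <- lapply(assemblies, function(a) {
    doms <- unique(ann$domain_name[ann$assembly_id == a])
    sort(intersect(doms, T6SS_CORE_COGS))
  })
  vgrg <- vapply(assemblies, function(a) {
    "COG3501" %in% ann$domain_name[ann$assembly_id == a]
  }, logical(1))
  n_comp <- lengths(comp) + if (include_vgrg) as.integer(vgrg) else 0L
  out <- data.frame(assembly_id = assemblies,
                    n_components = as.integer(n_comp),
                    vgrg_present = vgrg,
                    is_t6ss = n_comp >= min_components,
                    stringsAsFactors = FALSE)
  out$components_present <- comp
  rownames(out) <- NULL
  out
}

#' Marker / T6SS co-occurrence
#'
#' Percent of distinct assemblies containing at least one kept marker locus
#' that are classified T6SS-positive. Reported half-up at 2 decimals; an
#' empty marker set yields NA.
#'
#' @param marker_loci data.frame with assembly_id
#' @param calls output of [detect_components()]
#' @return list(n_marker_genomes, n_with_t6ss, percent)
#' @export
cooccurrence <- function(marker_loci, calls) {
  asm <- unique(marker_loci$assembly_id)
  if (!length(asm)) {
    return(list(n_marker_genomes = 0L, n_with_t6ss = 0L,
                percent = NA_real_))
  }
  missing_call <- setdiff(asm, calls$assembly_id)
  if (length(missing_call)) {
    stop("no T6SS call for assembly: ", missing_call[1])
  }
  pos <- calls$assembly_id[calls$is_t6ss]
  n_with <- sum(asm %in% pos)
  list(n_marker_genomes = length(asm), n_with_t6ss = n_with,
       percent = round_half_up(100 * n_with / length(asm), 2))
}
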