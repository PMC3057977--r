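#' Somatic mutation catalog triage
#'
#' Triage of overlap genes against somatic mutation catalogs and fusion
#' annotations. Genes qualify for catalog interrogation when they are
#' dysregulated in the same direction in at least three datasets, or
#' when they appear in a consensus cancer-gene list or a kinase
#' driver-mutation list. Catalog records carry mutated/screened counts
#' per tissue ("n/N" notation) and optional fusion partners.
#'
#' @name mutation_evidence
NULL

#' Select genes for mutation-catalog interrogation
#'
#' A gene is selected iff (i) it has dysregulation support in at least
#' \code{min_support} datasets with a consistent direction, or (ii) it
#' is a member of the consensus cancer-gene list or the kinase
#' driver-mutation list.
#'
#' @param summaries evidence table with columns \code{gene},
#'   \code{support_count}, \code{consensus_direction}.
#' @param consensus_list character vector of consensus cancer-gene
#'   symbols.
#' @param kinase_list character vector of kinase driver-gene symbols.
#' @param min_support support threshold for rule (i) (default 3).
#' @return data.frame with columns \code{gene}, \code{by_support}
#'   (rule i), \code{in_consensus_list}, \code{in_kinase_list}.
#' @export
select_catalog_queries <- function(summaries, consensus_list = character(0),
                                   kinase_list = character(0),
                                   min_support = 3L) {
  by_support <- summaries$support_count >= min_support &
    summaries$consensus_direction != "inconsistent"
  in_cons <- summaries$gene %in% consensus_list
  in_kin <- summaries$gene %in% kinase_list
  sel <- by_support | in_cons | in_kin
  out <- data.frame(gene = summaries$gene[sel],
                    by_support = by_support[sel],
                    in_consensus_list = in_cons[sel],
                    in_kinase_list = in_kin[sel],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a mutation catalog
#'
#' Tab-delimited with columns \code{gene}, \code{tissue},
#' \code{n_mutated}, \code{n_screened}, \code{fusion_partner} (counts
#' may be NA for records reported without explicit denominators, e.g.
#' "mutations in multiple organs").
#'
#' @param path file path.
#' @return data.frame of mutation records.
#' @export
read_mutation_catalog <- function(path) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("gene", "tissue", "n_mutated", "n_screened")
  if (!all(need %in% names(rec)))
    stop("mutation catalog must have columns: ", paste(need, collapse = ", "))
  if (!"fusion_partner" %in% names(rec)) rec$fusion_partner <- NA_character_
  rec
}

#' Classify mutation evidence per gene
#'
#' For each query gene: records with tissue matching "ovary"/"ovarian"
#' (case-insensitive) populate the ovarian mutated/screened fraction; a
#' gene with any ovarian screening record is classed
#' \code{mutated-in-ovarian} (the catalogs report screened-in-ovary
#' genes, including 0/N results, separately from genes never screened
#' there); a gene with records only in other tissues is
#' \code{mutated-in-other}; a gene with no record in any tissue is
#' \code{no-record}. "No record" (gene absent from the catalog) is
#' deliberately distinct from "0/N" (screened, nothing found).
#'
#' @param genes character vector of query gene symbols.
#' @param records mutation record data.frame (see
#'   \code{\link{read_mutation_catalog}}).
#' @return data.frame with one row per query gene: \code{gene},
#'   \code{class}, \code{ovarian_n}, \code{ovarian_N},
#'   \code{other_tissues} (semicolon-separated "n/N tissue"),
#'   \code{fusion_partner}, \code{fusion_site}.
#' @export
classify_mutation_evidence <- function(genes, records) {
  if (any(!is.na(records$n_mutated) & !is.na(records$n_screened) &
          (records$n_mutated < 0 | records$n_screened < 0 |
           records$n_mutated > records$n_screened)))
    stop("invalid mutation counts (negative or n_mutated > n_screened)")
  is_ov <- grepl("^ovar", records$tissue, ignore.case = TRUE)
  rows <- lapply(genes, function(g) {
    rg <- records[records$gene == g, , drop = FALSE]
    ov <- rg[is_ov[records$gene == g], , drop = FALSE]
    ot <- rg[!is_ov[records$gene == g], , drop = FALSE]
    cls <- if (nrow(rg) == 0L) "no-record"
           else if (nrow(ov) > 0L) "mutated-in-ovarian"
           else "mutated-in-other"
    other <- if (nrow(ot))
      paste(ifelse(is.na(ot$n_mutated), ot$tissue,
                   sprintf("%d/%d %s", ot$n_mutated, ot$n_screened, ot$tissue)),
            collapse = "; ")
    else NA_character_
    fus <- rg$fusion_partner[!is.na(rg$fusion_partner) & rg$fusion_partner != ""]
    fus <- if (length(fus)) fus[1L] else NA_character_
    pf <- parse_fusion_annotation(fus)
    data.frame(gene = g, class = cls,
               ovarian_n = if (nrow(ov)) sum(ov$n_mutated) else NA_integer_,
               ovarian_N = if (nrow(ov)) sum(ov$n_screened) else NA_integer_,
               other_tissues = other,
               fusion_partner = pf$partner, fusion_site = pf$site,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), class = character(0),
                      ovarian_n = integer(0), ovarian_N = integer(0),
                      other_tissues = character(0),
                      fusion_partner = character(0),
                      fusion_site = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## "ALK; haematopoietic and soft tissue" -> partner "ALK", site text
parse_fusion_annotation <- function(x) {
  if (is.na(x) || x == "") return(list(partner = NA_character_,
                                       site = NA_character_))
  parts <- strsplit(x, ";", fixed = TRUE)[[1L]]
  list(partner = trimws(parts[1L]),
       site = if (length(parts) > 1L)
         trimws(paste(parts[-1L], collapse = ";")) else NA_character_)
}

#' Fusion-annotated subset of a mutation-evidence table
#'
#' @param evidence table from \code{\link{classify_mutation_evidence}}.
#' @return the rows with a non-empty fusion partner.
#' @export
collect_fusion_partners <- function(evidence) {
  out <- evidence[!is.na(evidence$fusion_partner) &
                    evidence$fusion_partner != "", , drop = FALSE]
  rownames(out) <- NULL
  out
}
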