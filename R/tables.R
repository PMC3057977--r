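#' Published evidence tables shipped with the package
#'
#' Small tab-delimited tables transcribed from the emulated study's
#' printed results, used to replay the integration rules: the
#' consistently dysregulated genes of the five ovarian cancer datasets
#' (with per-dataset fold changes), the estrous/cancer overlap subset
#' with dataset support, the dual-source copy-number gain and loss gene
#' tables, and the mutation-triage table with catalog records in "n/N
#' tissue" notation.
#'
#' @param name one of \code{"eoc_consistent_genes"},
#'   \code{"estrous_overlap_subset"}, \code{"cna_gain_genes"},
#'   \code{"cna_loss_genes"}, \code{"mutation_triage"}.
#' @return data.frame.
#' @export
load_reference_table <- function(name = c("eoc_consistent_genes",
                                          "estrous_overlap_subset",
                                          "cna_gain_genes",
                                          "cna_loss_genes",
                                          "mutation_triage")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "ovcand")
  if (path == "") stop("reference table not found: ", name)
  utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                    na.strings = character(0))
}

#' Dysregulation calls from the consistent-gene table
#'
#' Converts the wide per-dataset fold-change table (numeric fold
#' changes, qualitative ">3"/"up" flags, "-" for no call, "na" for
#' datasets that did not report the direction) into long-format
#' dysregulation calls suitable for \code{\link{count_support}}. The
#' datasets that reported upregulated genes only are
#' \code{c("lu", "heinzelmann")}.
#'
#' @param tab the \code{eoc_consistent_genes} table (default: load it).
#' @return list with \code{calls} (gene, dataset, direction,
#'   fold_change), \code{roster}, \code{up_only}.
#' @export
consistent_gene_calls <- function(tab = load_reference_table("eoc_consistent_genes")) {
  datasets <- setdiff(names(tab), "gene")
  rows <- list()
  for (d in datasets) {
    v <- as.character(tab[[d]])
    has <- !(v %in% c("-", "na", "", NA))
    if (!any(has)) next
    num <- suppressWarnings(as.numeric(v[has]))
    dir <- ifelse(is.na(num), ifelse(v[has] == "up", "up",
                                     ifelse(v[has] == "down", "down", "up")),
                  ifelse(num < 0, "down", "up"))
    rows[[d]] <- data.frame(gene = tab$gene[has], dataset = d,
                            direction = dir, fold_change = v[has],
                            stringsAsFactors = FALSE)
  }
  list(calls = do.call(rbind, rows), roster = datasets,
       up_only = intersect(c("lu", "heinzelmann"), datasets))
}

#' Dysregulation calls implied by the overlap-subset table
#'
#' The overlap subset records, per gene, the number of datasets showing
#' dysregulation and the consensus direction but not which datasets;
#' this expands each gene into that many per-dataset calls (down calls
#' are assigned to the datasets that reported both directions), so the
#' support-counting rule can be replayed on it.
#'
#' @param tab the \code{estrous_overlap_subset} table (default: load
#'   it).
#' @return list with \code{calls}, \code{roster}, \code{up_only} as in
#'   \code{\link{consistent_gene_calls}}.
#' @export
overlap_subset_calls <- function(tab = load_reference_table("estrous_overlap_subset")) {
  roster <- c("tothill", "bonome", "donninger", "lu", "heinzelmann")
  up_only <- c("lu", "heinzelmann")
  both_dir <- setdiff(roster, up_only)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    k <- tab$eoc_datasets[i]
    dsets <- if (tab$direction[i] == "down") both_dir[seq_len(k)]
             else roster[seq_len(k)]
    data.frame(gene = tab$gene[i], dataset = dsets,
               direction = tab$direction[i], stringsAsFactors = FALSE)
  })
  list(calls = do.call(rbind, rows), roster = roster, up_only = up_only)
}

#' Per-source copy-number calls from the gain/loss gene tables
#'
#' Each row of the gain (loss) table documents a gene reported as
#' gained (lost) by both copy-number sources -- the meta-analysis
#' source and the tumor-atlas source -- either through the >30%
#' frequency rule on per-sample log2 ratios or through membership in a
#' reported peak region of recurrent aberration. The printed
#' percentages are rounded summaries, so replay encodes the documented
#' per-source call directly rather than re-thresholding them.
#'
#' @param gain the \code{cna_gain_genes} table (default: load it).
#' @param loss the \code{cna_loss_genes} table (default: load it).
#' @return list with \code{calls} (gene, source, call; two sources
#'   "gorringe" and "tcga"), \code{directions} (gene, direction:
#'   up for gained, down for lost genes), \code{locations} (gene,
#'   cytoband).
#' @export
cna_table_calls <- function(gain = load_reference_table("cna_gain_genes"),
                            loss = load_reference_table("cna_loss_genes")) {
  mk <- function(tab, call) {
    do.call(rbind, lapply(c("gorringe", "tcga"), function(s)
      data.frame(gene = tab$gene, source = s, call = call,
                 stringsAsFactors = FALSE)))
  }
  calls <- rbind(mk(gain, "gain"), mk(loss, "loss"))
  directions <- data.frame(gene = c(gain$gene, loss$gene),
                           direction = c(rep("up", nrow(gain)),
                                         rep("down", nrow(loss))),
                           stringsAsFactors = FALSE)
  locations <- data.frame(gene = c(gain$gene, loss$gene),
                          cytoband = c(gain$cytoband, loss$cytoband),
                          stringsAsFactors = FALSE)
  list(calls = calls, directions = directions, locations = locations)
}

## parse "1/476 CNS, 1/6 skin" -> data.frame(tissue, n_mutated, n_screened)
.parse_nN_records <- function(text) {
  if (is.na(text) || text %in% c("", "-", "no record")) return(NULL)
  parts <- trimws(strsplit(text, ",", fixed = TRUE)[[1L]])
  rows <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([0-9]+)/([0-9]+)\\s*(.*)$", p))[[1L]]
    if (length(m) == 4L) {
      tissue <- if (m[4L] == "") "unspecified" else m[4L]
      data.frame(tissue = tissue, n_mutated = as.integer(m[2L]),
                 n_screened = as.integer(m[3L]), stringsAsFactors = FALSE)
    } else {
      ## qualitative records such as "mutations in multiple organs"
      data.frame(tissue = p, n_mutated = NA_integer_,
                 n_screened = NA_integer_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Mutation catalog records from the triage table
#'
#' Expands the triage table's "n/N tissue" columns into one mutation
#' record per gene and tissue. The ovarian column yields records with
#' tissue "ovary"; the other-cancers column is parsed entry by entry
#' (qualitative entries such as "mutations in multiple organs" become
#' records without counts). "no record" and "-" yield no rows, keeping
#' absent-from-catalog distinct from screened-but-negative.
#'
#' @param tab the \code{mutation_triage} table (default: load it).
#' @return data.frame with columns \code{gene}, \code{tissue},
#'   \code{n_mutated}, \code{n_screened}, \code{fusion_partner}.
#' @export
mutation_table_catalog <- function(tab = load_reference_table("mutation_triage")) {
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    out <- NULL
    ov <- .parse_nN_records(tab$ovarian[i])
    if (!is.null(ov)) { ov$tissue <- "ovary"; out <- ov }
    ot <- .parse_nN_records(tab$other[i])
    out <- rbind(out, ot)
    if (is.null(out)) return(NULL)
    out$gene <- tab$gene[i]
    fus <- tab$fusion[i]
    out$fusion_partner <- if (!is.na(fus) && fus != "") fus else NA_character_
    out[, c("gene", "tissue", "n_mutated", "n_screened", "fusion_partner")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
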