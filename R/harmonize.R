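#' Mouse-to-human gene harmonization
#'
#' Gene lists from the murine estrous-cycle study and the human ovarian
#' cancer datasets can only be joined after mapping mouse genes to their
#' human orthologs and normalizing every symbol to a single (HUGO)
#' nomenclature. Matching prefers Entrez IDs and falls back to symbols
#' and aliases.
#'
#' @name harmonize
NULL

#' Read an ortholog map
#'
#' Tab-delimited file with columns \code{mouse_entrez},
#' \code{mouse_symbol}, \code{human_entrez}, \code{hugo_symbol}.
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_ortholog_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mouse_entrez", "mouse_symbol", "human_entrez", "hugo_symbol")
  if (!all(need %in% names(map)))
    stop("ortholog map must have columns: ", paste(need, collapse = ", "))
  map
}

.check_ortholog_map <- function(map) {
  need <- c("mouse_entrez", "mouse_symbol", "human_entrez", "hugo_symbol")
  if (!is.data.frame(map) || !all(need %in% names(map)))
    stop("ortholog map must have columns: ", paste(need, collapse = ", "))
  if (nrow(map) == 0L) stop("ortholog map is empty")
  if (any(is.na(map$mouse_entrez) & is.na(map$human_entrez) &
          (is.na(map$mouse_symbol) | map$mouse_symbol == "")))
    stop("ortholog map rows need a mouse Entrez ID or symbol")
  ## conflicting duplicates: same mouse key mapping twice to the same
  ## human_entrez under different hugo symbols
  key <- paste(map$mouse_entrez, map$human_entrez, sep = "|")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    conf <- unique(key[dup][tapply(map$hugo_symbol[dup], key[dup],
                                   function(s) length(unique(s)) > 1L)[key[dup]]])
    conf <- conf[!is.na(conf)]
    if (length(conf))
      stop("conflicting ortholog rows for: ", paste(conf, collapse = ", "))
  }
  map
}

#' Map mouse genes to human orthologs
#'
#' Produces one output row per (mouse gene, human ortholog) pair; mouse
#' genes with no match are returned separately with a reason code so
#' that no gene is ever silently dropped. Mouse genes matched by Entrez
#' ID take priority; symbol matching (case-insensitive) is the
#' fallback. Mouse genes with more than one human ortholog are flagged
#' \code{one_to_many}.
#'
#' @param mouse_genes data.frame with columns \code{mouse_symbol} and
#'   optionally \code{mouse_entrez}; extra columns (e.g. estrous stage,
#'   direction) are carried through.
#' @param map ortholog map data.frame (see \code{\link{read_ortholog_map}}).
#' @return list with \code{mapped} (data.frame: input columns plus
#'   \code{human_entrez}, \code{hugo_symbol}, \code{one_to_many}) and
#'   \code{unmapped} (data.frame: \code{mouse_symbol}, \code{reason}
#'   with codes NO_ORTHOLOG).
#' @export
map_orthologs <- function(mouse_genes, map) {
  map <- .check_ortholog_map(map)
  if (!is.data.frame(mouse_genes) || !"mouse_symbol" %in% names(mouse_genes))
    stop("mouse_genes must be a data.frame with a mouse_symbol column")
  has_entrez <- "mouse_entrez" %in% names(mouse_genes)

  mapped_rows <- vector("list", nrow(mouse_genes))
  unmapped <- character(0)
  for (i in seq_len(nrow(mouse_genes))) {
    g <- mouse_genes[i, , drop = FALSE]
    hit <- integer(0)
    if (has_entrez && !is.na(g$mouse_entrez))
      hit <- which(!is.na(map$mouse_entrez) & map$mouse_entrez == g$mouse_entrez)
    if (!length(hit) && !is.na(g$mouse_symbol))
      hit <- which(tolower(map$mouse_symbol) == tolower(g$mouse_symbol))
    if (!length(hit)) {
      unmapped <- c(unmapped, g$mouse_symbol)
      next
    }
    out <- g[rep(1L, length(hit)), , drop = FALSE]
    out$human_entrez <- map$human_entrez[hit]
    out$hugo_symbol <- map$hugo_symbol[hit]
    out$one_to_many <- length(hit) > 1L
    mapped_rows[[i]] <- out
  }
  mapped <- do.call(rbind, mapped_rows[!vapply(mapped_rows, is.null, logical(1))])
  if (is.null(mapped))
    mapped <- data.frame(mouse_symbol = character(0),
                         human_entrez = integer(0),
                         hugo_symbol = character(0),
                         one_to_many = logical(0))
  rownames(mapped) <- NULL
  list(mapped = mapped,
       unmapped = data.frame(mouse_symbol = unmapped,
                             reason = rep("NO_ORTHOLOG", length(unmapped)),
                             stringsAsFactors = FALSE))
}

#' Normalize gene symbols to canonical HUGO nomenclature
#'
#' Replaces aliases by their canonical symbols using an alias table.
#' Matching is case-insensitive; the canonical case of the table is
#' preserved. Symbols already canonical pass through unchanged, so the
#' operation is idempotent. Unknown symbols are passed through and
#' flagged (strict = FALSE) or raise an error (strict = TRUE).
#'
#' @param symbols character vector of gene symbols.
#' @param alias_table data.frame with columns \code{alias},
#'   \code{hugo_symbol}.
#' @param strict error on unknown symbols instead of passing through.
#' @return data.frame with columns \code{input}, \code{hugo_symbol},
#'   \code{known} (FALSE for passed-through unknowns).
#' @export
normalize_symbols <- function(symbols, alias_table, strict = FALSE) {
  if (!all(c("alias", "hugo_symbol") %in% names(alias_table)))
    stop("alias_table must have columns alias, hugo_symbol")
  al <- tolower(alias_table$alias)
  amb <- tapply(alias_table$hugo_symbol, al,
                function(s) length(unique(s)) > 1L)
  if (any(amb))
    stop("ambiguous aliases map to multiple canonical symbols: ",
         paste(names(amb)[amb], collapse = ", "))
  ## an alias that is also a canonical symbol of a different gene breaks
  ## idempotence
  canon_lc <- tolower(alias_table$hugo_symbol)
  cyc <- intersect(al[al != canon_lc], canon_lc)
  bad <- cyc[vapply(cyc, function(a) {
    tgt <- unique(alias_table$hugo_symbol[al == a])
    any(tolower(tgt) != a)
  }, logical(1))]
  if (length(bad))
    stop("alias table not acyclic; alias equals canonical symbol of another gene: ",
         paste(bad, collapse = ", "))

  canon <- unique(alias_table$hugo_symbol)
  lut <- stats::setNames(alias_table$hugo_symbol, al)
  lc <- tolower(symbols)
  out <- character(length(symbols)); known <- logical(length(symbols))
  is_canon <- lc %in% tolower(canon)
  out[is_canon] <- canon[match(lc[is_canon], tolower(canon))]
  known[is_canon] <- TRUE
  rest <- !is_canon & lc %in% names(lut)
  out[rest] <- unname(lut[lc[rest]])
  known[rest] <- TRUE
  miss <- !is_canon & !rest
  if (any(miss) && strict)
    stop("unknown symbols: ", paste(unique(symbols[miss]), collapse = ", "))
  out[miss] <- symbols[miss]
  data.frame(input = symbols, hugo_symbol = out, known = known,
             stringsAsFactors = FALSE)
}

#' Deduplicate a harmonized gene list
#'
#' Keeps one record per \code{hugo_symbol} (first occurrence),
#' preserving order of first appearance.
#'
#' @param genes data.frame with a \code{hugo_symbol} column.
#' @param key column to deduplicate on (default \code{hugo_symbol}).
#' @return deduplicated data.frame.
#' @export
dedupe_harmonized <- function(genes, key = "hugo_symbol") {
  genes[!duplicated(genes[[key]]), , drop = FALSE]
}
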