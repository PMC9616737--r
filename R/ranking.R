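#' Marker-gene table
#'
#' One row per (gene, compartment) pair with the linear-scale fold change
#' of the gene in that epidermal compartment relative to the baseline over
#' all analyzed cells.
#'
#' @param gene Gene symbols.
#' @param compartment Compartment labels (e.g. `"SG"`, `"IFE"`,
#'   `"outer bulge"`).
#' @param fold_change Linear fold changes, > 0.
#' @return A data frame of class `"marker_table"`.
#' @export
marker_table <- function(gene, compartment, fold_change) {
  if (length(gene) == 0L) stop("marker table must be non-empty")
  if (any(!is.finite(fold_change)) || any(fold_change <= 0))
    stop("fold changes must be finite and > 0")
  if (anyDuplicated(paste(gene, compartment)))
    stop("duplicate (gene, compartment) rows")
  structure(data.frame(gene = as.character(gene),
                       compartment = as.character(compartment),
                       fold_change = as.numeric(fold_change)),
            class = c("marker_table", "data.frame"))
}

#' Read a marker table from TSV
#'
#' Header columns: `gene`, `compartment`, `fold_change`.
#'
#' @param path Path to a tab-separated file.
#' @return A [marker_table()].
#' @export
read_marker_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "compartment", "fold_change")
  if (!all(need %in% names(tab)))
    stop("marker TSV must have columns: ", paste(need, collapse = ", "))
  marker_table(tab$gene, tab$compartment, tab$fold_change)
}

#' Read gene-to-GO annotations
#'
#' Accepts either a headerless two-column TSV (`gene<TAB>GO:ddddddd`, one
#' pair per line, `#` comments allowed) or a GAF 2.x file (`!` comment
#' header; gene symbol from column 3, GO ID from column 5). The format is
#' auto-detected from the first non-comment line.
#'
#' @param path Path to the annotation file.
#' @return A named list mapping gene symbol to a character vector of GO
#'   IDs (genes without annotation are absent, never empty).
#' @export
read_go_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_gaf <- any(startsWith(lines, "!")) ||
    length(strsplit(lines[!startsWith(lines, "#")][1L], "\t")[[1L]]) >= 15L
  body <- lines[!startsWith(lines, "!") & !startsWith(lines, "#")]
  if (length(body) == 0L) stop("annotation file contains no records")
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (is_gaf) {
    gene <- vapply(fields, `[`, "", 3L)
    go <- vapply(fields, `[`, "", 5L)
  } else {
    if (any(lengths(fields) < 2L))
      stop("two-column annotation file has malformed lines")
    gene <- vapply(fields, `[`, "", 1L)
    go <- vapply(fields, `[`, "", 2L)
  }
  bad <- !grepl("^GO:[0-9]{7}$", go)
  if (any(bad))
    stop("malformed GO identifiers (expected GO:ddddddd): ",
         paste(utils::head(unique(go[bad]), 3L), collapse = ", "))
  ann <- lapply(split(go, gene), unique)
  if (length(ann) == 0L) stop("empty annotation map")
  ann
}

#' Filter marker rows by GO annotation
#'
#' Keeps exactly the rows whose gene carries at least one of the configured
#' GO terms in the annotation map; unannotated genes are dropped and row
#' order is preserved. Matching is by exact GO identifier — no
#' ontology-graph descendant expansion. The defaults are the adhesion
#' screen terms: cell-cell adhesion mediator activity (GO:0098632) and
#' cell-matrix adhesion (GO:0007160).
#'
#' @param rows A [marker_table()].
#' @param annotations A gene-to-GO map as from [read_go_annotations()]
#'   (named list of character vectors).
#' @param go_terms Character vector of GO IDs to keep. Default
#'   `c("GO:0098632", "GO:0007160")`.
#' @return The filtered `marker_table` (possibly zero rows, with a warning
#'   when nothing matches).
#' @export
filter_by_go <- function(rows, annotations,
                         go_terms = c("GO:0098632", "GO:0007160")) {
  stopifnot(inherits(rows, "marker_table"))
  if (nrow(rows) == 0L) stop("marker table must be non-empty")
  if (!is.list(annotations) || length(annotations) == 0L ||
      is.null(names(annotations)))
    stop("empty or unnamed annotation map (wrong file supplied?)")
  if (length(go_terms) == 0L) stop("at least one GO term is required")
  keep <- vapply(rows$gene, function(g) {
    ids <- annotations[[g]]
    !is.null(ids) && any(ids %in% go_terms)
  }, TRUE, USE.NAMES = FALSE)
  if (!any(keep))
    warning("no marker gene carries any of the configured GO terms")
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("marker_table", "data.frame"))
}

#' Rank marker genes by fold change within each compartment
#'
#' Sorts rows by descending fold change within compartment; ties are broken
#' alphabetically by gene symbol. An optional subset list (e.g. a curated
#' non-integrin membrane-protein list) restricts the table before ranking.
#'
#' @param rows A (typically GO-filtered) [marker_table()].
#' @param subset_list Optional character vector of gene symbols to restrict
#'   to before ranking.
#' @return A data frame of class `c("ranked_markers", "marker_table")` with
#'   an added integer `rank` column (1 = strongest enrichment, per
#'   compartment).
#' @export
rank_markers <- function(rows, subset_list = NULL) {
  stopifnot(inherits(rows, "marker_table"))
  if (!is.null(subset_list)) {
    rows <- rows[rows$gene %in% subset_list, , drop = FALSE]
  }
  if (nrow(rows) == 0L) {
    out <- cbind(rows, rank = integer(0))
    return(structure(out, class = c("ranked_markers", "marker_table",
                                    "data.frame")))
  }
  ord <- order(rows$compartment, -rows$fold_change, rows$gene)
  out <- rows[ord, , drop = FALSE]
  out$rank <- stats::ave(out$fold_change, out$compartment,
                         FUN = seq_along)
  out$rank <- as.integer(out$rank)
  rownames(out) <- NULL
  structure(out, class = c("ranked_markers", "marker_table", "data.frame"))
}

#' Top-ranked candidate genes in a compartment
#'
#' @param ranked A `"ranked_markers"` table from [rank_markers()].
#' @param compartment Compartment label; must be present in the table
#'   unless the whole table is empty.
#' @param top_n Number of candidates to return (>= 1); shorter lists are
#'   returned in full.
#' @return Character vector of gene symbols in rank order (possibly empty,
#'   with a warning).
#' @export
top_candidates <- function(ranked, compartment, top_n = 5) {
  stopifnot(inherits(ranked, "ranked_markers"), top_n >= 1)
  if (nrow(ranked) == 0L) {
    warning("no genes left after filtering; returning empty candidate list")
    return(character(0))
  }
  if (!compartment %in% ranked$compartment)
    stop("unknown compartment: ", compartment)
  sub <- ranked[ranked$compartment == compartment, , drop = FALSE]
  sub$gene[order(sub$rank)][seq_len(min(top_n, nrow(sub)))]
}

#' Write a ranked marker table to TSV
#'
#' @param ranked A `"ranked_markers"` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_markers <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_markers"))
  utils::write.table(ranked, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
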