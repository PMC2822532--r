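#' splicefun: splice-function networks from protein keyword annotations
#'
#' The package projects transcriptional units (TUs) and their splice-variant
#' proteins onto the functional space of the proteome. A functional label
#' (FL) is the unique, sorted, deduplicated combination of annotation
#' keywords carried by a protein; TUs whose annotated isoforms all share one
#' FL are "monoform", TUs whose isoforms realize two or more FLs are
#' "polyform". On top of this classification the package provides
#' frequency-distribution fitting (exponential body + generalized discrete
#' Pareto tail mixtures), weighted FL co-occurrence networks built from
#' polyform TUs, keyword over-representation tests, and a synthetic-data
#' generator emulating curated isoform protein sets.
#'
#' @keywords internal
#' @importFrom stats coef cor na.omit pexp phyper rbinom rexp rpois runif
#'   setNames var
#' @importFrom utils combn head read.delim write.table
"_PACKAGE"

# separator used for canonical keyword-tuple keys; sorts below all printable
# characters so that joined-string order equals lexicographic tuple order
.KEY_SEP <- "\x1f"

new_organism_dataset <- function(organism, proteins, tus,
                                 catalogue = NULL) {
  structure(
    list(organism = organism, proteins = proteins, tus = tus,
         catalogue = catalogue),
    class = "organism_dataset"
  )
}

#' Assemble an organism dataset from a protein annotation table
#'
#' Builds the container shared by all pipeline stages from a data frame of
#' protein records. Proteins are grouped into transcriptional units by
#' `tu_id`; duplicate keywords within one protein are removed. The FL
#' catalogue is not built yet (see [build_catalogue()]), so TU classes are
#' undetermined at this stage.
#'
#' @param protein_id,tu_id character vectors of equal length; `protein_id`
#'   must be unique.
#' @param keywords list of character vectors (one per protein), or a single
#'   character vector of `;`-separated keyword strings. Empty keyword sets
#'   are allowed and retained.
#' @param organism organism name stored with the dataset.
#' @return An `organism_dataset`: a list with elements `organism`,
#'   `proteins` (data frame with list-column `keywords`), `tus` (data frame
#'   with per-TU protein counts) and `catalogue` (`NULL` until built).
#' @seealso [read_annotation_table()], [build_catalogue()]
#' @export
organism_dataset <- function(protein_id, tu_id, keywords, organism) {
  protein_id <- as.character(protein_id)
  tu_id <- as.character(tu_id)
  if (length(protein_id) != length(tu_id))
    stop("protein_id and tu_id must have equal length")
  if (anyDuplicated(protein_id)) {
    dup <- protein_id[duplicated(protein_id)][1L]
    stop("duplicate protein_id: ", dup)
  }
  if (is.character(keywords)) keywords <- strsplit(keywords, ";", fixed = TRUE)
  if (length(keywords) != length(protein_id))
    stop("keywords must match protein_id in length")
  keywords <- lapply(keywords, function(k) {
    k <- as.character(k)
    unique(k[nzchar(k)])
  })
  proteins <- data.frame(protein_id = protein_id, tu_id = tu_id,
                         stringsAsFactors = FALSE)
  proteins$keywords <- keywords
  tu_ids <- unique(tu_id)
  tus <- data.frame(tu_id = tu_ids,
                    n_proteins = as.integer(table(factor(tu_id, tu_ids))),
                    class = rep(NA_character_, length(tu_ids)),
                    stringsAsFactors = FALSE)
  tus$fls <- rep(list(character(0)), nrow(tus))
  new_organism_dataset(organism, proteins, tus)
}

#' Read a protein-to-keyword annotation table
#'
#' Ingests the tab-separated mapping produced by upstream annotation
#' scanners: one line per protein with columns `protein_id`, `tu_id` and a
#' `;`-joined keyword list (the keyword field may be empty). This is the
#' entry point for real data; synthetic datasets written by
#' [write_annotation_table()] flow through the identical path.
#'
#' @param path path to a UTF-8 TSV file.
#' @param organism organism name stored with the dataset.
#' @param header logical; skip one header line (default `FALSE`).
#' @return An `organism_dataset`; see [organism_dataset()].
#' @export
read_annotation_table <- function(path, organism, header = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  first <- if (header) 2L else 1L
  if (length(lines) >= first) lines <- lines[first:length(lines)]
  else lines <- character(0)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(organism_dataset(character(0), character(0), list(), organism))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  # a trailing empty keyword field is dropped by strsplit; restore it
  bad <- which(nfield < 2L | nfield > 3L)
  if (length(bad))
    stop("malformed line ", bad[1L] + (if (header) 1L else 0L),
         ": expected 3 tab-separated fields")
  pid <- vapply(parts, `[[`, "", 1L)
  tid <- vapply(parts, `[[`, "", 2L)
  kw <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "", "")
  organism_dataset(pid, tid, kw, organism)
}

#' Write an organism dataset as an annotation table
#'
#' Inverse of [read_annotation_table()]: one line per protein,
#' `protein_id<TAB>tu_id<TAB>kw1;kw2;...`. Keywords are written in their
#' stored order; re-reading the file reproduces the dataset's protein
#' records exactly.
#'
#' @param dataset an `organism_dataset`.
#' @param path output file path.
#' @export
write_annotation_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "organism_dataset"))
  p <- dataset$proteins
  kw <- vapply(p$keywords, paste, "", collapse = ";")
  writeLines(paste(p$protein_id, p$tu_id, kw, sep = "\t"), path,
             useBytes = TRUE)
  invisible(path)
}

#' @export
print.organism_dataset <- function(x, ...) {
  cat("organism_dataset:", x$organism, "\n")
  cat("  proteins:", nrow(x$proteins), " TUs:", nrow(x$tus), "\n")
  if (!is.null(x$catalogue)) {
    cat("  catalogue: ", nrow(x$catalogue$table), " FLs (scope '",
        x$catalogue$scope, "')\n", sep = "")
    cls <- table(factor(x$tus$class,
                        c("monoform", "polyform", "unannotated")))
    cat("  classes: ", paste(names(cls), cls, sep = "=", collapse = " "),
        "\n", sep = "")
  } else cat("  catalogue: <not built>\n")
  invisible(x)
}

#' Export a splice-function network
#'
#' Writes an SFN graph in one of Cytoscape's interchange formats. The SIF
#' format (`node1<TAB>sw<TAB>node2`, isolated nodes as bare names) carries
#' no edge attributes, so edge weights survive a round trip only through
#' GraphML, where they are written as the numeric edge attribute `weight`.
#'
#' @param graph an igraph object as returned by [build_sfn()].
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @seealso [read_network()]
#' @export
write_network <- function(graph, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "igraph"))
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(graph, names = TRUE)
  lines <- character(0)
  if (nrow(el))
    lines <- paste(el[, 1L], "sw", el[, 2L], sep = "\t")
  deg <- igraph::degree(graph)
  isolated <- names(deg)[deg == 0L]
  writeLines(c(lines, isolated), path, useBytes = TRUE)
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path file path.
#' @param format `"sif"` or `"graphml"`.
#' @return An undirected igraph object; GraphML restores the `weight` edge
#'   attribute, SIF edges get weight 1.
#' @export
read_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(igraph::as_undirected(g, mode = "collapse"))
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 1L & nf != 3L))
    stop("malformed SIF line ", which(nf != 1L & nf != 3L)[1L])
  edges <- do.call(rbind, lapply(parts[nf == 3L],
                                 function(p) c(p[[1L]], p[[3L]])))
  singles <- vapply(parts[nf == 1L], `[[`, "", 1L)
  nodes <- unique(c(if (!is.null(edges)) as.vector(t(edges)), singles))
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
    igraph::E(g)$weight <- 1
  }
  g
}
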