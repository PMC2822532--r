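# Functional-label catalogues: canonical keyword tuples, FL identifier
# assignment, per-protein/per-TU labeling, and cross-organism intersection.

#' Canonicalize a keyword set
#'
#' Reduces a keyword collection to its canonical tuple: unique elements in
#' byte-wise (C locale) sorted order. Two proteins have the same functional
#' label exactly when their canonical tuples are equal.
#'
#' @param keywords character vector (order and duplicates irrelevant).
#' @return Sorted character vector of unique keywords; empty input gives a
#'   zero-length vector.
#' @examples
#' canonicalize(c("Transmembrane", "Membrane", "Membrane"))
#' @export
canonicalize <- function(keywords) {
  keywords <- as.character(keywords)
  sort(unique(keywords[nzchar(keywords)]), method = "radix")
}

canonical_key <- function(keywords) {
  paste(canonicalize(keywords), collapse = .KEY_SEP)
}

key_to_keywords <- function(key) strsplit(key, .KEY_SEP, fixed = TRUE)

#' Build the functional-label catalogue of a dataset
#'
#' Every distinct nonempty canonical keyword tuple over all proteins becomes
#' one functional label. Identifiers follow the scheme `FL{scope}{n}` with
#' `n` the 1-based rank of the tuple in lexicographic (byte-wise) order, so
#' catalogue construction is deterministic and invariant to input order.
#' Each protein with nonempty keywords is mapped to its FL; each TU receives
#' the set of distinct FLs of its proteins and is classified:
#' \describe{
#'   \item{monoform}{exactly one distinct FL among its annotated isoforms,}
#'   \item{polyform}{two or more distinct FLs,}
#'   \item{unannotated}{no annotated isoform at all.}
#' }
#'
#' @param dataset an `organism_dataset`.
#' @param scope short scope code embedded in FL ids (e.g. `"h"`, `"m"`,
#'   `"c"`, or any organism mnemonic); must be nonempty.
#' @return The dataset with `$catalogue` set (a `fl_catalogue`), a per
#'   protein `fl_id` column, and per-TU `fls` / `class` filled in.
#' @export
build_catalogue <- function(dataset, scope) {
  stopifnot(inherits(dataset, "organism_dataset"))
  if (!is.character(scope) || length(scope) != 1L || !nzchar(scope))
    stop("scope must be a nonempty string")
  p <- dataset$proteins
  keys <- vapply(p$keywords, canonical_key, "")
  uniq <- sort(unique(keys[nzchar(keys)]), method = "radix")
  fl_ids <- if (length(uniq)) paste0("FL", scope, seq_along(uniq))
            else character(0)
  tab <- data.frame(fl_id = fl_ids, key = uniq, stringsAsFactors = FALSE)
  tab$keywords <- key_to_keywords(uniq)
  idx <- match(keys, uniq)
  p$fl_id <- ifelse(is.na(idx), NA_character_, fl_ids[idx])
  occ <- table(factor(p$fl_id, levels = fl_ids))
  tab$n_proteins <- as.integer(occ)

  tus <- dataset$tus
  fl_by_tu <- split(p$fl_id, factor(p$tu_id, levels = tus$tu_id))
  tus$fls <- lapply(fl_by_tu, function(f) sort(unique(f[!is.na(f)])))
  nfl <- lengths(tus$fls)
  tus$class <- ifelse(nfl == 0L, "unannotated",
                      ifelse(nfl == 1L, "monoform", "polyform"))
  catalogue <- structure(list(scope = scope, table = tab),
                         class = "fl_catalogue")
  new_organism_dataset(dataset$organism, p, tus, catalogue)
}

#' @export
print.fl_catalogue <- function(x, ...) {
  cat("fl_catalogue: scope '", x$scope, "', ", nrow(x$table), " FLs\n",
      sep = "")
  invisible(x)
}

#' Export a catalogue as TSV (fl_id, ';'-joined keywords, occurrence count)
#'
#' @param catalogue an `fl_catalogue`.
#' @param path output path.
#' @export
write_catalogue <- function(catalogue, path) {
  stopifnot(inherits(catalogue, "fl_catalogue"))
  tab <- catalogue$table
  out <- data.frame(fl_id = tab$fl_id,
                    keywords = vapply(tab$keywords, paste, "",
                                      collapse = ";"),
                    n_proteins = tab$n_proteins)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intersect functional-label catalogues across organisms
#'
#' Finds the canonical keyword tuples present in every catalogue: the set of
#' functions shared by all organisms compared, a proxy for a conserved core
#' of the proteome functional space. Shared labels are re-issued under scope
#' `"c"` (common), and keyword membership is tallied over the shared labels.
#'
#' @param catalogues list of at least two `fl_catalogue` objects (or
#'   `organism_dataset`s carrying one).
#' @return A `shared_fl_report`: list with `common_count`, `common_labels`
#'   (data frame `fl_id`, list-column `keywords`) and `keyword_frequency`
#'   (named integer vector: for each keyword, the number of shared FLs
#'   containing it).
#' @export
intersect_catalogues <- function(catalogues) {
  catalogues <- lapply(catalogues, function(x) {
    if (inherits(x, "organism_dataset")) x <- x$catalogue
    if (!inherits(x, "fl_catalogue"))
      stop("expected fl_catalogue or organism_dataset with catalogue")
    x
  })
  if (length(catalogues) < 2L)
    stop("need at least 2 catalogues to intersect")
  keysets <- lapply(catalogues, function(cat) cat$table$key)
  common <- Reduce(intersect, keysets)
  common <- sort(common, method = "radix")
  labels <- data.frame(
    fl_id = if (length(common)) paste0("FLc", seq_along(common))
            else character(0),
    key = common, stringsAsFactors = FALSE)
  labels$keywords <- key_to_keywords(common)
  kw <- unlist(labels$keywords)
  keyword_frequency <- if (length(kw)) {
    tb <- table(kw)
    setNames(as.integer(tb), names(tb))
  } else setNames(integer(0), character(0))
  structure(list(common_count = length(common),
                 common_labels = labels,
                 keyword_frequency = keyword_frequency),
            class = "shared_fl_report")
}

#' @export
print.shared_fl_report <- function(x, ...) {
  cat("shared_fl_report:", x$common_count, "common FLs,",
      length(x$keyword_frequency), "distinct keywords\n")
  invisible(x)
}

#' Top keywords of a shared-FL report
#'
#' Ranks keywords by the number of shared functional labels containing
#' them, the tally behind "top keyword" diagrams of conserved function sets.
#' Ties are broken lexicographically.
#'
#' @param report a `shared_fl_report`.
#' @param n maximum number of keywords to return (`>= 1`).
#' @return Data frame with columns `keyword` and `count`, at most `n` rows.
#' @export
top_keywords <- function(report, n) {
  stopifnot(inherits(report, "shared_fl_report"), n >= 1)
  f <- report$keyword_frequency
  if (!length(f)) return(data.frame(keyword = character(0),
                                    count = integer(0)))
  ord <- order(-f, names(f), method = "radix")
  f <- f[ord]
  k <- min(as.integer(n), length(f))
  data.frame(keyword = names(f)[seq_len(k)],
             count = as.integer(f[seq_len(k)]),
             stringsAsFactors = FALSE)
}
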