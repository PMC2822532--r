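# Monoform/polyform classification, functional-switch detection via
# Jaccard comparison of keyword sets, and the cross-organism complexity
# correlation.

#' Jaccard index and distance between two keyword sets
#'
#' `index = |a n b| / |a u b|`, `distance = 1 - index`. A candidate
#' functional switch is an isoform pair whose keyword sets are disjoint
#' (index 0), e.g. a protease isoform versus an oxygen-transport isoform of
#' the same TU.
#'
#' @param a,b character vectors of keywords; at least one must be nonempty
#'   (the measure is undefined on two empty sets).
#' @return List with elements `index` and `distance`, both in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(as.character(a)); a <- a[nzchar(a)]
  b <- unique(as.character(b)); b <- b[nzchar(b)]
  if (length(a) == 0L && length(b) == 0L)
    stop("jaccard undefined for two empty sets")
  idx <- length(intersect(a, b)) / length(union(a, b))
  list(index = idx, distance = 1 - idx)
}

#' Detect candidate functional switches
#'
#' Scans every polyform TU for unordered pairs of annotated isoforms with
#' disjoint keyword sets (Jaccard index 0). Such pairs mark TUs whose
#' alternative splicing appears to switch protein function outright rather
#' than modulate it. Pairs involving an unannotated protein are skipped.
#'
#' @param dataset an `organism_dataset` with catalogue built.
#' @param denominator population for the switch fraction: `"annotated"`
#'   (default), `"all"` TUs, or `"polyform"` only.
#' @return A `switch_report`: list with `candidates` (data frame `tu_id`,
#'   `protein_a`, `protein_b`, `jaccard_index`, `jaccard_distance`),
#'   `n_switch_tus`, `n_denominator`, and `switch_fraction` (percent of
#'   denominator TUs with at least one disjoint pair).
#' @export
detect_switches <- function(dataset,
                            denominator = c("annotated", "all",
                                            "polyform")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(dataset, "organism_dataset"))
  if (is.null(dataset$catalogue)) stop("catalogue not built")
  tus <- dataset$tus
  poly_ids <- tus$tu_id[tus$class == "polyform"]
  p <- dataset$proteins
  ann <- p[!is.na(p$fl_id), , drop = FALSE]
  rows <- list()
  for (tid in poly_ids) {
    sub <- ann[ann$tu_id == tid, , drop = FALSE]
    if (nrow(sub) < 2L) next
    prs <- combn(nrow(sub), 2L)
    for (j in seq_len(ncol(prs))) {
      i1 <- prs[1L, j]; i2 <- prs[2L, j]
      jc <- jaccard(sub$keywords[[i1]], sub$keywords[[i2]])
      if (jc$index == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          tu_id = tid,
          protein_a = sub$protein_id[i1],
          protein_b = sub$protein_id[i2],
          jaccard_index = jc$index,
          jaccard_distance = jc$distance,
          stringsAsFactors = FALSE)
      }
    }
  }
  candidates <- if (length(rows)) do.call(rbind, rows)
    else data.frame(tu_id = character(0), protein_a = character(0),
                    protein_b = character(0), jaccard_index = numeric(0),
                    jaccard_distance = numeric(0))
  n_den <- switch(denominator,
                  annotated = sum(tus$class != "unannotated"),
                  all = nrow(tus),
                  polyform = sum(tus$class == "polyform"))
  n_switch <- length(unique(candidates$tu_id))
  structure(list(candidates = candidates,
                 n_switch_tus = n_switch,
                 n_denominator = n_den,
                 switch_fraction = if (n_den > 0) 100 * n_switch / n_den
                                   else NA_real_),
            class = "switch_report")
}

#' @export
print.switch_report <- function(x, ...) {
  cat("switch_report:", x$n_switch_tus, "switch TUs /", x$n_denominator,
      sprintf("TUs (%.2f%%), %d candidate pairs\n",
              x$switch_fraction, nrow(x$candidates)))
  invisible(x)
}

#' Monoform/polyform classification summary
#'
#' Counts TUs per class and computes the headline complexity statistics:
#' the polyform-to-monoform percentage (`100 * n_poly / n_mono`) and the
#' mean number of splice variants per classified (annotated) TU.
#'
#' @param dataset an `organism_dataset` with catalogue built.
#' @return A `classification_summary`: one-row data frame with columns
#'   `organism`, `n_poly`, `n_mono`, `n_unannotated`, `poly_over_mono_pct`
#'   (full precision; `NA` when `n_mono == 0`) and `mean_sv_per_tu`.
#' @export
tu_summary <- function(dataset) {
  stopifnot(inherits(dataset, "organism_dataset"))
  if (is.null(dataset$catalogue)) stop("catalogue not built")
  tus <- dataset$tus
  n_poly <- sum(tus$class == "polyform")
  n_mono <- sum(tus$class == "monoform")
  n_un <- sum(tus$class == "unannotated")
  classified <- tus$class != "unannotated"
  out <- data.frame(
    organism = dataset$organism,
    n_poly = n_poly, n_mono = n_mono, n_unannotated = n_un,
    poly_over_mono_pct = if (n_mono > 0) 100 * n_poly / n_mono else NA_real_,
    mean_sv_per_tu = if (any(classified))
      mean(tus$n_proteins[classified]) else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("classification_summary", "data.frame")
  out
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("%s: %d polyform / %d monoform (%s%%), %d unannotated, %.2f SVs/TU\n",
              x$organism, x$n_poly, x$n_mono,
              ifelse(is.na(x$poly_over_mono_pct), "NA",
                     sprintf("%.2f", x$poly_over_mono_pct)),
              x$n_unannotated, x$mean_sv_per_tu))
  invisible(x)
}

#' Correlation between splicing intensity and polyform fraction
#'
#' Pearson correlation, across organisms, between the mean number of splice
#' variants per TU (x) and the fraction of polyform TUs among classified
#' TUs (y). The `exclude` argument supports outlier handling (e.g. dropping
#' Arabidopsis, whose curated isoform coverage is an outlier).
#'
#' @param summaries list of `classification_summary` objects, or a data
#'   frame binding them.
#' @param exclude character vector of organism names to drop.
#' @return Pearson `r` (length-1 numeric).
#' @export
complexity_correlation <- function(summaries, exclude = character(0)) {
  if (is.data.frame(summaries)) df <- summaries
  else df <- do.call(rbind, lapply(summaries, as.data.frame))
  df <- df[!(df$organism %in% exclude), , drop = FALSE]
  if (nrow(df) < 3L) stop("need at least 3 organisms after exclusion")
  x <- df$mean_sv_per_tu
  y <- df$n_poly / (df$n_poly + df$n_mono)
  if (var(x) == 0 || var(y) == 0)
    stop("zero variance; correlation undefined")
  cor(x, y)
}
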