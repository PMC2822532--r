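# Keyword over-representation in TU groups: one-sided hypergeometric test
# with the modified Bonferroni correction (multiply by the number of terms
# represented in the study set, cap at 1).

#' Upper-tail hypergeometric probability
#'
#' `P(X >= x)` where `X ~ Hypergeometric(N, K, n)`: drawing `n` objects
#' without replacement from a population of `N` containing `K` marked
#' ones. The over-representation p-value of observing `x` or more marked
#' objects in the study set.
#'
#' @param x observed count in the study set.
#' @param n study-set size.
#' @param K population occurrence count of the term.
#' @param N population size.
#' @return `P(X >= x)`; exactly 1 at `x = 0`.
#' @export
hypergeom_upper <- function(x, n, K, N) {
  ok <- K >= 0 & K <= N & n >= 0 & n <= N & x >= 0 & x <= pmin(n, K)
  if (!all(ok)) stop("inconsistent counts: need 0 <= x <= min(n, K), K <= N, n <= N")
  phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Keyword over-representation in a TU study set
#'
#' Tests every keyword occurring in the study set for over-representation
#' relative to the population of TUs. The counting unit is the TU: a
#' keyword counts once per TU if any of its proteins carries it. Raw
#' p-values are upper-tail hypergeometric; the modified Bonferroni
#' correction multiplies by the number of distinct keywords represented in
#' the study set (capped at 1).
#'
#' @param dataset an `organism_dataset` with catalogue built.
#' @param study character vector of TU ids (must all be in the population).
#' @param threshold adjusted-p cutoff for reporting (default `1e-4`).
#' @param population `"annotated"` TUs (default) or `"all"` TUs.
#' @param all_results logical; return every tested keyword instead of only
#'   those below the threshold.
#' @return Data frame ordered by adjusted p-value (ties by keyword):
#'   `rank`, `keyword`, `x`, `n`, `K`, `N`, `p_raw`, `p_adj`.
#' @export
enrich <- function(dataset, study, threshold = 1e-4,
                   population = c("annotated", "all"),
                   all_results = FALSE) {
  population <- match.arg(population)
  stopifnot(inherits(dataset, "organism_dataset"))
  if (is.null(dataset$catalogue)) stop("catalogue not built")
  if (length(study) == 0L) stop("empty study set")
  tus <- dataset$tus
  pop_ids <- if (population == "annotated")
    tus$tu_id[tus$class != "unannotated"] else tus$tu_id
  if (!all(study %in% pop_ids))
    stop("study set contains TUs outside the population")
  study <- unique(study)

  # keyword -> TU incidence, one count per TU
  p <- dataset$proteins
  p <- p[p$tu_id %in% pop_ids, , drop = FALSE]
  pairs <- unique(data.frame(
    tu_id = rep(p$tu_id, lengths(p$keywords)),
    keyword = unlist(p$keywords), stringsAsFactors = FALSE))
  K_tab <- table(pairs$keyword)
  in_study <- pairs[pairs$tu_id %in% study, , drop = FALSE]
  x_tab <- table(in_study$keyword)
  terms <- names(x_tab)
  T_terms <- length(terms)
  if (T_terms == 0L)
    return(data.frame(rank = integer(0), keyword = character(0),
                      x = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0)))
  N <- length(pop_ids)
  n <- length(study)
  x <- as.integer(x_tab)
  K <- as.integer(K_tab[terms])
  p_raw <- hypergeom_upper(x, n, K, N)
  p_adj <- pmin(1, p_raw * T_terms)
  out <- data.frame(keyword = terms, x = x, n = n, K = K, N = N,
                    p_raw = p_raw, p_adj = p_adj,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$keyword, method = "radix"), ,
             drop = FALSE]
  if (!all_results) out <- out[out$p_adj < threshold, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
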