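# Shared in-code fixtures and independent oracles for the test suite.

# two-TU toy dataset: tu1 has isoforms with FLs {A} and {A,B}; tu2 has one
make_toy_dataset <- function() {
  ds <- organism_dataset(
    protein_id = c("p1", "p2", "p3"),
    tu_id = c("tu1", "tu1", "tu2"),
    keywords = list(c("A"), c("A", "B"), c("A")),
    organism = "toy")
  build_catalogue(ds, scope = "x")
}

# random small annotation dataset drawing keyword sets from a fixed pool
# of at most 6 distinct functional labels
random_small_dataset <- function(n_tu = 6L) {
  pool <- list("A", "B", c("A", "B"), "C", c("B", "C"), "D")
  pid <- character(0); tid <- character(0); kw <- list()
  for (t in seq_len(n_tu)) {
    n_prot <- sample(1:4, 1L)
    for (p in seq_len(n_prot)) {
      pid <- c(pid, sprintf("t%dp%d", t, p))
      tid <- c(tid, sprintf("tu%d", t))
      kw <- c(kw, if (runif(1) < 0.15) list(character(0))
              else pool[sample(6L, 1L)])
    }
  }
  build_catalogue(organism_dataset(pid, tid, kw, "rand"), scope = "r")
}

# brute-force SFN edge weights: direct enumeration over (TU, FL-pair)
# incidences, independent of the igraph-based implementation
sfn_oracle_weights <- function(dataset) {
  tus <- dataset$tus
  fl_ids <- dataset$catalogue$table$fl_id
  out <- list()
  if (length(fl_ids) >= 2L) {
    prs <- combn(sort(fl_ids), 2L)
    for (j in seq_len(ncol(prs))) {
      f1 <- prs[1L, j]; f2 <- prs[2L, j]
      w <- 0L
      for (i in seq_len(nrow(tus))) {
        if (tus$class[i] == "polyform" &&
            f1 %in% tus$fls[[i]] && f2 %in% tus$fls[[i]]) w <- w + 1L
      }
      if (w > 0L) out[[paste(f1, f2, sep = "|")]] <- w
    }
  }
  out
}

# edge weights of an igraph SFN as a named list keyed "fl1|fl2" (sorted)
sfn_edge_weights <- function(g) {
  if (igraph::ecount(g) == 0L) return(list())
  el <- igraph::as_edgelist(g)
  keys <- apply(el, 1L, function(e) paste(sort(e), collapse = "|"))
  stats::setNames(as.list(igraph::E(g)$weight), keys)
}

# exact upper-tail hypergeometric by counting draws with binomial
# coefficients (exact in double precision for N <= 20)
hyper_upper_oracle <- function(x, n, K, N) {
  i <- x:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# single default synthetic dataset shared across tests (generation is the
# expensive step; the object is never mutated)
.synth_cache <- new.env(parent = emptyenv())
shared_synth <- function() {
  if (is.null(.synth_cache$ds)) {
    .synth_cache$cfg <- sim_config()
    .synth_cache$ds <- generate_organism(.synth_cache$cfg)
  }
  list(cfg = .synth_cache$cfg, ds = .synth_cache$ds)
}
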