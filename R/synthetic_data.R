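# Synthetic organism datasets with the statistical structure the analysis
# assumes (exponential-like FLs per TU, Pareto-like TUs per FL, mixture
# body+tail SVs per TU), plus exact degenerate fixtures that reproduce
# printed marginal counts.

#' Simulation configuration
#'
#' Defaults emulate a curated mammalian isoform protein set: polyform
#' fraction 0.127 among annotated TUs, 30% unannotated TUs, splice-variant
#' counts from a mixture of a discretized exponential body (rate 0.49,
#' below 10 SVs, weight 0.985) and a generalized discrete Pareto tail
#' (k = 4.16, b = 8.75, 10..73 SVs), distinct-FL counts per TU capped at 9.
#'
#' @param organism organism mnemonic; also used as the FL id scope.
#' @param n_tus number of TUs to generate.
#' @param keyword_vocab_size size of the keyword vocabulary.
#' @param mean_keywords_per_fl mean number of keywords per functional
#'   label (`>= 1`).
#' @param sv_model list with `s` (body weight), `exp_b` (body rate),
#'   `gdp_k`, `gdp_b` (tail shape/shift), `breakpoint`, `J`.
#' @param fl_per_tu_exp_b decay rate of the truncated discretized
#'   exponential for distinct-FL counts of polyform TUs.
#' @param polyform_target target fraction of polyform TUs among annotated
#'   TUs.
#' @param unannotated_fraction fraction of TUs with no keyword annotation.
#' @param fl_cap maximum number of distinct FLs per TU.
#' @param seed integer RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(organism = "synth",
                       n_tus = 20000L,
                       keyword_vocab_size = 400L,
                       mean_keywords_per_fl = 3,
                       sv_model = list(s = 0.985, exp_b = 0.49,
                                       gdp_k = 4.16, gdp_b = 8.75,
                                       breakpoint = 10L, J = 73L),
                       fl_per_tu_exp_b = 2.0,
                       polyform_target = 0.127,
                       unannotated_fraction = 0.30,
                       fl_cap = 9L,
                       seed = 2010L) {
  stopifnot(n_tus >= 1, keyword_vocab_size >= 2,
            mean_keywords_per_fl >= 1,
            polyform_target >= 0, polyform_target <= 1,
            unannotated_fraction >= 0, unannotated_fraction <= 1,
            fl_per_tu_exp_b > 0, fl_cap >= 2)
  stopifnot(sv_model$s >= 0, sv_model$s <= 1, sv_model$exp_b > 0,
            sv_model$gdp_k > 0, sv_model$gdp_b > -1,
            sv_model$breakpoint >= 2, sv_model$J >= sv_model$breakpoint)
  structure(list(organism = organism, n_tus = as.integer(n_tus),
                 keyword_vocab_size = as.integer(keyword_vocab_size),
                 mean_keywords_per_fl = mean_keywords_per_fl,
                 sv_model = sv_model,
                 fl_per_tu_exp_b = fl_per_tu_exp_b,
                 polyform_target = polyform_target,
                 unannotated_fraction = unannotated_fraction,
                 fl_cap = as.integer(fl_cap),
                 seed = as.integer(seed)),
            class = "sim_config")
}

sample_pmf <- function(n, pmf, support) {
  cdf <- cumsum(pmf)
  cdf[length(cdf)] <- 1
  support[findInterval(runif(n), cdf) + 1L]
}

#' Sample from the generalized discrete Pareto distribution
#'
#' Inverse-CDF draws over the finite support `1..J` from
#' `f(m) = C / (m + b)^(k+1)`.
#'
#' @param n number of draws.
#' @inheritParams gdp_norm_const
#' @param seed optional RNG seed; draws are reproducible per seed.
#' @return Integer vector of length `n`.
#' @export
sample_gdp <- function(n, k, b, J, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.infinite(J)) stop("sampling requires a finite J")
  pmf <- gdp_pmf(seq_len(J), k, b, J)
  sample_pmf(n, pmf, seq_len(J))
}

trunc_exp_pmf <- function(rate, lo, hi) {
  m <- seq(lo, hi)
  w <- exp(-rate * m)
  w / sum(w)
}

#' Splice-variant mixture pmf over 1..J
#'
#' The generative pmf of SV counts: discretized exponential body on
#' `1..breakpoint-1` with total mass `s`, GDP tail on `breakpoint..J` with
#' mass `1 - s`.
#'
#' @param sv_model model list as in [sim_config()].
#' @return Numeric vector of length `J` summing to 1.
#' @export
sv_mixture_pmf <- function(sv_model) {
  bp <- sv_model$breakpoint; J <- sv_model$J
  body <- trunc_exp_pmf(sv_model$exp_b, 1L, bp - 1L)
  tail_w <- (seq(bp, J) + sv_model$gdp_b)^(-(sv_model$gdp_k + 1))
  c(sv_model$s * body, (1 - sv_model$s) * tail_w / sum(tail_w))
}

#' Sample splice-variant counts from the mixture model
#'
#' @param n number of draws.
#' @inheritParams sv_mixture_pmf
#' @param seed optional RNG seed.
#' @return Integer vector in `1..J`.
#' @export
sample_sv_mixture <- function(n, sv_model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample_pmf(n, sv_mixture_pmf(sv_model), seq_len(sv_model$J))
}

# distinct keyword subsets of the vocabulary, one per FL pool entry
make_keyword_pool <- function(n_fl, vocab, mean_kw) {
  sizes <- pmin(1L + rpois(n_fl, max(0, mean_kw - 1)), length(vocab))
  sets <- lapply(sizes, function(s) sort(sample(vocab, s)))
  keys <- vapply(sets, paste, "", collapse = .KEY_SEP)
  for (tries in 1:50) {
    dup <- which(duplicated(keys))
    if (!length(dup)) break
    for (i in dup) {
      s <- min(sizes[i] + 1L, length(vocab))
      sets[[i]] <- sort(sample(vocab, s))
      keys[i] <- paste(sets[[i]], collapse = .KEY_SEP)
    }
  }
  if (anyDuplicated(keys))
    stop("could not realize distinct keyword sets; enlarge the vocabulary")
  sets
}

# assign SV counts (pool) to TUs so that each TU gets sv >= its FL demand,
# preserving the pool's marginal distribution exactly; TUs whose demand
# cannot be met are demoted to the next lower demand
allocate_sv <- function(fl_counts, sv_pool) {
  n <- length(fl_counts)
  stopifnot(length(sv_pool) == n)
  Jmax <- max(sv_pool)
  avail <- tabulate(sv_pool, nbins = Jmax)
  assigned <- integer(n)
  fl_out <- fl_counts
  for (f in sort(unique(fl_counts), decreasing = TRUE)) {
    idx <- which(fl_out == f)
    if (!length(idx)) next
    elig_vals <- seq(f, Jmax)
    n_elig <- sum(avail[elig_vals])
    if (n_elig < length(idx) && f > 1L) {
      # demote the shortfall to demand f-1 (re-processed next round)
      short <- length(idx) - n_elig
      demote <- idx[seq_len(short)]
      fl_out[demote] <- f - 1L
      idx <- setdiff(idx, demote)
    }
    if (!length(idx)) next
    pool_vals <- rep(elig_vals, avail[elig_vals])
    take <- if (length(pool_vals) == 1L) pool_vals
            else sample(pool_vals, length(idx))
    assigned[idx] <- take
    dec <- tabulate(take, nbins = Jmax)
    avail <- avail - dec
  }
  list(sv = assigned, fl = pmin(fl_out, assigned))
}

#' Generate a synthetic organism dataset
#'
#' Draws, per TU, a splice-variant count from the body+tail mixture and a
#' distinct-FL count from a truncated discretized exponential (capped), and
#' materializes keyword sets so the dataset flows through the standard
#' ingestion and labeling path. FL identities are sampled from a pool with
#' Zipf-like popularity weights, producing the heavy-tailed TUs-per-FL
#' relation. The configured fraction of TUs is left unannotated. SV counts
#' are assigned to TUs so that every TU has at least as many isoforms as
#' distinct FLs while preserving the drawn SV marginal exactly.
#'
#' @param config a `sim_config`.
#' @return An `organism_dataset` with catalogue built (scope =
#'   `config$organism`); byte-identical across runs at a fixed seed.
#' @export
generate_organism <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_tus
  tu_ids <- sprintf("TU%06d", seq_len(n))
  n_un <- round(config$unannotated_fraction * n)
  is_un <- seq_len(n) <= n_un  # ids are arbitrary; no need to shuffle
  ann_idx <- which(!is_un)
  n_ann <- length(ann_idx)
  if (n_ann == 0L) stop("config leaves no annotated TUs")

  sv_all <- sample_sv_mixture(n, config$sv_model)

  # FL demand per annotated TU: monoform 1, polyform from truncated exp 2..cap
  is_poly <- rbinom(n_ann, 1L, config$polyform_target) == 1L
  fl_counts <- rep(1L, n_ann)
  if (any(is_poly)) {
    pmf <- trunc_exp_pmf(config$fl_per_tu_exp_b, 2L, config$fl_cap)
    fl_counts[is_poly] <- sample_pmf(sum(is_poly), pmf,
                                     seq(2L, config$fl_cap))
  }
  alloc <- allocate_sv(fl_counts, sv_all[ann_idx])
  sv <- integer(n)
  sv[ann_idx] <- alloc$sv
  sv[is_un] <- sv_all[is_un]
  fl_n <- alloc$fl

  # FL pool with Zipf popularity weights -> heavy-tailed TUs-per-FL
  n_pool <- max(50L, round(n / 4))
  w <- 1 / seq_len(n_pool)
  vocab <- sprintf("KW%04d", seq_len(config$keyword_vocab_size))
  kw_pool <- make_keyword_pool(n_pool, vocab,
                               config$mean_keywords_per_fl)

  fl_sets <- vector("list", n_ann)
  mono <- fl_n == 1L
  if (any(mono))
    fl_sets[mono] <- as.list(sample(n_pool, sum(mono), replace = TRUE,
                                    prob = w))
  for (i in which(!mono))
    fl_sets[[i]] <- sample(n_pool, fl_n[i], prob = w)

  # per-protein FL assignment: each of the TU's FLs at least once
  fl_assign <- vector("list", n)
  for (j in seq_len(n_ann)) {
    i <- ann_idx[j]
    fls <- fl_sets[[j]]
    extra <- sv[i] - length(fls)
    fl_assign[[i]] <- c(fls, if (extra > 0)
      fls[sample.int(length(fls), extra, replace = TRUE)])
  }
  fl_assign[is_un] <- lapply(sv[is_un], function(s) rep(NA_integer_, s))

  flat <- unlist(fl_assign)
  tu_rep <- rep(tu_ids, sv)
  pid <- paste0(tu_rep, "_sv", sequence(sv))
  keywords <- vector("list", length(flat))
  has_fl <- !is.na(flat)
  keywords[has_fl] <- kw_pool[flat[has_fl]]
  keywords[!has_fl] <- list(character(0))

  ds <- organism_dataset(pid, tu_rep, keywords, config$organism)
  build_catalogue(ds, scope = config$organism)
}

#' Exact fixture dataset from class counts
#'
#' Builds a minimal dataset whose monoform/polyform/unannotated TU counts
#' equal the given values exactly; `n_switch` of the polyform TUs carry a
#' disjoint (Jaccard index 0) isoform pair, the remaining polyform TUs
#' carry overlapping keyword sets.
#'
#' @param n_mono,n_poly,n_unannotated,n_switch TU counts
#'   (`n_switch <= n_poly`).
#' @param organism organism name.
#' @return An `organism_dataset` with catalogue built.
#' @export
fixture_dataset <- function(n_mono, n_poly, n_unannotated = 0,
                            n_switch = 0, organism = "fixture") {
  stopifnot(n_mono >= 0, n_poly >= 0, n_unannotated >= 0,
            n_switch >= 0, n_switch <= n_poly)
  pid <- character(0); tid <- character(0); kw <- list()
  if (n_mono > 0) {
    ids <- sprintf("TUmono%06d", seq_len(n_mono))
    pid <- c(pid, paste0(ids, "_sv1"))
    tid <- c(tid, ids)
    kw <- c(kw, rep(list("KWmono"), n_mono))
  }
  if (n_poly > 0) {
    ids <- sprintf("TUpoly%06d", seq_len(n_poly))
    sw <- seq_len(n_poly) <= n_switch
    pid <- c(pid, paste0(rep(ids, each = 2L), c("_sv1", "_sv2")))
    tid <- c(tid, rep(ids, each = 2L))
    sets <- lapply(sw, function(is_sw) {
      if (is_sw) list("KWswA", "KWswB")
      else list(c("KWa", "KWshared"), c("KWb", "KWshared"))
    })
    kw <- c(kw, unlist(sets, recursive = FALSE))
  }
  if (n_unannotated > 0) {
    ids <- sprintf("TUuna%06d", seq_len(n_unannotated))
    pid <- c(pid, paste0(ids, "_sv1"))
    tid <- c(tid, ids)
    kw <- c(kw, rep(list(character(0)), n_unannotated))
  }
  ds <- build_catalogue(organism_dataset(pid, tid, kw, organism),
                        scope = "x")
  s <- tu_summary(ds)
  stopifnot(s$n_mono == n_mono, s$n_poly == n_poly,
            s$n_unannotated == n_unannotated)
  ds
}

#' Exact fixture histogram from marginal totals
#'
#' Builds a frequency distribution with exactly the given number of
#' objects, events, singletons and maximum abundance: `n1` objects at
#' `m = 1`, one object at `m = J`, and the remaining objects spread over
#' two adjacent interior abundances chosen so the event total matches
#' exactly.
#'
#' @param total_events sum of `m * frequency`.
#' @param total_objects number of objects `M`.
#' @param n1 number of singletons.
#' @param J maximum abundance.
#' @return A `freq_dist` whose [describe_relation()] row reproduces the
#'   specified marginals exactly.
#' @export
fixture_histogram <- function(total_events, total_objects, n1, J) {
  stopifnot(n1 >= 0, n1 <= total_objects, J >= 1)
  counts <- integer(0); ms <- integer(0)
  add <- function(m, k) {
    if (k <= 0) return()
    i <- match(m, ms)
    if (is.na(i)) { ms <<- c(ms, m); counts <<- c(counts, k) }
    else counts[i] <<- counts[i] + k
  }
  add(1L, n1)
  rest_obj <- total_objects - n1
  rest_ev <- total_events - n1
  if (J == 1L) {
    if (rest_obj != 0 || rest_ev != 0)
      stop("inconsistent fixture spec: J = 1 forces all singletons")
  } else {
    if (rest_obj < 1L) stop("inconsistent fixture spec: no object left for m = J")
    add(J, 1L)
    r <- rest_obj - 1L
    e <- rest_ev - J
    if (r == 0L) {
      if (e != 0) stop("inconsistent fixture spec: leftover events")
    } else {
      if (e < 2 * r || e > as.numeric(J) * r)
        stop("inconsistent fixture spec: interior events out of range")
      q <- e %/% r; rem <- e %% r
      if (q + (rem > 0) > J) stop("inconsistent fixture spec")
      add(as.integer(q), as.integer(r - rem))
      if (rem > 0) add(as.integer(q + 1L), as.integer(rem))
    }
  }
  fd <- freq_dist_from_counts(ms, counts)
  stopifnot(fd$M == total_objects, fd$total_events == total_events,
            fd$J == J, freq_at(fd, 1L) == n1)
  fd
}

#' Exact fixture from printed marginal counts
#'
#' Dispatches on the fields of `spec`: a spec with `n_mono`/`n_poly`
#' builds a minimal [fixture_dataset()]; a spec with
#' `total_events`/`total_objects`/`n1`/`J` builds a
#' [fixture_histogram()]. Inconsistent specs error.
#'
#' @param spec named list of counts.
#' @return An `organism_dataset` or a `freq_dist`.
#' @export
fixture_from_counts <- function(spec) {
  if (!is.null(spec$n_mono) || !is.null(spec$n_poly)) {
    return(fixture_dataset(
      n_mono = spec$n_mono %||% 0, n_poly = spec$n_poly %||% 0,
      n_unannotated = spec$n_unannotated %||% 0,
      n_switch = spec$n_switch %||% 0,
      organism = spec$organism %||% "fixture"))
  }
  if (!is.null(spec$total_objects)) {
    return(fixture_histogram(
      total_events = spec$total_events, total_objects = spec$total_objects,
      n1 = spec$n1, J = spec$J))
  }
  stop("unrecognized fixture spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
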