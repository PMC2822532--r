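# Frequency distributions of the three transcript-protein-function
# relations and their parameterization: exponential body, (generalized)
# discrete Pareto tail, and the two-regime mixture.

#' Build a frequency distribution from occurrence counts
#'
#' Histogram of "how many objects occur m times": `counts[m]` is the number
#' of objects with occurrence count `m`.
#'
#' @param values vector of positive integer occurrence counts, one per
#'   object; must be nonempty.
#' @return A `freq_dist`: list with `m` (sorted occurrence counts having
#'   nonzero frequency), `freq` (their frequencies), `M` (total objects),
#'   `total_events` (`sum(m * freq)`) and `J` (maximum observed `m`).
#' @export
freq_distribution <- function(values) {
  if (length(values) == 0L) stop("empty input: no occurrence counts")
  if (any(values < 1) || any(values != round(values)))
    stop("occurrence counts must be positive integers")
  tb <- table(values)
  freq_dist_from_counts(as.integer(names(tb)), as.integer(tb))
}

#' Assemble a frequency distribution from (m, frequency) pairs
#'
#' @param m positive integer occurrence counts (distinct).
#' @param freq non-negative frequencies, same length as `m`; non-integer
#'   frequencies are accepted (useful for noiseless model curves).
#' @return A `freq_dist`; see [freq_distribution()].
#' @export
freq_dist_from_counts <- function(m, freq) {
  stopifnot(length(m) == length(freq), !anyDuplicated(m),
            all(m >= 1), all(m == round(m)), all(freq >= 0))
  keep <- freq > 0
  m <- as.integer(m[keep]); freq <- as.numeric(freq[keep])
  if (!length(m)) stop("distribution has no mass")
  ord <- order(m)
  m <- m[ord]; freq <- freq[ord]
  structure(list(m = m, freq = freq, M = sum(freq),
                 total_events = sum(as.numeric(m) * freq), J = max(m)),
            class = "freq_dist")
}

#' @export
print.freq_dist <- function(x, ...) {
  cat("freq_dist: M =", x$M, " events =", x$total_events, " J =", x$J, "\n")
  invisible(x)
}

freq_at <- function(freq, mm) {
  i <- match(mm, freq$m)
  ifelse(is.na(i), 0L, freq$freq[i])
}

tu_fl_counts <- function(dataset) {
  stopifnot(inherits(dataset, "organism_dataset"))
  if (is.null(dataset$catalogue)) stop("catalogue not built")
  tus <- dataset$tus
  ann <- tus$class != "unannotated"
  if (!any(ann)) stop("no annotated TUs")
  list(tus = tus[ann, , drop = FALSE])
}

#' Relation histograms of an organism dataset
#'
#' The three transcript-protein-function relations, over annotated TUs
#' only:
#' \describe{
#'   \item{`fls_per_tu`}{number of distinct FLs carried by each TU;}
#'   \item{`tus_per_fl`}{number of distinct TUs attributed with each FL
#'     (restricted to FLs of annotated TUs);}
#'   \item{`svs_per_tu`}{number of splice-variant proteins per TU.}
#' }
#' By double counting, `fls_per_tu` and `tus_per_fl` have equal
#' `total_events`.
#'
#' @param dataset an `organism_dataset` with catalogue built.
#' @return A `freq_dist`.
#' @export
fls_per_tu <- function(dataset) {
  a <- tu_fl_counts(dataset)
  freq_distribution(lengths(a$tus$fls))
}

#' @rdname fls_per_tu
#' @export
tus_per_fl <- function(dataset) {
  a <- tu_fl_counts(dataset)
  fl <- unlist(a$tus$fls)
  if (!length(fl)) stop("no FL attributions")
  freq_distribution(as.integer(table(fl)))
}

#' @rdname fls_per_tu
#' @export
svs_per_tu <- function(dataset) {
  a <- tu_fl_counts(dataset)
  freq_distribution(a$tus$n_proteins)
}

# Hurwitz-style tail sum: sum_{m=1}^Inf (m + b)^(-s) via Euler-Maclaurin
gdp_infinite_sum <- function(s, b, n_head = 10000L) {
  head <- sum((seq_len(n_head) + b)^(-s))
  a <- n_head + 1 + b
  tail <- a^(1 - s) / (s - 1) + 0.5 * a^(-s) + s * a^(-s - 1) / 12 -
    s * (s + 1) * (s + 2) * a^(-s - 3) / 720
  head + tail
}

#' Generalized discrete Pareto normalization constant
#'
#' `C` such that `sum_{m=1..J} C * (m + b)^-(k+1) = 1`. With `J = Inf` the
#' sum is evaluated by Euler-Maclaurin summation (a Hurwitz-zeta value); at
#' `b = 0` it reduces to the Riemann zeta value `1/zeta(k+1)`.
#'
#' @param k shape parameter, `> 0`; the log-log slope of the pmf is `k+1`.
#' @param b shift parameter, `> -1`; `b = 0` gives the standard discrete
#'   Pareto (pure power law).
#' @param J truncation point (maximum abundance), a positive integer or
#'   `Inf`.
#' @return The normalization constant `C`.
#' @export
gdp_norm_const <- function(k, b, J) {
  if (k <= 0) stop("k must be > 0")
  if (b <= -1) stop("b must be > -1")
  s <- k + 1
  if (is.infinite(J)) return(1 / gdp_infinite_sum(s, b))
  if (J < 1 || J != round(J)) stop("J must be a positive integer or Inf")
  1 / sum((seq_len(J) + b)^(-s))
}

#' Generalized discrete Pareto probability mass function
#'
#' `f(m) = C / (m + b)^(k+1)` on `m = 1, ..., J`: the probability that a
#' randomly chosen object occurs `m` times in the sample. `b = 0` gives the
#' standard discrete Pareto; slope `k + 1 ~ 2` is the Zipf-Lotka regime.
#'
#' @param m vector of integers in `1..J`.
#' @inheritParams gdp_norm_const
#' @return Probabilities `f(m)`, summing to 1 over the full support.
#' @examples
#' gdp_pmf(1:2, k = 1, b = 0, J = 2)   # 0.8, 0.2
#' @export
gdp_pmf <- function(m, k, b, J) {
  C <- gdp_norm_const(k, b, J)
  if (any(m < 1 | m > J | m != round(m)))
    stop("m must be integers in 1..J")
  C * (m + b)^(-(k + 1))
}

range_support <- function(freq, m_range) {
  if (is.null(m_range)) m_range <- c(1L, freq$J)
  lo <- max(1L, as.integer(m_range[1L]))
  hi <- as.integer(m_range[2L])
  if (hi < lo) stop("degenerate m range")
  keep <- freq$m >= lo & freq$m <= hi
  list(lo = lo, hi = hi, m = freq$m[keep], freq = freq$freq[keep])
}

#' Fit an exponential frequency law
#'
#' Default (`method = "ls"`): unweighted nonlinear least squares of
#' `frequency ~ a * exp(-b * m)` over the observed (nonzero-frequency)
#' points in `m_range`, emulating a curve-fitting workflow on plotted
#' histogram points; standard errors and parameter p-values come from the
#' NLS covariance. `method = "mle"`: multinomial maximum likelihood of the
#' discretized exponential normalized over the regime, with Wald standard
#' errors from the observed information — the appropriate estimator for
#' parameter-recovery studies on sampled counts. `rmse` is the residual
#' standard error of the fitted counts in both modes.
#'
#' @param freq a `freq_dist`.
#' @param m_range integer vector `c(lo, hi)` delimiting the fitted regime;
#'   default the full support.
#' @param method `"ls"` (least squares on frequencies, default) or
#'   `"mle"` (multinomial maximum likelihood).
#' @return An `exp_fit`: list with `a`, `b`, `se_a`, `se_b`, `p_a`, `p_b`,
#'   `rmse`, `m_range`, `n_points`, `method`.
#' @export
fit_exponential <- function(freq, m_range = NULL,
                            method = c("ls", "mle")) {
  method <- match.arg(method)
  rs <- range_support(freq, m_range)
  if (length(rs$m) < 3L)
    stop("need at least 3 support points to fit the exponential")
  df <- data.frame(m = rs$m, y = rs$freq)
  Mr <- sum(rs$freq)
  grid <- seq(rs$lo, rs$hi)
  if (method == "mle") {
    nll <- function(b)
      -sum(df$y * (-b * df$m - log(sum(exp(-b * grid)))))
    opt <- stats::optim(0.5, nll, method = "Brent", lower = 1e-9,
                        upper = 50, hessian = TRUE)
    b <- opt$par
    if (b < 1e-6) stop("degenerate fit: rate parameter at zero boundary")
    se_b <- sqrt(1 / opt$hessian[1L, 1L])
    a <- Mr / sum(exp(-b * grid))
    fitted <- a * exp(-b * df$m)
    rmse <- sqrt(sum((df$y - fitted)^2) / max(1L, length(rs$m) - 1L))
    out <- list(a = a, b = b, se_a = NA_real_, se_b = se_b,
                p_a = NA_real_,
                p_b = 2 * stats::pnorm(-abs(b / se_b)), rmse = rmse)
  } else {
    lmfit <- stats::lm(log(pmax(y, 0.5)) ~ m, data = df)
    b0 <- max(1e-3, -coef(lmfit)[[2L]])
    a0 <- exp(coef(lmfit)[[1L]])
    fit <- minpack.lm::nlsLM(y ~ a * exp(-b * m), data = df,
                             start = list(a = a0, b = b0),
                             lower = c(a = 1e-12, b = 1e-9),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- summary(fit)$coefficients
    if (cf["b", "Estimate"] < 1e-6)
      stop("degenerate fit: rate parameter at zero boundary")
    out <- list(a = cf["a", "Estimate"], b = cf["b", "Estimate"],
                se_a = cf["a", "Std. Error"], se_b = cf["b", "Std. Error"],
                p_a = cf["a", "Pr(>|t|)"], p_b = cf["b", "Pr(>|t|)"],
                rmse = summary(fit)$sigma)
  }
  structure(c(out, list(m_range = c(rs$lo, rs$hi),
                        n_points = length(rs$m), method = method)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("exponential fit: a = %.4g +/- %.3g, b = %.4g +/- %.3g (rmse %.4g)\n",
              x$a, x$se_a, x$b, x$se_b, x$rmse))
  invisible(x)
}

#' Fit a generalized discrete Pareto law
#'
#' Unweighted nonlinear least squares of the observed frequencies against
#' `M_r * f_r(m)`, where `f_r` is the GDP pmf renormalized over the fitted
#' regime and `M_r` the number of objects observed there, so the model mass
#' matches the data mass by construction and only the shape parameters
#' `(k, b)` are estimated. `fix_b_zero = TRUE` fits the standard discrete
#' Pareto (pure power law, `b = 0`).
#'
#' @inheritParams fit_exponential
#' @param fix_b_zero logical; constrain `b = 0`.
#' @param J truncation used for the reported normalization constant;
#'   default the distribution's maximum observed `m`.
#' @return A `gdp_fit`: list with `k`, `b`, `J`, `C` (normalization over
#'   `1..J`), standard errors, p-values, `rmse`, `m_range`, `n_points`,
#'   `method`.
#' @export
fit_gdp <- function(freq, m_range = NULL, fix_b_zero = FALSE, J = NULL,
                    method = c("ls", "mle")) {
  method <- match.arg(method)
  rs <- range_support(freq, m_range)
  need <- if (fix_b_zero) 2L else 3L
  if (length(rs$m) < need)
    stop("need at least ", need, " support points to fit the GDP")
  if (is.null(J)) J <- freq$J
  df <- data.frame(m = rs$m, y = rs$freq)
  Mr <- sum(rs$freq)
  grid <- seq(rs$lo, rs$hi)
  # log-log trend slope as starting point for k
  llfit <- stats::lm(log(pmax(y, 0.5)) ~ log(m), data = df)
  k0 <- max(0.1, -coef(llfit)[[2L]] - 1)
  if (method == "mle") {
    nll <- function(par) {
      k <- par[1L]; b <- if (fix_b_zero) 0 else par[2L]
      lw <- -(k + 1) * log(grid + b)
      -sum(df$y * (-(k + 1) * log(df$m + b) - log(sum(exp(lw)))))
    }
    par0 <- if (fix_b_zero) k0 else c(k0, 0)
    lower <- if (fix_b_zero) 1e-8 else c(1e-8, -1 + 1e-6)
    opt <- stats::optim(par0, nll, method = "L-BFGS-B", lower = lower,
                        hessian = TRUE)
    if (opt$convergence != 0)
      stop("GDP fit did not converge: code ", opt$convergence,
           " (", opt$message, ")")
    k <- opt$par[1L]
    b <- if (fix_b_zero) 0 else opt$par[2L]
    cov <- tryCatch(solve(opt$hessian), error = function(e)
      matrix(NA_real_, length(opt$par), length(opt$par)))
    se <- sqrt(pmax(diag(cov), 0))
    se_k <- se[1L]
    se_b <- if (fix_b_zero) NA_real_ else se[2L]
    wald <- function(est, s) 2 * stats::pnorm(-abs(est / s))
    wgt <- (df$m + b)^(-(k + 1))
    fitted <- Mr * wgt / sum((grid + b)^(-(k + 1)))
    rmse <- sqrt(sum((df$y - fitted)^2) /
                   max(1L, length(rs$m) - length(opt$par)))
    out <- list(k = k, b = b, se_k = se_k, se_b = se_b,
                p_k = wald(k, se_k),
                p_b = if (fix_b_zero) NA_real_ else wald(b, se_b),
                rmse = rmse)
  } else {
    model_counts <- function(k, b) {
      w <- (grid + b)^(-(k + 1))
      (Mr / sum(w)) * (df$m + b)^(-(k + 1))
    }
    if (fix_b_zero) {
      fit <- minpack.lm::nlsLM(y ~ model_counts(k, 0), data = df,
                               start = list(k = k0), lower = c(k = 1e-8),
                               control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      fit <- minpack.lm::nlsLM(y ~ model_counts(k, b), data = df,
                               start = list(k = k0, b = 0),
                               lower = c(k = 1e-8, b = -1 + 1e-8),
                               control = minpack.lm::nls.lm.control(maxiter = 500))
    }
    if (!fit$convInfo$isConv && fit$convInfo$stopCode %in% c(5L, 6L))
      stop("GDP fit did not converge: ", fit$convInfo$stopMessage,
           " after ", fit$convInfo$finIter, " iterations")
    cf <- summary(fit)$coefficients
    k <- cf["k", "Estimate"]
    b <- if (fix_b_zero) 0 else cf["b", "Estimate"]
    out <- list(
      k = k, b = b,
      se_k = cf["k", "Std. Error"],
      se_b = if (fix_b_zero) NA_real_ else cf["b", "Std. Error"],
      p_k = cf["k", "Pr(>|t|)"],
      p_b = if (fix_b_zero) NA_real_ else cf["b", "Pr(>|t|)"],
      rmse = summary(fit)$sigma)
  }
  structure(c(list(k = out$k, b = out$b, J = J,
                   C = gdp_norm_const(out$k, out$b, J)),
              out[c("se_k", "se_b", "p_k", "p_b", "rmse")],
              list(fix_b_zero = fix_b_zero, m_range = c(rs$lo, rs$hi),
                   n_points = length(rs$m), method = method)),
            class = "gdp_fit")
}

#' @export
print.gdp_fit <- function(x, ...) {
  cat(sprintf("GDP fit: k = %.4g +/- %.3g (slope %.3g), b = %.4g%s, J = %s (rmse %.4g)\n",
              x$k, x$se_k, x$k + 1, x$b,
              if (x$fix_b_zero) " [fixed]"
              else sprintf(" +/- %.3g", x$se_b),
              format(x$J), x$rmse))
  invisible(x)
}

#' Fit the two-component mixture frequency model
#'
#' Mixture `P(X = m) = s * P1(m) + (1 - s) * P2(m)`: a low-complexity body
#' below the breakpoint and a heavy high-complexity tail at and above it.
#' The two regimes are fitted separately (the procedure visible in split
#' body/tail histogram fits): component 1 on `m < breakpoint`, component 2
#' on `m >= breakpoint`, and `s` is the fraction of objects observed in the
#' body regime. Both components are renormalized over their regimes so the
#' mixture pmf sums to 1 over `1..J` (see [mixture_pmf()]).
#'
#' When the tail regime has fewer than 2 support points the tail component
#' is reported as `NULL` (printed `NAN`) and `s` is the body mass, the
#' behavior expected of a wholly exponential distribution. A tail with
#' exactly 2 support points falls back to the standard Pareto (`b = 0`).
#'
#' @param freq a `freq_dist`.
#' @param breakpoint first `m` of the tail regime, in `[2, J]`; default 10
#'   (tail at 10 or more occurrences).
#' @param comp1_kind `"exponential"` (default) or `"gdp"`.
#' @param comp2_kind `"gdp"` (the only supported tail family).
#' @param method fitting objective passed to the component fits; see
#'   [fit_exponential()].
#' @return A `mixture_fit`: list with `s`, `comp1`, `comp2` (possibly
#'   `NULL`), `breakpoint`, `J`, `M`.
#' @export
fit_mixture <- function(freq, breakpoint = 10,
                        comp1_kind = c("exponential", "gdp"),
                        comp2_kind = "gdp", method = c("ls", "mle")) {
  comp1_kind <- match.arg(comp1_kind)
  method <- match.arg(method)
  stopifnot(comp2_kind == "gdp")
  breakpoint <- as.integer(breakpoint)
  if (breakpoint < 2L || breakpoint > freq$J)
    stop("breakpoint must lie in [2, J]")
  body_rng <- c(1L, breakpoint - 1L)
  tail_rng <- c(breakpoint, freq$J)
  n_body <- sum(freq$m < breakpoint & freq$freq > 0)
  n_tail <- sum(freq$m >= breakpoint & freq$freq > 0)
  if (n_body < 2L)
    stop("body regime has fewer than 2 support points")
  comp1 <- if (comp1_kind == "exponential")
    fit_exponential(freq, body_rng, method = method)
  else fit_gdp(freq, body_rng, method = method)
  comp2 <- if (n_tail >= 3L) fit_gdp(freq, tail_rng, method = method)
           else if (n_tail == 2L)
             fit_gdp(freq, tail_rng, fix_b_zero = TRUE, method = method)
           else NULL
  s <- sum(freq$freq[freq$m < breakpoint]) / freq$M
  structure(list(s = s, comp1 = comp1, comp2 = comp2,
                 breakpoint = breakpoint, J = freq$J, M = freq$M),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture fit: s = %.4f, breakpoint m* = %d, J = %d\n",
              x$s, x$breakpoint, x$J))
  cat("  body:  "); print(x$comp1)
  if (is.null(x$comp2)) cat("  tail:  NAN (fewer than 2 support points)\n")
  else { cat("  tail:  "); print(x$comp2) }
  invisible(x)
}

#' Mixture probability mass function
#'
#' Evaluates the fitted mixture of [fit_mixture()]: the body component
#' normalized over `1..breakpoint-1` scaled by `s`, the tail component
#' normalized over `breakpoint..J` scaled by `1 - s`; sums to 1 over
#' `1..J`. With a `NULL` tail component the body component is normalized
#' over the full `1..J`.
#'
#' @param fit a `mixture_fit`.
#' @param m integers in `1..J`; default the full support.
#' @return Probabilities `P(X = m)`.
#' @export
mixture_pmf <- function(fit, m = NULL) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (is.null(m)) m <- seq_len(fit$J)
  if (any(m < 1 | m > fit$J | m != round(m)))
    stop("m must be integers in 1..J")
  comp_weights <- function(comp, grid) {
    if (inherits(comp, "exp_fit")) exp(-comp$b * grid)
    else (grid + comp$b)^(-(comp$k + 1))
  }
  bp <- fit$breakpoint
  if (is.null(fit$comp2)) {
    grid <- seq_len(fit$J)
    w <- comp_weights(fit$comp1, grid)
    return((w / sum(w))[m])
  }
  body_grid <- seq_len(bp - 1L)
  tail_grid <- seq(bp, fit$J)
  wb <- comp_weights(fit$comp1, body_grid); wb <- wb / sum(wb)
  wt <- comp_weights(fit$comp2, tail_grid); wt <- wt / sum(wt)
  out <- numeric(length(m))
  is_body <- m < bp
  out[is_body] <- fit$s * wb[m[is_body]]
  out[!is_body] <- (1 - fit$s) * wt[m[!is_body] - bp + 1L]
  out
}

#' Descriptive statistics of a relation histogram
#'
#' The per-relation summary row: totals, events-per-object ratio, maximum
#' abundance, singleton count `n1` (objects occurring exactly once) with
#' its percentage `p1`, and the adjusted Fisher-Pearson sample skewness of
#' the object-level occurrence counts (0 by convention for constant data).
#'
#' @param freq a `freq_dist`.
#' @return A `descriptive_row`: one-row data frame with columns
#'   `total_events`, `total_objects`, `ratio`, `max_m`, `n1`, `p1`,
#'   `skewness`.
#' @export
describe_relation <- function(freq) {
  stopifnot(inherits(freq, "freq_dist"))
  n1 <- freq_at(freq, 1L)
  values <- rep(freq$m, freq$freq)
  skew <- if (length(values) >= 3L && var(values) > 0)
    e1071::skewness(values, type = 2) else 0
  out <- data.frame(total_events = freq$total_events,
                    total_objects = freq$M,
                    ratio = freq$total_events / freq$M,
                    max_m = freq$J,
                    n1 = n1, p1 = 100 * n1 / freq$M,
                    skewness = skew)
  class(out) <- c("descriptive_row", "data.frame")
  out
}

#' Write a histogram as TSV (columns m, frequency)
#'
#' @param freq a `freq_dist`.
#' @param path output path.
#' @export
write_histogram <- function(freq, path) {
  write.table(data.frame(m = freq$m, frequency = freq$freq), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabulate a mixture fit as a parameter report
#'
#' One row per parameter (component, parameter, estimate, SE, p-value,
#' rmse), mirroring a published best-fit parameter table; `NA` entries mark
#' an absent tail component.
#'
#' @param fit a `mixture_fit`.
#' @return Data frame ready for TSV export.
#' @export
mixture_report <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  c1 <- fit$comp1
  rows <- list(
    data.frame(component = "P1", parameter = "s", estimate = fit$s,
               se = NA_real_, p_value = NA_real_, rmse = NA_real_))
  if (inherits(c1, "exp_fit")) {
    rows <- c(rows, list(
      data.frame(component = "P1", parameter = "a", estimate = c1$a,
                 se = c1$se_a, p_value = c1$p_a, rmse = c1$rmse),
      data.frame(component = "P1", parameter = "b", estimate = c1$b,
                 se = c1$se_b, p_value = c1$p_b, rmse = c1$rmse)))
  } else {
    rows <- c(rows, list(
      data.frame(component = "P1", parameter = "k", estimate = c1$k,
                 se = c1$se_k, p_value = c1$p_k, rmse = c1$rmse),
      data.frame(component = "P1", parameter = "b", estimate = c1$b,
                 se = c1$se_b, p_value = c1$p_b, rmse = c1$rmse)))
  }
  c2 <- fit$comp2
  if (is.null(c2)) {
    rows <- c(rows, list(
      data.frame(component = "P2", parameter = c("k", "b"),
                 estimate = NA_real_, se = NA_real_, p_value = NA_real_,
                 rmse = NA_real_)))
  } else {
    rows <- c(rows, list(
      data.frame(component = "P2", parameter = "k", estimate = c2$k,
                 se = c2$se_k, p_value = c2$p_k, rmse = c2$rmse),
      data.frame(component = "P2", parameter = "b", estimate = c2$b,
                 se = c2$se_b, p_value = c2$p_b, rmse = c2$rmse)))
  }
  do.call(rbind, rows)
}
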