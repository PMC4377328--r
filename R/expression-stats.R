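#' Quantile-normalize a log2 expression matrix
#'
#' Forces every column (sample) to share the same distribution: the sorted
#' values of each column are replaced by the row-wise means of the
#' column-sorted input, ties averaged, within-column rank order preserved.
#' Delegates to [limma::normalizeQuantiles()].
#'
#' @param mat numeric genes-by-samples matrix of log2 intensities.
#' @return A matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 1L) stop("at least one column required")
  if (!all(is.finite(mat))) stop("non-finite values in input matrix")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

# run expr under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit a two-component Gaussian mixture to pooled log2 intensities
#'
#' Models the pooled intensity distribution of one dataset as a mixture of
#' a low (non-expressed) and a high (expressed) Gaussian component, fitted
#' by expectation-maximization with random restarts. The expressed-gene
#' threshold is the intensity between the two component means at which the
#' two weighted component densities are equal.
#'
#' @param x numeric vector of log2 intensities (>= 50 values, positive
#'   variance).
#' @param seed integer seed controlling EM restarts.
#' @param restarts number of EM initializations; the best log-likelihood
#'   wins.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations per restart.
#' @return An object of class `mixture_fit` with fields `weight_low`,
#'   `weight_high`, `mean_low`, `mean_high`, `sd_low`, `sd_high`,
#'   `threshold`, `loglik`.
#' @export
fit_expression_mixture <- function(x, seed = 1L, restarts = 5L,
                                   tol = 1e-8, max_iter = 1000L) {
  x <- as.numeric(x)
  if (length(x) < 50L) stop("at least 50 intensity values required")
  if (!all(is.finite(x))) stop("intensities must be finite")
  if (stats::var(x) <= 0) stop("intensities have zero variance")
  fits <- with_seed(seed, lapply(seq_len(restarts), function(r) {
    em_two_gaussian(x, init = r, tol = tol, max_iter = max_iter)
  }))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) stop("components not separable")
  best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  pooled_sd <- sqrt(best$w[1L] * best$s[1L]^2 + best$w[2L] * best$s[2L]^2)
  if (abs(best$m[2L] - best$m[1L]) < 0.1 * pooled_sd) {
    stop("components not separable")
  }
  thr <- mixture_crossing(best$w, best$m, best$s)
  structure(list(weight_low = best$w[1L], weight_high = best$w[2L],
                 mean_low = best$m[1L], mean_high = best$m[2L],
                 sd_low = best$s[1L], sd_high = best$s[2L],
                 threshold = thr, loglik = best$loglik),
            class = "mixture_fit")
}

# one EM run; components returned sorted by mean; NULL on degenerate collapse
em_two_gaussian <- function(x, init, tol, max_iter) {
  n <- length(x)
  if (init == 1L) {
    cut <- stats::median(x)
  } else {
    cut <- stats::quantile(x, stats::runif(1L, 0.2, 0.8))
  }
  lo <- x <= cut
  if (sum(lo) < 2L || sum(!lo) < 2L) lo <- x <= stats::median(x)
  m <- c(mean(x[lo]), mean(x[!lo]))
  s <- pmax(c(stats::sd(x[lo]), stats::sd(x[!lo])), 1e-3)
  w <- c(mean(lo), 1 - mean(lo))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1L] * stats::dnorm(x, m[1L], s[1L])
    d2 <- w[2L] * stats::dnorm(x, m[2L], s[2L])
    tot <- d1 + d2
    if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
    g <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
    n1 <- sum(g)
    if (n1 < 1e-8 || n - n1 < 1e-8) return(NULL)
    m <- c(sum(g * x) / n1, sum((1 - g) * x) / (n - n1))
    s <- sqrt(c(sum(g * (x - m[1L])^2) / n1,
                sum((1 - g) * (x - m[2L])^2) / (n - n1)))
    s <- pmax(s, 1e-6)
    w <- c(n1 / n, 1 - n1 / n)
  }
  o <- order(m)
  list(w = w[o], m = m[o], s = s[o], loglik = ll_old)
}

# crossing of the two weighted component densities strictly between the
# means; with unequal sds two roots can exist -- take the one nearest the
# midpoint of the means
mixture_crossing <- function(w, m, s) {
  f <- function(x) {
    log(w[1L]) + stats::dnorm(x, m[1L], s[1L], log = TRUE) -
      log(w[2L]) - stats::dnorm(x, m[2L], s[2L], log = TRUE)
  }
  eps <- 1e-6 * (m[2L] - m[1L])
  grid <- seq(m[1L] + eps, m[2L] - eps, length.out = 512L)
  fv <- f(grid)
  flips <- which(fv[-1L] * fv[-length(fv)] <= 0)
  if (length(flips) == 0L) stop("no density crossing between component means")
  roots <- vapply(flips, function(i) {
    stats::uniroot(f, c(grid[i], grid[i + 1L]), tol = 1e-10)$root
  }, numeric(1))
  mid <- mean(m)
  roots[which.min(abs(roots - mid))]
}

#' Select expressed genes by maximum intensity above the mixture threshold
#'
#' A gene is expressed when its maximum intensity across all samples of the
#' dataset is strictly higher than the mixture-fit threshold.
#'
#' @param dataset an [expression_dataset()].
#' @param fit a [fit_expression_mixture()] result for this dataset's pooled
#'   values.
#' @return Character vector of expressed gene identifiers.
#' @export
filter_expressed <- function(dataset, fit) {
  mx <- apply(dataset$values, 1L, max)
  keep <- dataset$genes[mx > fit$threshold]
  if (length(keep) == 0L) warning("no gene passes the expressed filter")
  keep
}

#' Two-sample pooled-variance Student t statistic
#'
#' Positive when the cancer mean exceeds the normal mean. A zero pooled
#' variance with a nonzero mean difference yields a signed infinity
#' sentinel, which downstream empirical P computation clamps.
#'
#' @param cancer,normal numeric vectors (>= 2 values each).
#' @return A single number.
#' @export
t_statistic <- function(cancer, normal) {
  if (length(cancer) < 2L || length(normal) < 2L) {
    stop("at least 2 samples per class required")
  }
  n1 <- length(cancer); n2 <- length(normal)
  sp2 <- ((n1 - 1L) * stats::var(cancer) + (n2 - 1L) * stats::var(normal)) /
    (n1 + n2 - 2L)
  d <- mean(cancer) - mean(normal)
  if (sp2 <= 0) return(sign(d) * Inf)
  d / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Log2-median-ratio between cancer and normal samples
#'
#' Values are already on the log2 scale, so the ratio of medians is the
#' difference of medians.
#'
#' @param cancer,normal nonempty numeric vectors of log2 intensities.
#' @return median(cancer) - median(normal), in log2 units.
#' @export
log2_median_ratio <- function(cancer, normal) {
  if (length(cancer) == 0L || length(normal) == 0L) {
    stop("both groups must be nonempty")
  }
  stats::median(cancer) - stats::median(normal)
}

# vectorized per-row pooled-variance t over a matrix; returns t and the
# cancer-minus-normal mean difference
row_t_stats <- function(values, is_cancer) {
  n1 <- sum(is_cancer); n2 <- sum(!is_cancer)
  x1 <- values[, is_cancer, drop = FALSE]
  x2 <- values[, !is_cancer, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  d <- m1 - m2
  t <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  t[sp2 <= 0] <- sign(d[sp2 <= 0]) * Inf
  list(t = t, diff = d)
}

row_lmr_stats <- function(values, is_cancer) {
  med1 <- apply(values[, is_cancer, drop = FALSE], 1L, stats::median)
  med2 <- apply(values[, !is_cancer, drop = FALSE], 1L, stats::median)
  med1 - med2
}

#' Permutation-based empirical null for a differential statistic
#'
#' Permutes the cancer/normal labels `n_perm` times, recomputes the chosen
#' statistic for every gene under each permutation, and pools the permuted
#' statistics across genes into one smoothed null per dataset and statistic.
#' Smoothing is a Gaussian kernel density (Silverman's rule-of-thumb
#' bandwidth) whose cumulative distribution is evaluated in closed form.
#'
#' @param dataset an [expression_dataset()].
#' @param statistic `"t"` (pooled-variance Student t) or `"lmr"`
#'   (log2-median-ratio).
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed for the permutations.
#' @param genes optional gene subset (typically the expressed genes);
#'   defaults to all genes.
#' @return An object of class `empirical_null` (see
#'   [empirical_null_density()]).
#' @export
empirical_null <- function(dataset, statistic = c("t", "lmr"),
                           n_perm = 1000L, seed = 1L, genes = NULL) {
  statistic <- match.arg(statistic)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  is_cancer <- dataset$labels == "cancer"
  n <- length(is_cancer)
  n_distinct <- choose(n, sum(is_cancer))
  if (n_distinct < n_perm) {
    stop(sprintf(paste0(
      "only %d distinct label assignments exist (< n_perm = %d); ",
      "use exact enumeration for such small cohorts"), n_distinct, n_perm))
  }
  values <- dataset$values
  if (!is.null(genes)) values <- values[genes, , drop = FALSE]
  pooled <- with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(i) {
      perm <- sample(is_cancer)
      if (statistic == "t") row_t_stats(values, perm)$t
      else row_lmr_stats(values, perm)
    }), use.names = FALSE)
  })
  pooled <- pooled[is.finite(pooled)]
  empirical_null_density(pooled, statistic = statistic, n_perm = n_perm)
}

#' Smoothed empirical null distribution from pooled statistic draws
#'
#' Wraps a vector of null draws as a Gaussian-KDE-smoothed distribution
#' with an exactly evaluable cumulative distribution function
#' F(x) = mean over draws v of Phi((x - v) / h), h by Silverman's rule.
#'
#' @param values numeric vector of null statistic draws (finite).
#' @param statistic label recorded on the object.
#' @param n_perm number of permutations that produced the draws.
#' @return An object of class `empirical_null` with fields `values`,
#'   `bw`, `statistic`, `n_perm` and functions `cdf`, `pdf`.
#' @export
empirical_null_density <- function(values, statistic = "t",
                                   n_perm = NA_integer_) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("too few finite null draws")
  h <- stats::bw.nrd0(values)
  obj <- list(values = values, bw = h, statistic = statistic,
              n_perm = n_perm)
  obj$cdf <- function(x) {
    vapply(x, function(xi) {
      if (!is.finite(xi)) return(if (xi > 0) 1 else 0)
      mean(stats::pnorm((xi - values) / h))
    }, numeric(1))
  }
  obj$pdf <- function(x) {
    vapply(x, function(xi) mean(stats::dnorm((xi - values) / h)) / h,
           numeric(1))
  }
  class(obj) <- "empirical_null"
  obj
}

#' @export
print.empirical_null <- function(x, ...) {
  cat(sprintf("<empirical_null for '%s': %d pooled draws, bandwidth %.4g>\n",
              x$statistic, length(x$values), x$bw))
  invisible(x)
}

#' Two-tailed empirical P value
#'
#' P = min(1, 2 min(F(stat), 1 - F(stat))) where F is the null cumulative
#' distribution; doubling the smaller tail keeps the test valid for
#' asymmetric nulls. Clamped to \[1e-15, 1\] so downstream Z conversion
#' never sees 0.
#'
#' @param stat numeric vector of observed statistics.
#' @param null an `empirical_null` object.
#' @return Numeric vector of P values in (0, 1].
#' @export
two_tailed_p <- function(stat, null) {
  F <- null$cdf(stat)
  p <- pmin(1, 2 * pmin(F, 1 - F))
  pmin(pmax(p, 1e-15), 1)
}

#' Combine two-tailed P values by the directional Stouffer method
#'
#' Each two-tailed P is converted to a signed one-sided Z,
#' z_i = sign_i * Phi^{-1}(1 - p_i / 2); the combined Z = sum(z) / sqrt(k)
#' is converted back to a two-tailed P = 2 (1 - Phi(|Z|)). Discordant
#' directions cancel.
#'
#' @param p_values numeric vector of P values in (0, 1].
#' @param signs vector of directions in \{-1, 0, 1\}, same length
#'   (0 contributes a zero Z).
#' @return The combined two-tailed P, clamped to \[1e-15, 1\], with the
#'   combined Z attached as attribute `"z"`.
#' @export
stouffer_combine <- function(p_values, signs = rep(1, length(p_values))) {
  if (length(p_values) == 0L) stop("no P values to combine")
  if (length(signs) != length(p_values)) {
    stop("signs must match p_values in length")
  }
  if (any(p_values <= 0 | p_values > 1)) stop("P values must lie in (0, 1]")
  if (!all(signs %in% c(-1, 0, 1))) stop("signs must be -1, 0 or 1")
  z <- signs * stats::qnorm(p_values / 2, lower.tail = FALSE)
  Z <- sum(z) / sqrt(length(z))
  p <- 2 * stats::pnorm(abs(Z), lower.tail = FALSE)
  structure(pmin(pmax(p, 1e-15), 1), z = Z)
}

#' Identify differentially expressed genes in one dataset
#'
#' The full per-dataset pipeline: (optional) quantile normalization,
#' two-Gaussian expressed-gene filter, Student t and log2-median-ratio
#' statistics, permutation empirical nulls (one pooled null per statistic),
#' two-tailed empirical P values, per-gene directional Stouffer combination
#' of the two P values, and the DEG call p_combined <= alpha.
#'
#' @param dataset an [expression_dataset()] with >= 2 samples per class.
#' @param alpha significance level for the DEG call (default 0.05).
#' @param n_perm number of label permutations per null (default 1000).
#' @param seed integer seed (mixture restarts and permutations).
#' @param normalize apply [quantile_normalize()] first (default FALSE:
#'   input assumed pre-normalized log2 intensities).
#' @param dependence_adjust the t and log2-median-ratio statistics are
#'   computed on the same samples and are strongly positively dependent
#'   under the null, so the plain Stouffer denominator sqrt(2) makes the
#'   combined P anticonservative. With `TRUE`, the null correlation rho of
#'   the two statistics is estimated from paired label permutations and
#'   the denominator becomes sqrt(2 + 2 rho) (Strube's correction),
#'   restoring type-I calibration. Default `FALSE`: the plain independent
#'   Stouffer combination.
#' @return A data frame of class `differential_result` with one row per
#'   gene: `gene`, `expressed`, `t`, `lmr`, `lfc` (mean cancer - mean
#'   normal), `p_t`, `p_lmr`, `p_combined`, `is_de`. Genes failing the
#'   expressed filter carry NA statistics. Attributes: `dataset_id`,
#'   `cancer_type`, `alpha`, `mixture_fit`.
#' @export
identify_degs <- function(dataset, alpha = 0.05, n_perm = 1000L, seed = 1L,
                          normalize = FALSE, dependence_adjust = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  is_cancer <- dataset$labels == "cancer"
  if (sum(is_cancer) < 2L || sum(!is_cancer) < 2L) {
    stop("at least 2 samples per class required")
  }
  if (normalize) {
    dataset$values <- quantile_normalize(dataset$values)
  }
  fit <- fit_expression_mixture(as.vector(dataset$values), seed = seed)
  expressed <- filter_expressed(dataset, fit)
  sub <- dataset$values[expressed, , drop = FALSE]
  obs_t <- row_t_stats(sub, is_cancer)
  obs_lmr <- row_lmr_stats(sub, is_cancer)
  null_t <- empirical_null(dataset, "t", n_perm = n_perm,
                           seed = seed %% 999983L + 1L, genes = expressed)
  null_lmr <- empirical_null(dataset, "lmr", n_perm = n_perm,
                             seed = seed %% 999983L + 2L, genes = expressed)
  p_t <- two_tailed_p(obs_t$t, null_t)
  p_lmr <- two_tailed_p(obs_lmr, null_lmr)
  if (dependence_adjust) {
    # null correlation of the two statistics from paired permutations
    rho <- with_seed(seed %% 999983L + 3L, {
      nrep <- min(n_perm, 100L)
      pairs <- vapply(seq_len(nrep), function(r) {
        perm <- sample(is_cancer)
        c(row_t_stats(sub, perm)$t, row_lmr_stats(sub, perm))
      }, numeric(2L * length(expressed)))
      tvals <- as.vector(pairs[seq_along(expressed), ])
      lvals <- as.vector(pairs[-seq_along(expressed), ])
      ok <- is.finite(tvals) & is.finite(lvals)
      stats::cor(tvals[ok], lvals[ok])
    })
    z1 <- sign(obs_t$t) * stats::qnorm(p_t / 2, lower.tail = FALSE)
    z2 <- sign(obs_lmr) * stats::qnorm(p_lmr / 2, lower.tail = FALSE)
    Z <- (z1 + z2) / sqrt(2 + 2 * max(0, rho))
    p_comb <- pmin(pmax(2 * stats::pnorm(abs(Z), lower.tail = FALSE),
                        1e-15), 1)
  } else {
    p_comb <- vapply(seq_along(expressed), function(i) {
      as.numeric(stouffer_combine(c(p_t[i], p_lmr[i]),
                                  c(sign(obs_t$t[i]), sign(obs_lmr[i]))))
    }, numeric(1))
  }
  res <- data.frame(gene = dataset$genes, expressed = FALSE,
                    t = NA_real_, lmr = NA_real_, lfc = NA_real_,
                    p_t = NA_real_, p_lmr = NA_real_,
                    p_combined = NA_real_, is_de = NA,
                    stringsAsFactors = FALSE)
  rownames(res) <- res$gene
  res[expressed, "expressed"] <- TRUE
  res[expressed, "t"] <- obs_t$t
  res[expressed, "lmr"] <- obs_lmr
  res[expressed, "lfc"] <- obs_t$diff
  res[expressed, "p_t"] <- p_t
  res[expressed, "p_lmr"] <- p_lmr
  res[expressed, "p_combined"] <- p_comb
  res[expressed, "is_de"] <- p_comb <= alpha
  rownames(res) <- NULL
  structure(res, dataset_id = dataset$dataset_id,
            cancer_type = dataset$cancer_type, alpha = alpha,
            mixture_fit = fit,
            class = c("differential_result", "data.frame"))
}

#' Summarize per-dataset differential results for one cancer type
#'
#' The representative P of a gene in a cancer type is the directional
#' Stouffer combination of its per-dataset combined P values (signs taken
#' from each dataset's mean-shift direction), over the datasets where the
#' gene passed the expressed filter. The representative log2-fold-change is
#' the mean of the per-dataset mean differences.
#'
#' @param results list of `differential_result` objects (>= 1) for the
#'   same cancer type.
#' @param cancer_type label for the summary; defaults to the first
#'   result's.
#' @return A data frame of class `cancer_type_summary`: `gene`,
#'   `p_representative`, `lfc_representative`, `n_datasets`. Genes
#'   expressed in no dataset are absent.
#' @export
summarize_cancer_type <- function(results, cancer_type = NULL) {
  if (length(results) == 0L) stop("at least one dataset result required")
  if (is.null(cancer_type)) {
    cancer_type <- attr(results[[1L]], "cancer_type")
  }
  tabs <- lapply(results, function(r) r[r$expressed, , drop = FALSE])
  genes <- sort(unique(unlist(lapply(tabs, `[[`, "gene"))))
  rows <- lapply(genes, function(g) {
    ps <- numeric(0); sg <- numeric(0); lfc <- numeric(0)
    for (tab in tabs) {
      i <- match(g, tab$gene)
      if (!is.na(i)) {
        ps <- c(ps, tab$p_combined[i])
        sg <- c(sg, sign(tab$lfc[i]))
        lfc <- c(lfc, tab$lfc[i])
      }
    }
    data.frame(gene = g,
               p_representative = as.numeric(stouffer_combine(ps, sg)),
               lfc_representative = mean(lfc),
               n_datasets = length(ps), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, cancer_type = cancer_type,
            class = c("cancer_type_summary", "data.frame"))
}
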