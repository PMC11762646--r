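# Plug-in mutual information with bootstrap/permutation inference,
# Pearson correlations for the UTR analysis, chance k-mer expectation.

# Equal-width binning over [min, max]; a constant vector occupies one bin.
.bin_equal_width <- function(v, bins) {
  if (bins < 2) abort("bins must be >= 2")
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(1L, length(v)))
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  cut(v, breaks = breaks, include.lowest = TRUE, labels = FALSE)
}

.entropy_from_counts <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

.mi_from_joint <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  idx <- which(p > 0, arr.ind = TRUE)
  sum(p[idx] * log(p[idx] / (px[idx[, 1]] * py[idx[, 2]])))
}

.joint_counts <- function(bx, by, bins_x, bins_y) {
  tab <- matrix(0, nrow = bins_x, ncol = bins_y)
  for (i in seq_along(bx)) tab[bx[i], by[i]] <- tab[bx[i], by[i]] + 1
  tab
}

.check_xy <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have the same length")
  if (length(x) < 10) abort("need at least 10 paired observations")
  if (anyNA(x) || anyNA(y)) abort("missing values not allowed")
}

#' Plug-in mutual information (nats)
#'
#' Discretises `x` and `y` independently with equal-width bins over their
#' observed ranges and computes the maximum-likelihood (plug-in) estimate
#' MI = sum p(i,j) log( p(i,j) / (p(i) p(j)) ) over occupied cells, in
#' natural-log units. Deterministic given its inputs.
#'
#' @param x,y Numeric vectors of equal length (>= 10).
#' @param bins_x,bins_y Number of equal-width bins per axis (>= 2).
#' @return MI in nats (non-negative scalar).
#' @export
mutual_information <- function(x, y, bins_x = 10, bins_y = 10) {
  .check_xy(x, y)
  bx <- .bin_equal_width(x, bins_x)
  by <- .bin_equal_width(y, bins_y)
  .mi_from_joint(.joint_counts(bx, by, bins_x, bins_y))
}

#' Relative mutual information
#'
#' MI divided by the maximum MI extractable from the dataset under the
#' same discretisation, taken as the smaller of the two binned marginal
#' entropies; lies in \[0, 1\]. Defined as 0 when either marginal entropy
#' is 0 (a constant variable carries no information).
#'
#' @inheritParams mutual_information
#' @return rMI in \[0, 1\].
#' @export
relative_mi <- function(x, y, bins_x = 10, bins_y = 10) {
  .check_xy(x, y)
  bx <- .bin_equal_width(x, bins_x)
  by <- .bin_equal_width(y, bins_y)
  hx <- .entropy_from_counts(tabulate(bx, nbins = bins_x))
  hy <- .entropy_from_counts(tabulate(by, nbins = bins_y))
  denom <- min(hx, hy)
  if (denom <= 0) return(0)
  .mi_from_joint(.joint_counts(bx, by, bins_x, bins_y)) / denom
}

#' Mutual information with bootstrap CI and permutation significance
#'
#' Point MI and rMI as in [mutual_information()]; a 95% percentile
#' confidence interval from paired case-resampling bootstrap replicates;
#' and a permutation p-value
#' p = (1 + #\{MI_perm >= MI_obs\}) / (1 + n_perm) obtained by randomly
#' permuting `y`. Significance is assessed by permutation rather than by
#' centring a bootstrap distribution, because the plug-in MI bootstrap
#' null is ill-centred; the bootstrap is kept for interval reporting.
#' Fully reproducible given `seed`.
#'
#' @inheritParams mutual_information
#' @param n_boot,n_perm Resampling sizes (a value below 100 triggers a
#'   warning but still runs).
#' @param seed Integer seed controlling all resampling.
#' @return Object of class `"mi_result"`.
#' @export
resample_mi <- function(x, y, bins_x = 10, bins_y = 10,
                        n_boot = 1000, n_perm = 1000, seed) {
  .check_xy(x, y)
  if (missing(seed)) abort("seed is required")
  if (n_boot < 100 || n_perm < 100) {
    warn("n_boot or n_perm below 100: interval and p-value will be coarse")
  }
  n <- length(x)
  mi_obs <- mutual_information(x, y, bins_x, bins_y)
  rmi_obs <- relative_mi(x, y, bins_x, bins_y)

  res <- withr::with_seed(seed, {
    boot <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      mutual_information(x[idx], y[idx], bins_x, bins_y)
    }, numeric(1))
    perm <- vapply(seq_len(n_perm), function(i) {
      mutual_information(x, sample(y), bins_x, bins_y)
    }, numeric(1))
    list(boot = boot, perm = perm)
  })
  ci <- unname(quantile(res$boot, c(0.025, 0.975), type = 7))

  structure(
    list(mi_nats = mi_obs, rmi = rmi_obs,
         ci_low = ci[1], ci_high = ci[2],
         p_perm = (1 + sum(res$perm >= mi_obs)) / (1 + n_perm),
         n_boot = n_boot, n_perm = n_perm,
         bins_x = bins_x, bins_y = bins_y, n = n, seed = seed,
         boot_replicates = res$boot),
    class = "mi_result"
  )
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf(
    "<mi_result> MI = %.4f nats, rMI = %.4f, 95%% CI [%.4f, %.4f], p_perm = %.4g (n = %d)\n",
    x$mi_nats, x$rmi, x$ci_low, x$ci_high, x$p_perm, x$n))
  invisible(x)
}

#' @export
tidy.mi_result <- function(x, ...) {
  tibble(statistic = c("mi_nats", "rmi"),
         estimate = c(x$mi_nats, x$rmi),
         ci_low = c(x$ci_low, NA_real_),
         ci_high = c(x$ci_high, NA_real_),
         p_perm = c(x$p_perm, NA_real_))
}

#' @export
glance.mi_result <- function(x, ...) {
  tibble(mi_nats = x$mi_nats, rmi = x$rmi, ci_low = x$ci_low,
         ci_high = x$ci_high, p_perm = x$p_perm, n = x$n,
         n_boot = x$n_boot, n_perm = x$n_perm,
         bins_x = x$bins_x, bins_y = x$bins_y, seed = x$seed)
}

#' Histogram of bootstrap MI replicates
#'
#' @param object An `"mi_result"`.
#' @param ... Unused.
#' @return A ggplot object with the observed MI and the 95% CI marked.
#' @export
autoplot.mi_result <- function(object, ...) {
  df <- tibble(mi = object$boot_replicates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mi)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$mi_nats, colour = "red") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "bootstrap MI (nats)", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value uses the t transform with
#' n - 2 degrees of freedom. Constant vectors are an error.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return One-row tibble: `r`, `p_two_sided`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have the same length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("constant vector")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p_two_sided = ct$p.value, n = length(x))
}

#' Pairwise Pearson correlations of the UTR analysis table
#'
#' Correlates 3'UTR length, transcript length, the number of
#' experimentally verified miRNA interactors and the predicted
#' binding-site counts from two prediction tools, pairwise over complete
#' observations. The result is a symmetric long-format table with a unit
#' diagonal; pairs with fewer than 3 complete rows are flagged
#' not-computable (`r` = NA).
#'
#' @param utr_table Data frame containing the columns in `vars`.
#' @param vars Columns to correlate.
#' @return Tibble of class `"correlation_table"`: `var1`, `var2`, `r`,
#'   `p_two_sided`, `n`, `computable`.
#' @export
correlation_table <- function(utr_table,
                              vars = c("utr3_length", "transcript_length",
                                       "n_verified", "n_pred_A", "n_pred_B")) {
  missing_cols <- setdiff(vars, names(utr_table))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  grid <- expand.grid(var1 = vars, var2 = vars, stringsAsFactors = FALSE)
  out <- purrr::pmap_dfr(grid, function(var1, var2) {
    xs <- utr_table[[var1]]; ys <- utr_table[[var2]]
    ok <- stats::complete.cases(xs, ys)
    xs <- xs[ok]; ys <- ys[ok]
    if (var1 == var2) {
      return(tibble(var1 = var1, var2 = var2, r = 1, p_two_sided = NA_real_,
                    n = length(xs), computable = TRUE))
    }
    if (length(xs) < 3 || stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      return(tibble(var1 = var1, var2 = var2, r = NA_real_,
                    p_two_sided = NA_real_, n = length(xs), computable = FALSE))
    }
    pc <- pearson(xs, ys)
    tibble(var1 = var1, var2 = var2, r = pc$r, p_two_sided = pc$p_two_sided,
           n = pc$n, computable = TRUE)
  })
  class(out) <- c("correlation_table", class(out))
  out
}

#' Correlation table as a matrix
#'
#' @param x A [correlation_table()] result.
#' @return Symmetric numeric matrix of `r` values (unit diagonal).
#' @export
correlation_matrix <- function(x) {
  vars <- unique(x$var1)
  m <- matrix(NA_real_, length(vars), length(vars), dimnames = list(vars, vars))
  m[cbind(match(x$var1, vars), match(x$var2, vars))] <- x$r
  m
}

#' Correlation heatmap
#'
#' @param object A [correlation_table()] result.
#' @param ... Unused.
#' @return A ggplot tile plot of pairwise r.
#' @export
autoplot.correlation_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$var1, y = .data$var2,
                                       fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Expected spacing of a chance k-mer match
#'
#' In uniform random nucleotide sequence a fixed k-mer occurs on average
#' once every 4^k nucleotides — e.g. a 6-nucleotide seed match is expected
#' by chance every 4096 nt, which is why raw seed matches vastly
#' overcount functional sites.
#'
#' @param k Motif length, integer in 1..15.
#' @return `4^k` as a numeric scalar.
#' @seealso [expected_kmer_count()]
#' @export
#' @examples
#' kmer_chance_spacing(6) # 4096
kmer_chance_spacing <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 1 || k > 15) {
    abort("k must be a single integer in 1..15")
  }
  4^k
}

#' Expected chance occurrences of a k-mer in a sequence of length L
#'
#' @param L Sequence length (>= k).
#' @param k Motif length, integer in 1..15.
#' @return `(L - k + 1) / 4^k`.
#' @export
expected_kmer_count <- function(L, k) {
  spacing <- kmer_chance_spacing(k)
  if (any(L < k)) abort("L must be >= k")
  (L - k + 1) / spacing
}
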