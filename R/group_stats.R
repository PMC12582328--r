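#' Normality-gated paired comparison
#'
#' Compares two paired samples the way within-sensillum morphometrics are
#' compared: a Shapiro-Wilk normality test on the paired differences gates
#' the choice between a paired t test (normality passed at `alpha`) and the
#' Wilcoxon signed-rank test (normality failed). All-zero differences are
#' degenerate: no test applies and p = 1 is reported.
#'
#' Signed-rank zeros are handled by the Pratt convention: zero differences
#' enter the ranking of absolute values but their ranks are discarded from
#' the rank sums (normal approximation with tie correction). With no zeros
#' and small samples the exact signed-rank distribution is used.
#'
#' @param a,b numeric vectors of equal length (paired by index), length >= 3.
#' @param alpha significance level of the normality gate (default 0.05).
#' @return list with `test` (`"paired t"`, `"wilcoxon signed rank"` or
#'   `"degenerate"`), `statistic`, `p_value`, `shapiro_p`, `n`.
#' @export
paired_compare <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("data error: a and b must be paired")
  if (length(a) < 3) stop("data error: need at least 3 pairs")
  d <- a - b
  if (all(d == 0))
    return(list(test = "degenerate", statistic = NA_real_, p_value = 1,
                shapiro_p = NA_real_, n = length(d)))
  sw <- stats::shapiro.test(d)
  if (sw$p.value >= alpha) {
    tt <- stats::t.test(a, b, paired = TRUE)
    list(test = "paired t", statistic = unname(tt$statistic),
         p_value = tt$p.value, shapiro_p = sw$p.value, n = length(d))
  } else {
    w <- signed_rank_test(d)
    list(test = "wilcoxon signed rank", statistic = w$statistic,
         p_value = w$p_value, shapiro_p = sw$p.value, n = length(d))
  }
}

# Wilcoxon signed-rank on a difference vector. Zeros: Pratt convention (rank
# with zeros included, then drop their ranks). Exact distribution when there
# are no zeros and no ties and n <= 50; otherwise normal approximation with
# tie and zero corrections.
signed_rank_test <- function(d) {
  n_all <- length(d)
  has_zero <- any(d == 0)
  ties <- any(duplicated(abs(d[d != 0])))
  if (!has_zero && !ties && n_all <= 50) {
    wt <- stats::wilcox.test(d, exact = TRUE)
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value))
  }
  r <- rank(abs(d))                      # zeros included in the ranking
  Vp <- sum(r[d > 0])
  nz <- sum(d == 0)
  r_nz <- r[d != 0]
  mu <- sum(r_nz) / 2
  # var of the signed rank sum over nonzero ranks, with tie correction
  sig2 <- sum(r_nz^2) / 4
  z <- (Vp - mu) / sqrt(sig2)
  list(statistic = Vp, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Kruskal-Wallis comparison across neuron types
#'
#' One-way ANOVA on ranks with tie correction, for comparisons across more
#' than two groups.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list with `H`, `p_value`, `df`.
#' @export
rank_group_compare <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("data error: need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("data error: each group needs at least 2 values")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Mann-Whitney rank-sum comparison
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test, tie-corrected; the
#' exact null distribution is used for small tie-free samples.
#'
#' @param a,b numeric vectors (nonempty).
#' @return list with `U`, `p_value`, `n` (`c(length(a), length(b))`).
#' @export
two_sample_rank <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("data error: empty input")
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n = c(length(a), length(b)))
}

#' Morphometric ratios relative to a reference neuron
#'
#' For a paired table (rows = sensilla, columns = neuron identities), each
#' value is divided by its row's reference value (the smallest-spike neuron,
#' "C", by default) and column means of these within-sensillum ratios are
#' reported. The display form rounds to one decimal ("5.0:1.2:1"); full
#' precision is kept in the returned means.
#'
#' @param table data frame or matrix, one column per neuron identity.
#' @param reference reference column name (default `"C"`).
#' @return list with `means` (named numeric), `display` (the "A:B:1"
#'   string).
#' @export
ratio_summary <- function(table, reference = "C") {
  tb <- as.data.frame(table)
  if (!reference %in% names(tb))
    stop("data error: reference column not present")
  ref <- tb[[reference]]
  if (any(!is.finite(ref)) || any(ref <= 0))
    stop("data error: reference values must be positive")
  rel <- as.data.frame(lapply(tb, function(col) col / ref))
  means <- colMeans(rel)
  others <- setdiff(names(means), reference)
  display <- paste0(paste(sprintf("%.1f", means[others]), collapse = ":"),
                    ":1")
  list(means = means, display = display)
}
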