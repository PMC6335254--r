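#' Descriptive summary of a sample
#'
#' @param x numeric vector, length >= 1 (NAs dropped).
#' @return list with `n`, `mean`, `sd` (sample SD, n-1 denominator; `NA`
#'   for n = 1), `min`, `max`.
#' @examples
#' describe_sample(c(1, 2, 3))
#' @export
describe_sample <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("empty sample", call. = FALSE)
  list(n = length(x), mean = mean(x),
       sd = if (length(x) > 1) stats::sd(x) else NA_real_,
       min = min(x), max = max(x))
}

# All permutations of 1..n (n small), as an n! x n matrix.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' Spearman rank correlation with a significance test
#'
#' Rank correlation on average (midrank) ranks, as used for the
#' within-posture weight-area association. The default p-value is the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom; `method = "exact"` enumerates all permutations of
#' one variable's ranks (supported for n <= 8).
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param method `"t"` (default) or `"exact"`.
#' @return list with `rho`, `statistic` (t; `NA` for the exact method
#'   at |rho| = 1 use `Inf`), `df`, `p_value`, `method`.
#' @examples
#' spearman_cor(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearman_cor <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("correlation undefined: a variable is constant", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "exact") {
    if (n > 8) stop("exact permutation p-value supported for n <= 8", call. = FALSE)
    perms <- all_perms(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(list(rho = rho, statistic = NA_real_, df = NA_real_,
                p_value = p, method = "Spearman (exact permutation)"))
  }
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, statistic = tstat, df = n - 2, p_value = min(p, 1),
       method = "Spearman (t approximation)")
}

#' Welch two-sample t-test from summary statistics
#'
#' The Welch (unequal-variance) t-test computed from per-group `n`,
#' `mean` and `sd` only, so that published group summaries — e.g. the
#' per-posture covered-area means and SDs — can be compared without raw
#' data. With equal n and equal sd it coincides exactly with the
#' pooled-variance t-test. `welch_t()` is the raw-data convenience
#' wrapper via [describe_sample()].
#'
#' @param s1,s2 group summaries: lists with `n`, `mean`, `sd` (as
#'   returned by [describe_sample()]), each with `n >= 2`.
#' @return list with `statistic`, `df` (Welch-Satterthwaite), `p_value`,
#'   `estimate` (mean difference), `method`.
#' @examples
#' welch_t_from_summary(list(n = 185, mean = 0.288, sd = 0.026),
#'                      list(n = 30, mean = 0.486, sd = 0.040))
#' @export
welch_t_from_summary <- function(s1, s2) {
  for (s in list(s1, s2)) {
    if (!all(c("n", "mean", "sd") %in% names(s)))
      stop("summaries need n, mean, sd", call. = FALSE)
    if (s$n < 2) stop("each group needs n >= 2", call. = FALSE)
  }
  v1 <- s1$sd^2 / s1$n; v2 <- s2$sd^2 / s2$n
  if (v1 + v2 <= 0) {
    # both SDs zero: degenerate; equal means -> t = 0
    t <- if (s1$mean == s2$mean) 0 else Inf * sign(s1$mean - s2$mean)
    return(list(statistic = t, df = s1$n + s2$n - 2,
                p_value = if (t == 0) 1 else 0,
                estimate = s1$mean - s2$mean, method = "Welch t (degenerate)"))
  }
  t <- (s1$mean - s2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (s1$n - 1) + v2^2 / (s2$n - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       estimate = s1$mean - s2$mean, method = "Welch two-sample t")
}

#' @rdname welch_t_from_summary
#' @param x,y raw numeric samples.
#' @export
welch_t <- function(x, y) {
  welch_t_from_summary(describe_sample(x), describe_sample(y))
}

#' Pairwise group comparisons with Tukey-Kramer adjustment
#'
#' One-way fixed-effects comparison of all group pairs on the
#' studentized-range distribution, with the Kramer correction for
#' unbalanced group sizes — the summary-statistics equivalent of a GLM
#' followed by Tukey-adjusted least-squares means, used here to check
#' that the posture groups are comparable in live weight. Accepts raw
#' samples (a values/groups pair) or per-group summaries.
#'
#' @param values numeric vector of observations.
#' @param groups factor/character vector parallel to `values`.
#' @param summaries alternative input: data frame with columns `group`,
#'   `n`, `mean`, `sd` (one row per group).
#' @param alpha significance level for the letter display.
#' @return list with `pairs` (data frame: `group1`, `group2`, `diff`,
#'   `se`, `q`, `p_adj`), `letters` (named character vector of compact
#'   letter display: groups sharing a letter do not differ at `alpha`),
#'   `mse` and `df_error`.
#' @examples
#' pw <- pairwise_group_comparison(
#'   summaries = data.frame(group = c("a", "b", "c"), n = c(10, 12, 9),
#'                          mean = c(1, 1.1, 3), sd = c(0.5, 0.4, 0.6)))
#' pw$letters
#' @export
pairwise_group_comparison <- function(values = NULL, groups = NULL,
                                      summaries = NULL, alpha = 0.05) {
  if (is.null(summaries)) {
    stopifnot(!is.null(values), !is.null(groups),
              length(values) == length(groups))
    g <- split(values, groups)
    summaries <- data.frame(
      group = names(g),
      n = vapply(g, length, integer(1)),
      mean = vapply(g, mean, numeric(1)),
      sd = vapply(g, stats::sd, numeric(1)),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("group", "n", "mean", "sd") %in% names(summaries)))
  if (any(summaries$n < 2)) stop("every group needs n >= 2", call. = FALSE)
  kgrp <- nrow(summaries)
  if (kgrp < 2) stop("need at least 2 groups", call. = FALSE)
  df_err <- sum(summaries$n) - kgrp
  mse <- sum((summaries$n - 1) * summaries$sd^2) / df_err

  idx <- utils::combn(kgrp, 2)
  g1 <- summaries$group[idx[1, ]]; g2 <- summaries$group[idx[2, ]]
  d <- summaries$mean[idx[1, ]] - summaries$mean[idx[2, ]]
  se <- sqrt(mse / 2 * (1 / summaries$n[idx[1, ]] + 1 / summaries$n[idx[2, ]]))
  q <- abs(d) / se
  p <- if (mse > 0) stats::ptukey(q, nmeans = kgrp, df = df_err,
                                  lower.tail = FALSE) else as.numeric(d != 0)
  pairs <- data.frame(group1 = g1, group2 = g2, diff = d, se = se, q = q,
                      p_adj = p, stringsAsFactors = FALSE)
  letters_out <- significance_letters(pairs, summaries$group, alpha = alpha)
  list(pairs = pairs, letters = letters_out, mse = mse, df_error = df_err)
}

#' Compact letter display from pairwise p-values
#'
#' Insert-and-absorb algorithm: starting from one letter covering all
#' groups, each significant pair splits the letter groups so that no
#' letter contains a significantly different pair, then redundant
#' letters are absorbed. Groups sharing any letter are not significantly
#' different. Ties in letter assignment are broken by the order of
#' `groups`.
#'
#' @param pairs data frame with `group1`, `group2`, `p_adj`.
#' @param groups group names in display order.
#' @param alpha significance level.
#' @return named character vector of letter strings, one per group.
#' @export
significance_letters <- function(pairs, groups, alpha = 0.05) {
  sets <- list(seq_along(groups))            # letter = set of group indices
  sig <- pairs[pairs$p_adj < alpha, , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    i <- match(sig$group1[r], groups); j <- match(sig$group2[r], groups)
    for (s in seq_along(sets)) {
      if (i %in% sets[[s]] && j %in% sets[[s]]) {
        sets[[length(sets) + 1]] <- setdiff(sets[[s]], i)
        sets[[s]] <- setdiff(sets[[s]], j)
      }
    }
    # absorb letters contained in another letter
    keep <- rep(TRUE, length(sets))
    for (s in seq_along(sets)) {
      for (t in seq_along(sets)) {
        if (s != t && keep[t] &&
            all(sets[[s]] %in% sets[[t]]) &&
            (length(sets[[s]]) < length(sets[[t]]) || s > t)) {
          keep[s] <- FALSE
          break
        }
      }
    }
    sets <- sets[keep]
  }
  ord <- order(vapply(sets, min, numeric(1)))
  sets <- sets[ord]
  out <- vapply(seq_along(groups), function(i) {
    paste0(letters[which(vapply(sets, function(s) i %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  names(out) <- groups
  out
}
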