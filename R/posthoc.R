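#' One-way (between-group) ANOVA
#'
#' Classical between/within decomposition for `k >= 2` groups of possibly
#' unequal size, with `df = (k - 1, N - k)`.  Accepts either raw samples or
#' exact summary statistics (means, SDs, group sizes), which give identical
#' results because the decomposition depends on the data only through them.
#'
#' @param groups list of numeric vectors (one per group), or `NULL` when
#'   summary statistics are supplied.
#' @param means,sds,ns numeric vectors of group means, standard deviations
#'   and sizes (summary-statistics path).
#' @return list with `F`, `df` (numerator, denominator), `p`, `ss_between`,
#'   `ss_within`, `ms_within`, `means`, `ns`, `degenerate` (`TRUE`, with a
#'   warning and `F = 0`, when all values are identical).
#' @examples
#' oneway_anova(list(rnorm(12), rnorm(11), rnorm(10)))$df  # 2, 30
#' @export
oneway_anova <- function(groups = NULL, means = NULL, sds = NULL, ns = NULL) {
  if (!is.null(groups)) {
    if (!is.list(groups) || length(groups) < 2)
      stop("need at least 2 groups")
    groups <- lapply(groups, function(g) g[!is.na(g)])
    ns <- lengths(groups)
    if (any(ns < 1)) stop("every group needs at least one observation")
    means <- vapply(groups, mean, numeric(1))
    sds <- vapply(groups, function(g)
      if (length(g) > 1) stats::sd(g) else 0, numeric(1))
  } else {
    if (is.null(means) || is.null(sds) || is.null(ns))
      stop("supply either raw groups or means, sds and ns")
    if (length(means) < 2) stop("need at least 2 groups")
  }
  k <- length(means)
  N <- sum(ns)
  if (N <= k) stop("total sample size must exceed the number of groups")
  gm <- sum(ns * means) / N
  ss_b <- sum(ns * (means - gm)^2)
  ss_w <- sum((ns - 1) * sds^2)
  df <- c(k - 1, N - k)
  if (ss_w <= 0 && ss_b <= 0) {
    warning("all values identical; F set to 0")
    return(list(F = 0, df = df, p = 1, ss_between = 0, ss_within = 0,
                ms_within = 0, means = means, ns = ns, degenerate = TRUE))
  }
  ms_w <- ss_w / df[2]
  F <- (ss_b / df[1]) / ms_w
  list(F = F, df = df, p = stats::pf(F, df[1], df[2], lower.tail = FALSE),
       ss_between = ss_b, ss_within = ss_w, ms_within = ms_w,
       means = means, ns = ns, degenerate = FALSE)
}

#' Ryan's sequentially rejective post-hoc procedure
#'
#' All pairwise comparisons among `k` group means with a shared error
#' variance (typically the within-group mean square of the preceding
#' ANOVA).  The means are ordered; a comparison spanning `r` ordered means
#' is tested at the adjusted nominal level `alpha' = 2 alpha / (k (r - 1))`,
#' proceeding from the widest span inward, and a pair is declared
#' significant only if `p < alpha'(r)` AND every enclosing (wider-span)
#' comparison containing it was itself significant.  With `k = 2` the
#' procedure reduces to a plain t test at level `alpha`.
#'
#' @param x either a list of numeric vectors (raw groups; error variance
#'   then defaults to the one-way within-group MS) or a numeric vector of
#'   group means (then `n`, `ms_error`, `df_error` are required).
#' @param n group sizes (scalar recycled, or vector).
#' @param ms_error shared error mean square.
#' @param df_error its degrees of freedom.
#' @param alpha familywise significance level (0.05).
#' @param labels optional group names.
#' @return a `ryan_comparisons` data frame: `level_a`, `level_b` (ordered so
#'   `mean_a <= mean_b`), `diff`, `t`, `df`, `p` (raw two-sided), `span`,
#'   `nominal_level`, `tested`, `significant`.
#' @export
ryan_test <- function(x, n = NULL, ms_error = NULL, df_error = NULL,
                      alpha = 0.05, labels = NULL) {
  if (is.list(x)) {
    if (is.null(labels)) labels <- names(x)
    aov1 <- oneway_anova(x)
    means <- aov1$means
    ns <- aov1$ns
    if (is.null(ms_error)) {
      ms_error <- aov1$ms_within
      df_error <- aov1$df[2]
    }
  } else {
    means <- x
    if (is.null(labels)) labels <- names(x)
    if (is.null(n) || is.null(ms_error) || is.null(df_error))
      stop("with group means, supply n, ms_error and df_error")
    ns <- rep_len(n, length(means))
  }
  k <- length(means)
  if (k < 2) stop("need at least 2 groups")
  if (!is.finite(ms_error) || ms_error <= 0)
    stop("error variance must be positive")
  if (is.null(labels)) labels <- paste0("g", seq_len(k))

  ord <- order(means)
  m <- means[ord]
  nn <- ns[ord]
  lab <- labels[ord]

  pairs <- utils::combn(k, 2)
  res <- data.frame(
    i = pairs[1, ], j = pairs[2, ],
    level_a = lab[pairs[1, ]], level_b = lab[pairs[2, ]],
    diff = m[pairs[2, ]] - m[pairs[1, ]],
    stringsAsFactors = FALSE)
  res$t <- res$diff / sqrt(ms_error * (1 / nn[res$i] + 1 / nn[res$j]))
  res$df <- df_error
  res$p <- 2 * stats::pt(abs(res$t), df_error, lower.tail = FALSE)
  res$span <- res$j - res$i + 1
  res$nominal_level <- 2 * alpha / (k * (res$span - 1))

  # widest spans first; a pair is tested only when every enclosing pair
  # (i' <= i, j' >= j, wider span) was significant
  res <- res[order(-res$span, res$i), ]
  res$tested <- FALSE
  res$significant <- FALSE
  for (r in seq_len(nrow(res))) {
    i <- res$i[r]; j <- res$j[r]
    encl <- res$i <= i & res$j >= j & res$span > res$span[r]
    if (any(encl & !res$significant)) next
    res$tested[r] <- TRUE
    res$significant[r] <- res$p[r] < res$nominal_level[r]
  }
  res <- res[order(res$i, res$j),
             c("level_a", "level_b", "diff", "t", "df", "p", "span",
               "nominal_level", "tested", "significant")]
  rownames(res) <- NULL
  class(res) <- c("ryan_comparisons", "data.frame")
  res
}

#' @export
print.ryan_comparisons <- function(x, ...) {
  cat("Ryan sequentially rejective pairwise comparisons\n")
  y <- as.data.frame(x)
  y$diff <- signif(y$diff, 4)
  y$t <- signif(y$t, 4)
  y$p <- signif(y$p, 4)
  y$nominal_level <- signif(y$nominal_level, 4)
  print(y, row.names = FALSE)
  invisible(x)
}
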