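#' Balanced within-subject factorial ANOVA
#'
#' Full repeated-measures decomposition for a complete balanced design in
#' which every participant contributes exactly one observation to every
#' cell of the within-subject factor grid.  Each effect (main effects and
#' all interactions) is tested against its own subject-by-effect
#' interaction error term, the classical univariate repeated-measures
#' analysis.  Sums of squares are computed by inclusion-exclusion over
#' marginal totals, which is exact for balanced data.
#'
#' No sphericity correction is applied by default (uncorrected degrees of
#' freedom are reported); set `gg = TRUE` to add Greenhouse-Geisser epsilon,
#' adjusted df and adjusted p per effect.
#'
#' @param data long-format data frame.
#' @param dv name of the response column.
#' @param subject name of the participant identifier column.
#' @param within character vector of within-subject factor column names.
#' @param gg logical; add Greenhouse-Geisser-corrected columns.
#' @return a `pupil_rm_anova`: list with
#'   \item{effects}{data frame `effect`, `SS`, `df`, `MS`, `F`, `p` (plus
#'     `eps_gg`, `df_gg`, `p_gg` when `gg = TRUE`), one row per effect;}
#'   \item{errors}{data frame `term`, `SS`, `df`, `MS`, the
#'     subject-interaction error strata;}
#'   \item{subject}{SS and df between participants;}
#'   \item{total}{total SS and df;}
#'   \item{design}{factor names, levels and participant count.}
#'   Degenerate cells with zero effect and zero error variance report
#'   `F = 0`, `p = 1`.
#' @examples
#' d <- expand.grid(s = factor(1:4), a = factor(1:2))
#' d$y <- c(1, 2, 3, 4, 2, 4, 4, 6)
#' fit <- rm_anova(d, "y", "s", "a")
#' fit$effects$F  # equals the squared paired t statistic
#' @export
rm_anova <- function(data, dv, subject, within, gg = FALSE) {
  if (!is.data.frame(data)) stop("data must be a data frame")
  need <- c(dv, subject, within)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data missing column(s): ",
                         paste(miss, collapse = ", "))
  y <- data[[dv]]
  if (anyNA(y)) stop("response contains missing values")
  fac <- lapply(data[c(subject, within)], function(v) factor(v))
  names(fac) <- c(subject, within)
  nlev <- vapply(fac, nlevels, integer(1))
  n_subj <- nlev[[subject]]
  if (n_subj < 2) stop("need at least 2 participants")

  # completeness / balance: every subject x cell exactly once
  counts <- table(fac)
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)
    lab <- apply(bad, 1, function(r)
      paste(mapply(function(f, i) paste0(f, "=", levels(fac[[f]])[i]),
                   names(fac), r), collapse = ", "))
    stop("design not complete/balanced; offending cell(s): ",
         paste(utils::head(unique(lab), 5), collapse = "; "))
  }

  N <- length(y)
  grand <- sum(y)

  # raw (uncorrected) sums of squared marginal totals over a factor subset
  raw_ss <- function(cols) {
    if (!length(cols)) return(grand^2 / N)
    tot <- tapply(y, fac[cols], sum)
    sum(tot^2) / (N / prod(nlev[cols]))
  }
  subsets <- function(set) {
    k <- length(set)
    out <- list()
    for (m in 0:(2^k - 1))
      out[[m + 1]] <- set[bitwAnd(m, 2^(seq_len(k) - 1)) > 0]
    out
  }
  effect_ss <- function(set) {   # inclusion-exclusion over marginal subsets
    s <- 0
    for (sub in subsets(set))
      s <- s + (-1)^(length(set) - length(sub)) * raw_ss(sub)
    s
  }

  eff_sets <- Filter(length, subsets(within))
  eff_name <- vapply(eff_sets, paste, character(1), collapse = ":")
  eff_df <- vapply(eff_sets, function(s) prod(nlev[s] - 1), numeric(1))
  eff_SS <- vapply(eff_sets, effect_ss, numeric(1))
  err_SS <- vapply(eff_sets, function(s) effect_ss(c(subject, s)), numeric(1))
  err_df <- (n_subj - 1) * eff_df

  SS_total <- sum(y^2) - grand^2 / N
  tol <- 1e-12 * max(1, SS_total)
  MS <- eff_SS / eff_df
  MSe <- err_SS / err_df
  F <- ifelse(eff_SS <= tol & err_SS <= tol, 0, MS / MSe)
  p <- ifelse(eff_SS <= tol & err_SS <= tol, 1,
              stats::pf(F, eff_df, err_df, lower.tail = FALSE))

  effects <- data.frame(effect = eff_name, SS = eff_SS, df = eff_df,
                        MS = MS, F = F, p = p, stringsAsFactors = FALSE)
  errors <- data.frame(term = paste(subject, eff_name, sep = ":"),
                       SS = err_SS, df = err_df, MS = MSe,
                       stringsAsFactors = FALSE)

  if (gg) {
    eps <- vapply(eff_sets, function(s) gg_epsilon(y, fac, subject, s),
                  numeric(1))
    effects$eps_gg <- eps
    effects$df_gg <- eff_df * eps
    effects$p_gg <- stats::pf(F, eff_df * eps, err_df * eps,
                              lower.tail = FALSE)
  }

  structure(list(
    effects = effects,
    errors = errors,
    subject = list(SS = raw_ss(subject) - grand^2 / N, df = n_subj - 1),
    total = list(SS = SS_total, df = N - 1),
    design = list(subject = subject, within = within,
                  levels = lapply(fac[within], levels),
                  n_participants = n_subj),
    fac = fac, y = y,
    error_index = stats::setNames(seq_along(eff_sets),
                                  vapply(lapply(eff_sets, sort), paste,
                                         character(1), collapse = ":"))),
    class = "pupil_rm_anova")
}

# Greenhouse-Geisser epsilon for one effect: per-subject cell means over the
# effect's factor grid (collapsing other factors), covariance S, and an
# orthonormal basis C of the effect's contrast space (Kronecker product of
# per-factor centering projections); eps = tr(CSC')^2 / (df * tr((CSC')^2)).
gg_epsilon <- function(y, fac, subject, set) {
  cellf <- interaction(fac[set], drop = FALSE, lex.order = TRUE)
  M <- tapply(y, list(fac[[subject]], cellf), mean)
  S <- stats::cov(M)
  P <- matrix(1, 1, 1)
  for (f in set) {
    l <- nlevels(fac[[f]])
    P <- kronecker(P, diag(l) - matrix(1 / l, l, l))
  }
  e <- eigen(P, symmetric = TRUE)
  C <- t(e$vectors[, e$values > 0.5, drop = FALSE])
  A <- C %*% S %*% t(C)
  d <- nrow(A)
  max(1 / d, min(1, sum(diag(A))^2 / (d * sum(A^2))))
}

#' @export
print.pupil_rm_anova <- function(x, ...) {
  cat(sprintf("Within-subject ANOVA: %s (%d participants)\n",
              paste(x$design$within, collapse = " x "),
              x$design$n_participants))
  tab <- x$effects
  tab$SS <- signif(tab$SS, 6)
  tab$MS <- signif(tab$MS, 6)
  tab$F <- signif(tab$F, 5)
  tab$p <- signif(tab$p, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Simple main effects with a pooled error term
#'
#' Tests the effect of one within-subject factor at fixed levels of other
#' factors, after [rm_anova()] on the same table.  The error term pools the
#' subject-interaction strata of every effect composed of the tested factor
#' and (any subset of) the fixing factors; the denominator df is the sum of
#' the pooled df.  In a 2x2x4 design with 14 participants this yields the
#' characteristic `F(1, 104)` pattern for a factor crossed with both other
#' factors, and `F(1, 26)` when one factor is fixed in a 2x2x3 design.
#' Factors neither tested nor fixed are averaged out (totals are used, so
#' sums of squares stay on the full-data scale).
#'
#' @param fit a `pupil_rm_anova`.
#' @param factor name of the tested within-subject factor.
#' @param at named list: fixing factor -> level(s) at which to test.  Every
#'   combination of the supplied levels is tested.  Empty (default) reduces
#'   to the omnibus test of `factor`.
#' @param pooled logical; `FALSE` uses the cell-wise error term (the
#'   subject-by-tested-factor stratum computed within each slice) instead of
#'   the pooled term.
#' @return data frame with one row per tested cell: the fixed levels, `SS`,
#'   `df_num`, `F`, `df_den`, `p`.
#' @export
simple_effects <- function(fit, factor, at = list(), pooled = TRUE) {
  stopifnot(inherits(fit, "pupil_rm_anova"))
  within <- fit$design$within
  if (!factor %in% within) stop("'", factor, "' is not a within-subject factor")
  fixing <- names(at)
  if (length(at) && (is.null(fixing) || any(fixing == "")))
    stop("'at' must be a named list of factor = levels")
  bad <- setdiff(fixing, setdiff(within, factor))
  if (length(bad)) stop("cannot fix on: ", paste(bad, collapse = ", "))

  fac <- fit$fac
  y <- fit$y
  subject <- fit$design$subject
  n <- fit$design$n_participants
  lev_t <- levels(fac[[factor]])
  l <- length(lev_t)
  free <- setdiff(within, c(factor, fixing))  # averaged out
  m <- if (length(free)) prod(vapply(fac[free], nlevels, integer(1))) else 1

  # pooled error: subject-interaction strata of effects E with
  # factor %in% E and E subset of {factor} union fixing
  pool_sets <- Filter(function(s) factor %in% s,
                      Filter(length, local({
                        set <- c(factor, fixing)
                        k <- length(set)
                        lapply(0:(2^k - 1), function(mm)
                          set[bitwAnd(mm, 2^(seq_len(k) - 1)) > 0])
                      })))
  keys <- vapply(lapply(pool_sets, sort), paste, character(1), collapse = ":")
  idx <- fit$error_index[keys]
  SS_pool <- sum(fit$errors$SS[idx])
  df_pool <- sum(fit$errors$df[idx])

  grid <- if (length(at)) expand.grid(at, stringsAsFactors = FALSE)
          else data.frame(row.names = 1)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    keep <- rep(TRUE, length(y))
    for (f in fixing) {
      lv <- as.character(grid[[f]][g])
      if (!lv %in% levels(fac[[f]]))
        stop("level '", lv, "' not found in factor '", f, "'")
      keep <- keep & fac[[f]] == lv
    }
    ys <- y[keep]
    ts <- tapply(ys, fac[[factor]][keep], sum)
    cell_obs <- n * m
    SS <- sum(ts^2) / cell_obs - sum(ts)^2 / (l * cell_obs)
    df_num <- l - 1
    if (pooled) {
      MSe <- SS_pool / df_pool
      df_den <- df_pool
    } else {
      # cell-wise error: subject x tested-factor interaction inside the slice
      # (free factors averaged; x m keeps SS on the full-data scale)
      cellm <- tapply(ys, list(fac[[subject]][keep], fac[[factor]][keep]),
                      mean)
      sm <- rowMeans(cellm)
      fm <- colMeans(cellm)
      gm <- mean(cellm)
      resid <- cellm - outer(sm, rep(1, l)) - outer(rep(1, n), fm) + gm
      MSe <- m * sum(resid^2) / ((n - 1) * (l - 1))
      df_den <- (n - 1) * (l - 1)
    }
    F <- (SS / df_num) / MSe
    p <- stats::pf(F, df_num, df_den, lower.tail = FALSE)
    rows[[g]] <- cbind(grid[g, , drop = FALSE],
                       data.frame(factor = factor, SS = SS, df_num = df_num,
                                  F = F, df_den = df_den, p = p,
                                  stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
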