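#' Rank tables from preference surveys
#'
#' A rank table holds `n` observations (e.g. survey responses for one
#' character state each), every observation ranking the same `t`
#' sources from 1 (best) to `t` (worst) with no ties.  The derived
#' count matrix `O` has `O[i, j]` = number of times source `i` received
#' rank `j`.  Rows containing missing values (respondents who skipped a
#' character) are dropped with a note, so ragged surveys pool their
#' complete ranking rows.  Tied ranks are rejected unless
#' `ties = "midrank"`, which converts them with a warning (the count
#' matrix then holds fractional entries).
#'
#' @param ranks An `n x t` matrix or data frame of ranks; column names
#'   are the source labels.
#' @param ties `"error"` (default) or `"midrank"`.
#' @return An object of class `eqsim_rank_table` with fields `sources`,
#'   `ranks`, `O`, `n`, `t`.
#' @export
rank_table <- function(ranks, ties = c("error", "midrank")) {
  ties <- match.arg(ties)
  ranks <- as.matrix(ranks)
  if (is.null(colnames(ranks))) {
    colnames(ranks) <- paste0("S", seq_len(ncol(ranks)))
  }
  t <- ncol(ranks)
  if (t < 2L) stop("a rank table needs at least two sources")
  complete <- stats::complete.cases(ranks)
  if (any(!complete)) {
    message(sum(!complete), " incomplete ranking row(s) dropped")
    ranks <- ranks[complete, , drop = FALSE]
  }
  if (!nrow(ranks)) stop("no complete ranking rows")
  for (r in seq_len(nrow(ranks))) {
    row <- as.numeric(ranks[r, ])
    if (anyDuplicated(row) || !all(sort(row) == seq_len(t))) {
      if (ties == "midrank") {
        warning("row ", r, " is not a permutation of 1..", t,
                "; converted to midranks")
        ranks[r, ] <- rank(row)
      } else {
        stop("row ", r, " is not a permutation of 1..", t,
             " (use ties = \"midrank\" to convert)")
      }
    }
  }
  n <- nrow(ranks)
  O <- matrix(0, nrow = t, ncol = t,
              dimnames = list(colnames(ranks), paste0("rank", seq_len(t))))
  for (r in seq_len(n)) {
    for (i in seq_len(t)) {
      j <- as.numeric(ranks[r, i])
      jf <- floor(j); frac <- j - jf
      # integer ranks land in one cell; midranks split between neighbors
      if (frac == 0) O[i, jf] <- O[i, jf] + 1
      else { O[i, jf] <- O[i, jf] + (1 - frac); O[i, jf + 1] <- O[i, jf + 1] + frac }
    }
  }
  structure(list(sources = colnames(ranks), ranks = ranks, O = O,
                 n = n, t = t),
            class = "eqsim_rank_table")
}

#' @export
print.eqsim_rank_table <- function(x, ...) {
  cat("<rank table> ", x$n, " observations x ", x$t, " sources; mean ranks:\n",
      sep = "")
  print(round(mean_ranks(x), 3))
  invisible(x)
}

#' Mean rank received by each source
#' @param table An `eqsim_rank_table`.
#' @return Named numeric vector (lower = preferred).
#' @export
mean_ranks <- function(table) {
  j <- seq_len(table$t)
  rs <- as.numeric(table$O %*% j)
  stats::setNames(rs / table$n, table$sources)
}

#' Anderson's statistic for the overall distribution of ranks
#'
#' Tests whether the full observed rank-count matrix `O` departs from
#' the uniform expectation `X(i,j) = n/t` (every source equally likely
#' to receive every rank):
#' `A = ((t-1)/t) * sum_ij (O(i,j) - n/t)^2 / (n/t)`,
#' referred to a chi-square distribution with `(t-1)^2` degrees of
#' freedom.  Sensitive to any difference in rank profiles, not just
#' shifts of the mean rank.
#'
#' @param table An `eqsim_rank_table`.
#' @return List with `A`, `df`, `p`.
#' @export
anderson_a <- function(table) {
  stopifnot(inherits(table, "eqsim_rank_table"))
  expd <- table$n / table$t
  A <- (table$t - 1) / table$t * sum((table$O - expd)^2 / expd)
  df <- (table$t - 1L)^2
  list(A = A, df = df, p = stats::pchisq(A, df, lower.tail = FALSE))
}

#' Friedman's statistic for differences in mean ranks
#'
#' Tests whether the rank sums `R_i = sum_j j * O(i,j)` of the sources
#' differ from their common expectation `n(t+1)/2`:
#' `F = 12 / (n t (t+1)) * sum_i (R_i - n(t+1)/2)^2`,
#' referred to chi-square with `t-1` degrees of freedom.  `F` ranges
#' from 0 (identical mean ranks) to `n(t-1)` (perfect agreement on one
#' full ordering).
#'
#' @param table An `eqsim_rank_table`.
#' @return List with `F`, `df`, `p`.
#' @export
friedman_f <- function(table) {
  stopifnot(inherits(table, "eqsim_rank_table"))
  j <- seq_len(table$t)
  R <- as.numeric(table$O %*% j)
  Fstat <- 12 / (table$n * table$t * (table$t + 1)) *
    sum((R - table$n * (table$t + 1) / 2)^2)
  df <- table$t - 1L
  list(F = Fstat, df = df, p = stats::pchisq(Fstat, df, lower.tail = FALSE))
}

#' Two-sided paired Wilcoxon signed-rank test
#'
#' Compares paired per-state scores from two conditions.  Zero
#' differences are handled by the Pratt convention: they take part in
#' ranking the absolute differences (midranks for ties) and are then
#' removed from the statistic.  With at most 25 non-zero differences
#' the exact two-sided p-value is computed by enumerating the signed-
#' rank distribution (a shift-algorithm convolution, valid with
#' midranks); beyond that a normal approximation with continuity
#' correction is used.  If every difference is zero the p-value is 1,
#' with a note.
#'
#' @param a,b Equal-length numeric vectors of paired scores.
#' @param exact_limit Largest number of non-zero differences for which
#'   the exact distribution is enumerated (default 25).
#' @return The two-sided p-value.
#' @export
paired_signed_rank <- function(a, b, exact_limit = 25L) {
  if (length(a) != length(b)) stop("paired vectors differ in length")
  if (!length(a)) stop("empty input")
  d <- a - b
  r_all <- rank(abs(d))          # Pratt: zeros included in the ranking
  nz <- d != 0
  if (!any(nz)) {
    message("all paired differences are zero; p = 1")
    return(1)
  }
  r <- r_all[nz]
  w <- sum(r[d[nz] > 0])
  m <- sum(nz)
  if (m <= exact_limit) {
    # exact null distribution of W+ over 2^m sign assignments; ranks are
    # half-integers at worst, so double them for integer convolution
    r2 <- round(2 * r)
    total <- sum(r2)
    dist <- numeric(total + 1L)    # dist[k+1] = #assignments with 2*W+ == k
    dist[1L] <- 1
    for (rv in r2) {
      shifted <- c(numeric(rv), dist[seq_len(total + 1L - rv)])
      dist <- dist + shifted
    }
    dist <- dist / sum(dist)
    w2 <- round(2 * w)
    p_lo <- sum(dist[seq_len(w2 + 1L)])
    p_hi <- sum(dist[(w2 + 1L):(total + 1L)])
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  mu <- sum(r) / 2
  sigma <- sqrt(sum(r^2) / 4)
  z <- (w - mu - sign(w - mu) * 0.5) / sigma
  min(1, 2 * stats::pnorm(-abs(z)))
}
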