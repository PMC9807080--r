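#' Pairwise relative deprivation between two incomes
#'
#' The primitive of all the deprivation indices: the income shortfall of a
#' focal person with income `xi` relative to a comparator with income `xj`,
#' which is `xj - xi` when the comparator is strictly richer and 0 otherwise
#' (ties deprive no one).
#'
#' @param xj Comparator income(s), finite numeric.
#' @param xi Focal income(s), finite numeric. Recycled against `xj`.
#' @return Nonnegative numeric vector, `pmax(xj - xi, 0)`.
#' @examples
#' rd_pairwise(40, 10)
#' rd_pairwise(10, 10)
#' @export
rd_pairwise <- function(xj, xi) {
  if (!is.numeric(xj) || !is.numeric(xi) || any(!is.finite(xj)) || any(!is.finite(xi))) {
    abort("`xj` and `xi` must be finite numeric.")
  }
  pmax(xj - xi, 0)
}

#' Relative deprivation indices within one reference group
#'
#' Given the incomes of all members of one reference group (here, a village),
#' these functions return one deprivation statistic per member:
#'
#' * `rd_yitzhaki()`: the mean income excess of strictly richer members,
#'   `(1/n) * sum over xk > xi of (xk - xi)`, in income units. Zero for
#'   anyone holding the (weakly) maximal income.
#' * `rd_deaton()`: the Yitzhaki index divided by the group mean income,
#'   dimensionless, scale-invariant and bounded in `[0, 1)` for positive
#'   incomes.
#' * `rd_podder()`: the Yitzhaki-style sum applied to log incomes,
#'   `(1/n) * sum over xk > xi of (log(xk) - log(xi))`. Members with
#'   nonpositive income are dropped from the log computation with a warning
#'   and receive `NA`.
#' * `rd_percentile()`: the within-group income percentile rank on 0-100,
#'   `100 * (r - 1) / (n - 1)` with average ranks at ties, so a unique
#'   maximum scores 100 and a unique minimum 0.
#'
#' Groups of size one carry no comparison information: all four functions
#' return `NA` for singletons.
#'
#' @param income Numeric vector of member incomes (any order; ties allowed).
#' @return Numeric vector aligned with `income`.
#' @seealso [add_rd_indices()] to apply all four per village in a data frame.
#' @examples
#' rd_yitzhaki(c(10, 20, 30, 40))
#' rd_deaton(c(10, 20, 30, 40))
#' rd_podder(c(1, exp(1), exp(2)))
#' rd_percentile(c(10, 20, 30, 40))
#' @export
rd_yitzhaki <- function(income) {
  check_income(income)
  n <- length(income)
  if (n < 2L) return(rep(NA_real_, n))
  sum_gt(income) / n
}

#' @rdname rd_yitzhaki
#' @export
rd_deaton <- function(income) {
  check_income(income)
  n <- length(income)
  if (n < 2L) return(rep(NA_real_, n))
  mu <- mean(income)
  if (!is.finite(mu) || mu <= 0) abort("Group mean income must be positive for the Deaton index.")
  sum_gt(income) / (n * mu)
}

#' @rdname rd_yitzhaki
#' @export
rd_podder <- function(income) {
  check_income(income)
  n <- length(income)
  if (n < 2L) return(rep(NA_real_, n))
  pos <- income > 0
  out <- rep(NA_real_, n)
  if (sum(pos) < 2L) {
    warn("Fewer than 2 positive incomes in group; Podder index is NA throughout.")
    return(out)
  }
  if (any(!pos)) {
    warn(sprintf("%d nonpositive income(s) excluded from the Podder index group.", sum(!pos)))
  }
  lx <- log(income[pos])
  out[pos] <- sum_gt(lx) / sum(pos)
  out
}

#' @rdname rd_yitzhaki
#' @export
rd_percentile <- function(income) {
  check_income(income)
  n <- length(income)
  if (n < 2L) return(rep(NA_real_, n))
  r <- rank(income, ties.method = "average")
  100 * (r - 1) / (n - 1)
}

# for each element, the sum of strictly greater elements minus its own value
# times their count: sum_{xk > xi} (xk - xi). O(n log n) via sorting and
# suffix sums over distinct values.
sum_gt <- function(x) {
  n <- length(x)
  ux <- sort(unique(x))
  cnt <- tabulate(match(x, ux), nbins = length(ux))
  # suffix totals over distinct values
  tot_above <- rev(cumsum(rev(ux * cnt))) # includes own value block
  n_above <- rev(cumsum(rev(cnt)))
  idx <- match(x, ux)
  s_above <- tot_above[idx] - ux[idx] * cnt[idx]
  k_above <- n_above[idx] - cnt[idx]
  s_above - k_above * x
}

check_income <- function(income) {
  if (!is.numeric(income)) abort("`income` must be numeric.")
  if (any(!is.finite(income))) abort("`income` contains non-finite values.")
  invisible(income)
}

#' Compute all deprivation indices per person within villages
#'
#' Applies the four indices of [rd_yitzhaki()] to every person within their
#' own village (the reference group) and appends the results as columns
#' `rd_yitzhaki`, `rd_deaton`, `rd_podder`, `rd_percentile`. With
#' `standardize = TRUE` (the default), z-scored copies over the full sample
#' are appended as `*_z` columns alongside the raw values, matching the
#' convention of standardizing the main continuous variables before
#' modelling.
#'
#' Singleton villages are retained in the output but receive `NA` indices
#' (and are counted in a warning); an input with only singleton villages
#' yields all-`NA` index columns.
#'
#' @param data Data frame with at least `income` and `village` columns.
#' @param income,village Column names (strings) for per-capita income and the
#'   reference-group identifier.
#' @param standardize Append z-scored `*_z` columns? Default `TRUE`.
#' @return A tibble: `data` plus the index columns, original row order.
#' @examples
#' df <- tibble::tibble(village_id = c(1, 1, 1, 1), income = c(10, 20, 30, 40))
#' add_rd_indices(df)
#' @export
add_rd_indices <- function(data, income = "income", village = "village_id",
                           standardize = TRUE) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  for (col in c(income, village)) {
    if (!col %in% names(data)) abort(paste0("Column `", col, "` not found in `data`."))
  }
  out <- tibble::as_tibble(data)
  if (nrow(out) == 0L) {
    out$rd_yitzhaki <- out$rd_deaton <- out$rd_podder <- out$rd_percentile <- numeric(0)
    return(out)
  }
  g <- out[[village]]
  x <- out[[income]]
  check_income(x)
  sizes <- table(g)
  n_singleton <- sum(sizes < 2)
  if (n_singleton > 0) {
    warn(sprintf("%d singleton village(s): their deprivation indices are NA.", n_singleton))
  }
  idx <- split(seq_along(x), g)
  res <- matrix(NA_real_, nrow = length(x), ncol = 4)
  for (rows in idx) {
    xi <- x[rows]
    if (length(rows) < 2L) next
    res[rows, 1] <- rd_yitzhaki(xi)
    res[rows, 2] <- rd_deaton(xi)
    res[rows, 3] <- rd_podder(xi)
    res[rows, 4] <- rd_percentile(xi)
  }
  out$rd_yitzhaki <- res[, 1]
  out$rd_deaton <- res[, 2]
  out$rd_podder <- res[, 3]
  out$rd_percentile <- res[, 4]
  if (standardize) {
    out$rd_yitzhaki_z <- zscore(out$rd_yitzhaki)
    out$rd_deaton_z <- zscore(out$rd_deaton)
    out$rd_podder_z <- zscore(out$rd_podder)
    out$rd_percentile_z <- zscore(out$rd_percentile)
  }
  out
}
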