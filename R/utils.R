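#' Render shares as integer percentages that sum to 100
#'
#' Converts a vector of non-negative counts (or weights) into integer
#' percentages by largest-remainder (Hamilton) apportionment: each share is
#' floored and the remaining percentage points are assigned to the largest
#' fractional remainders. Unlike independent rounding, the result always
#' sums to exactly 100, and it reproduces the conventional rendering of
#' published share tables (e.g. counts 2275/1054/785/106 of 4220 render as
#' 54/25/19/2).
#'
#' @param counts Numeric vector of non-negative counts or weights; names are
#'   preserved.
#' @return Integer vector of the same length summing to 100 (all zeros if
#'   `sum(counts)` is 0).
#' @examples
#' integer_percent_shares(c(Buildings = 2275, Traffic = 1054,
#'                          Industry = 785, Other = 106))
#' @export
integer_percent_shares <- function(counts) {
  if (any(counts < 0) || anyNA(counts)) {
    abort("`counts` must be non-negative and non-missing.")
  }
  tot <- sum(counts)
  if (tot == 0) {
    return(setNames(rep(0L, length(counts)), names(counts)))
  }
  quota <- 100 * counts / tot
  base <- floor(quota)
  left <- 100L - as.integer(sum(base))
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(counts))
}

# Dirichlet draw via normalized gammas; rows are independent draws.
rdirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n), rate = 1),
              nrow = n, ncol = k)
  sweep(g, 1, rowSums(g), "/")
}

# provenance bookkeeping --------------------------------------------------

new_provenance <- function() {
  tibble::tibble(stage = character(), action = character(),
                 n = integer(), detail = character())
}

add_provenance <- function(prov, stage, action, n = NA_integer_, detail = "") {
  dplyr::bind_rows(prov, tibble::tibble(
    stage = stage, action = action, n = as.integer(n), detail = detail
  ))
}

stopf <- function(...) abort(sprintf(...))

`%na0%` <- function(x, repl) ifelse(is.na(x), repl, x)
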