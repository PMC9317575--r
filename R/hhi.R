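#' Convert land-cover areas to percentages
#'
#' Rivers already expressed as percentages are renormalized so each
#' composition sums to exactly 100; area entries are divided by the river
#' total.
#'
#' @param landcover an `odocon_landcover` (see [read_landcover()]).
#' @return an `odocon_landcover` of percentage kind.
#' @export
lc_percentages <- function(landcover) {
  df <- as.data.frame(landcover)
  for (r in unique(df$river)) {
    i <- df$river == r
    tot <- sum(df$value[i])
    if (tot <= 0)
      stop("river ", r, " has an all-zero land-cover composition",
           call. = FALSE)
    df$value[i] <- 100 * df$value[i] / tot
  }
  df$value_kind <- "percentage"
  as_landcover(df)
}

#' Herfindahl-Hirschman land-cover heterogeneity index
#'
#' For each river with class shares \eqn{P_j} (proportions summing to 1
#' over the \eqn{k} land-cover classes),
#' \deqn{HHI = \sum_{j=1}^{k} (100 P_j)^2 .}
#' The value lies in \eqn{[10000/k, 10000]}; higher values mean a more
#' concentrated composition, i.e. lower land-cover heterogeneity. Note the
#' attainable minimum is 10000/k (an even split), not 0. Area-kind tables
#' are converted with [lc_percentages()] first. A single-class composition
#' (k = 1) is accepted with a warning and scores 10000.
#'
#' @param landcover an `odocon_landcover`.
#' @return data.frame of class `hhi_result` with columns `river,k,hhi`,
#'   one row per river.
#' @examples
#' lc <- as_landcover(data.frame(river = "r", class_code = c("a", "b", "c"),
#'                               value = c(50, 25, 25),
#'                               value_kind = "percentage"))
#' compute_hhi(lc)$hhi  # 2500 + 625 + 625 = 3750
#' @export
compute_hhi <- function(landcover) {
  pct <- lc_percentages(landcover)
  rivers <- unique(pct$river)
  out <- data.frame(river = rivers, k = NA_integer_, hhi = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(rivers)) {
    v <- pct$value[pct$river == rivers[i]]
    k <- length(v)
    if (k == 0L) stop("no land-cover classes for river ", rivers[i],
                      call. = FALSE)
    if (k == 1L)
      warning("river ", rivers[i], " has a single land-cover class; ",
              "HHI is degenerate (10000)", call. = FALSE)
    p <- v / 100  # proportions; formula scales by 100 internally
    if (abs(sum(p) - 1) > 1e-6)
      stop("proportions for river ", rivers[i], " do not sum to 1",
           call. = FALSE)
    out$k[i] <- k
    out$hhi[i] <- sum((100 * p)^2)
  }
  class(out) <- c("hhi_result", "data.frame")
  out
}
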