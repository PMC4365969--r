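#' @importFrom rlang %||% abort warn inform
#' @importFrom dplyr mutate filter select arrange bind_rows group_by summarise
#'   ungroup n left_join anti_join semi_join distinct pull across rename if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dfr map_chr map_dbl map_int map2
#' @importFrom stats median rbinom rnbinom rpois runif rnorm setNames
#'   fisher.test wilcox.test prop.test runmed quantile
#' @importFrom utils head tail
NULL

# round half away from zero to `digits` decimals (so 81.65 -> 81.7, 8.75 -> 9);
# base round() is half-to-even and would render 81.6
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

geometric_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}

# formats a proportion as integer percent text, "NA" when undefined
fmt_pct_int <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%d", as.integer(round_half_up(100 * x, 0))))
}

fmt_pct_1dp <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.1f", round_half_up(x, 1)))
}
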