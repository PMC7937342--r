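# Closed-form RNA-seq power and sample-size calculation.
#
# On the log scale the variance of a per-gene count is approximately
# 1/depth + cv^2 (shot noise plus biological variation, with cv the
# biological coefficient of variation = sqrt of the NB common dispersion);
# a two-sample normal approximation then gives
#   power = Phi( sqrt( n (ln effect)^2 / (2 (1/depth + cv^2)) ) - z_{1-a/2} ).

#' Power to detect a fold-change in a two-group RNA-seq comparison
#'
#' @param n replicates per group (may be fractional)
#' @param depth average sequencing coverage per gene (reads)
#' @param cv biological coefficient of variation (sqrt of the NB common
#'   dispersion; typically 0.3-0.4 for inbred lines)
#' @param effect fold-change to detect (> 0, not 1)
#' @param alpha two-sided type-I error rate
#' @return power in (0, 1); vectorised over all arguments
#' @export
#' @examples
#' power_at(n = 8.35, depth = 100, cv = 0.4, effect = 2)
power_at <- function(n, depth, cv, effect, alpha = 0.05) {
  assert_scalar_number(n, "n", lower = 1)
  assert_scalar_number(depth, "depth", lower = 0, strict_lower = TRUE)
  assert_scalar_number(cv, "cv", lower = 0)
  assert_scalar_number(effect, "effect", lower = 0, strict_lower = TRUE)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  if (any(effect == 1)) abort("`effect` = 1 is a degenerate (null) effect")
  v <- 1 / depth + cv^2
  if (any(v == 0)) abort("1/depth + cv^2 must be positive")
  pnorm(sqrt(n * log(effect)^2 / (2 * v)) - qnorm(1 - alpha / 2))
}

#' Replicates per group required for a target power
#'
#' Inverts [power_at()] in closed form:
#' `n = 2 (z_{1-alpha/2} + z_{power})^2 (1/depth + cv^2) / (ln effect)^2`.
#' The integer report rounds half away from zero to the nearest whole
#' replicate (not the ceiling): e.g. 93% power for a 2-fold change at 100X
#' coverage needs 5 replicates at cv 0.3 and 8 at cv 0.4.
#'
#' @inheritParams power_at
#' @param power target power in (0, 1)
#' @return tibble with the inputs, `n_exact` (real solution) and `n`
#'   (nearest integer)
#' @export
#' @examples
#' required_n(depth = 100, cv = 0.3, effect = 2, alpha = 0.05, power = 0.93)
required_n <- function(depth, cv, effect, alpha = 0.05, power = 0.93) {
  assert_scalar_number(power, "power", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar_number(effect, "effect", lower = 0, strict_lower = TRUE)
  if (any(effect == 1)) abort("`effect` = 1 is a degenerate (null) effect")
  v <- 1 / depth + cv^2
  n_exact <- 2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 * v / log(effect)^2
  tibble(depth = depth, cv = cv, effect = effect, alpha = alpha,
         power = power, n_exact = n_exact,
         n = as.integer(round_half_away(n_exact)))
}

#' Power over a parameter grid
#'
#' @param grid tibble/data frame with columns `n`, `depth`, `cv`, `effect`
#'   and optionally `alpha` (default 0.05), e.g. from [tidyr::crossing()]
#' @return the grid with a `power` column appended, classed `power_grid`
#'   (see [autoplot.power_grid()])
#' @export
power_table <- function(grid) {
  if (!nrow(grid)) abort("empty parameter grid")
  grid <- as_tibble(grid)
  if (!"alpha" %in% names(grid)) grid$alpha <- 0.05
  grid$power <- power_at(grid$n, grid$depth, grid$cv, grid$effect, grid$alpha)
  class(grid) <- c("power_grid", class(grid))
  grid
}

#' Probability that a small larval pool is all-female
#'
#' Under an equal sex ratio, a pool of `n` larvae is all-female with
#' probability `p_female^n` — e.g. 0.5^3 = 12.5% for a three-larva
#' replicate, enough to explain an outlier replicate that clusters with
#' male-killed treatments.
#'
#' @param n_larvae larvae in the pool
#' @param p_female probability an individual is female (default 0.5)
#' @return probability in `[0, 1]`
#' @export
#' @examples
#' all_female_pool_prob(3)
all_female_pool_prob <- function(n_larvae, p_female = 0.5) {
  assert_scalar_number(n_larvae, "n_larvae", lower = 0)
  assert_scalar_number(p_female, "p_female", lower = 0, upper = 1)
  p_female^n_larvae
}
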