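#' Group mean r2 by genetic distance
#'
#' Groups LD pairs by their genetic distance `c` (rounded to
#' `c_round_digits` decimals, which makes grouping on floating-point
#' distances well defined) and returns the mean r2 and pair count per
#' distinct distance. Pairs at c = 0 after rounding carry no recombination
#' information and are dropped; their count is in `attr(, "n_dropped_zero")`.
#'
#' @param pairs An `ld_pair_table` with a `c_morgan` column
#'   (see [add_genetic_distance()]).
#' @param c_round_digits Decimal digits for rounding c before grouping.
#' @return A `distance_bins` data.frame with columns `c` (Morgans, strictly
#'   increasing), `mean_r2`, `n_pairs`.
#' @export
bin_mean_r2 <- function(pairs, c_round_digits = 6) {
  stopifnot(inherits(pairs, "ld_pair_table"))
  if (is.null(pairs$c_morgan))
    stop("pair table has no genetic distances; run add_genetic_distance()")
  if (nrow(pairs) == 0L) stop("empty pair table")
  cr <- round(pairs$c_morgan, c_round_digits)
  zero <- cr == 0
  n_zero <- sum(zero)
  if (all(zero))
    stop("all pairs have c = 0 after rounding; no usable genetic distances")
  r2 <- pairs$r2[!zero]
  cr <- cr[!zero]
  m <- tapply(r2, cr, mean)
  n <- tapply(r2, cr, length)
  cv <- as.numeric(names(m))
  ord <- order(cv)
  bins <- data.frame(c = cv[ord], mean_r2 = as.numeric(m)[ord],
                     n_pairs = as.integer(n)[ord])
  structure(bins, class = c("distance_bins", "data.frame"),
            c_round_digits = c_round_digits, n_dropped_zero = n_zero)
}

#' Construct distance bins directly
#'
#' Convenience constructor for a `distance_bins` table from explicit
#' genetic distances and mean r2 values (e.g. for estimator validation on
#' analytic LD curves).
#'
#' @param c Genetic distances in Morgans, distinct and positive.
#' @param mean_r2 Mean r2 per distance, in `[0, 1]`.
#' @param n_pairs Pair counts (default 1).
#' @return A `distance_bins` data.frame.
#' @export
distance_bins <- function(c, mean_r2, n_pairs = 1L) {
  if (length(c) != length(mean_r2))
    stop("c and mean_r2 must have equal length")
  if (any(duplicated(c))) stop("c values must be distinct")
  if (any(c <= 0)) stop("c values must be positive")
  ord <- order(c)
  structure(data.frame(c = c[ord], mean_r2 = mean_r2[ord],
                       n_pairs = rep_len(as.integer(n_pairs),
                                         length(c))[ord]),
            class = c("distance_bins", "data.frame"))
}

#' Stage-1 linear prediction of expected r2
#'
#' Ordinary least squares of the binned mean r2 on genetic distance with an
#' intercept, solved literally through the normal equations
#' `beta = (X'X)^-1 X'Y` with design `X = [1 c]`. The fitted values are the
#' smoothed "expected r2" that feed the Ne regression in the two-stage
#' scheme.
#'
#' @param bins A `distance_bins` table with at least 2 distinct distances.
#' @return A `stage1_fit` list: `beta0`, `beta1`, `mu_hat` (fitted expected
#'   r2 per distance), `c`, `n_used`.
#' @export
fit_stage1 <- function(bins) {
  stopifnot(inherits(bins, "distance_bins"))
  if (length(unique(bins$c)) < 2L)
    stop("stage-1 regression needs >= 2 distinct genetic distances")
  X <- cbind(1, bins$c)
  Y <- bins$mean_r2
  beta <- solve(crossprod(X), crossprod(X, Y))
  mu_hat <- as.numeric(X %*% beta)
  structure(list(beta0 = beta[1L], beta1 = beta[2L], mu_hat = mu_hat,
                 c = bins$c, n_used = nrow(bins)),
            class = "stage1_fit")
}

#' Expected r2 under the Sved drift-recombination relation
#'
#' The equilibrium expectation `E(r2) = 1 / (1 + 4 * ne * c)` linking LD to
#' effective population size and recombination distance.
#'
#' @param ne Effective population size (> 0).
#' @param c Genetic distance in Morgans (>= 0). Vectorized.
#' @return Expected r2 in `(0, 1]`.
#' @export
sved_expected_r2 <- function(ne, c) {
  if (any(ne <= 0)) stop("ne must be positive")
  if (any(c < 0)) stop("c must be >= 0")
  1 / (1 + 4 * ne * c)
}

#' Estimate effective population size from binned LD
#'
#' Inverts the Sved relation by no-intercept least squares. With
#' `Y = 1/mu - 1` and `X = 4c`, the slope `beta1 = sum(XY) / sum(X^2)` is
#' the Ne estimate. In `"paper"` mode `mu` is the stage-1 fitted expected
#' r2 (see [fit_stage1()]), reproducing the two-stage scheme in which a
#' linear smooth of the decay profile feeds the transform; in `"direct"`
#' mode `mu` is the binned mean r2 itself, which inverts an exact Sved
#' curve perfectly and serves as the validation mode. Rows with `mu <= 0`
#' (possible at large distances under a negative stage-1 slope) are
#' excluded and counted, never clamped.
#'
#' @param bins A `distance_bins` table.
#' @param mode `"paper"` (two-stage, the default) or `"direct"`.
#' @param sample_n Optional number of samples used to compute r2; when
#'   given, `1/sample_n` is subtracted from `mu` first to offset the
#'   finite-sample upward bias of r2. Off by default: the plain Sved
#'   relation carries no correction term.
#' @return An `ne_estimate` list: `ne`, `mode`, `stage1` (`NULL` in direct
#'   mode), `n_points`, `dropped_nonpositive`, `degenerate` (TRUE when
#'   ne <= 0, flagged with a warning).
#' @export
estimate_ne <- function(bins, mode = c("paper", "direct"), sample_n = NULL) {
  stopifnot(inherits(bins, "distance_bins"))
  mode <- match.arg(mode)
  if (mode == "paper") {
    stage1 <- fit_stage1(bins)
    mu <- stage1$mu_hat
  } else {
    stage1 <- NULL
    mu <- bins$mean_r2
  }
  if (!is.null(sample_n)) {
    if (sample_n <= 1) stop("sample_n must exceed 1")
    mu <- mu - 1 / sample_n
  }
  keep <- mu > 0
  dropped <- sum(!keep)
  if (!any(keep))
    stop("all expected-r2 values are <= 0; cannot invert the Sved relation")
  Y <- 1 / mu[keep] - 1
  X <- 4 * bins$c[keep]
  ne <- sum(X * Y) / sum(X^2)
  degenerate <- !is.finite(ne) || ne <= 0
  if (degenerate)
    warning("non-positive Ne estimate: LD profile does not decay")
  structure(list(ne = ne, mode = mode, stage1 = stage1,
                 n_points = sum(keep), dropped_nonpositive = dropped,
                 degenerate = degenerate),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Ne estimate (%s mode): %.2f\n", x$mode, x$ne))
  cat(sprintf("  regression points: %d (dropped mu<=0: %d)\n",
              x$n_points, x$dropped_nonpositive))
  if (!is.null(x$stage1))
    cat(sprintf("  stage 1: mean r2 = %.4f + %.4f c\n",
                x$stage1$beta0, x$stage1$beta1))
  if (x$degenerate) cat("  WARNING: degenerate (non-decaying) LD profile\n")
  invisible(x)
}

#' Export an Ne estimate as JSON
#'
#' @param est An `ne_estimate`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ne_estimate <- function(est, path) {
  stopifnot(inherits(est, "ne_estimate"))
  x <- list(ne = est$ne, mode = est$mode, n_points = est$n_points,
            dropped_nonpositive = est$dropped_nonpositive,
            degenerate = est$degenerate)
  if (!is.null(est$stage1))
    x$stage1 <- list(beta0 = est$stage1$beta0, beta1 = est$stage1$beta1,
                     n_used = est$stage1$n_used)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
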