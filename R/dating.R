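#' Expected diploid ancestry-block count under hybrid isolation
#'
#' Tracing a pedigree of `T` generations, a haploid genome of length `L` cM
#' accumulates `0.01 T L` recombination events in expectation; under hybrid
#' isolation with genome-wide ancestry proportion `z`, a fraction `2 z (1-z)`
#' of them joins haplotypes of opposite ancestry and becomes a visible
#' ancestry switch. The expected number of ancestry switches in a diploid
#' genome is therefore `B = (2 x 2 x 0.01) T L z (1-z)`, and each switch adds
#' one block to the baseline of one block per chromosome per haplotype, giving
#' `B + 2 n_chrom` expected blocks (44 at `z = 0` for 22 autosomes).
#'
#' @param T_gen admixing time in generations (>= 0); vectorized.
#' @param z genome-wide target-ancestry proportion in `[0, 1]`; vectorized.
#' @param L total genome length in cM (default 3435).
#' @param n_chrom autosome count (default 22).
#' @return expected diploid block count.
#' @export
expected_block_count <- function(T_gen, z, L = 3435, n_chrom = 22) {
  stopifnot(all(T_gen >= 0), all(z >= 0 & z <= 1), L > 0)
  0.04 * T_gen * L * z * (1 - z) + 2 * n_chrom
}

#' Estimate the admixing time from ancestry-block counts
#'
#' Pooled least squares of observed per-individual diploid block counts
#' against the theoretical hybrid-isolation curves over an integer grid of
#' generations: `T_hat = argmin_T sum_i (count_i - E[blocks | T, z_i])^2`,
#' ties broken toward the smaller (older bound of the more recent) time. A
#' fractional refinement by quadratic interpolation of the residual profile
#' around the minimum is also reported (flagged as interpolation, not a grid
#' value).
#'
#' @param obs data.frame with columns `z` (target-ancestry proportion) and
#'   `count` (observed diploid block count, after any short-block filtering);
#'   optionally `id`.
#' @param T_grid integer candidate generations (default 5:25).
#' @param L,n_chrom see [expected_block_count()].
#' @return object of class `admix_dating`: `T_hat`, `profile` (residual sum
#'   of squares per grid point), `T_interp`, and the inputs.
#' @export
estimate_admixing_time <- function(obs, T_grid = 5:25, L = 3435,
                                   n_chrom = 22) {
  stopifnot(is.data.frame(obs), all(c("z", "count") %in% names(obs)),
            length(T_grid) >= 1, !is.unsorted(T_grid))
  if (nrow(obs) < 10)
    warning("fewer than 10 observations; the fit may be unstable")
  v <- obs$z * (1 - obs$z)
  if (all(v == 0))
    stop("all observations have z in {0, 1}; the expected curve is flat in T")
  rss <- vapply(T_grid, function(tt)
    sum((obs$count - expected_block_count(tt, obs$z, L, n_chrom))^2),
    numeric(1))
  # ties (within floating-point noise) resolve toward the smaller T
  i <- which(rss - min(rss) <= 1e-9 * max(min(rss), 1))[1]
  T_interp <- NA_real_
  if (i > 1 && i < length(T_grid)) {
    x <- T_grid[(i - 1):(i + 1)]
    y <- rss[(i - 1):(i + 1)]
    den <- (y[1] - 2 * y[2] + y[3])
    if (den > 0)
      T_interp <- x[2] - 0.5 * (x[3] - x[1]) / 2 * (y[3] - y[1]) / den
  }
  structure(list(T_hat = T_grid[i],
                 profile = data.frame(T_gen = T_grid, rss = rss),
                 T_interp = T_interp, obs = obs, L = L, n_chrom = n_chrom),
            class = "admix_dating")
}

#' @export
print.admix_dating <- function(x, ...) {
  cat("admixture dating from", nrow(x$obs), "diploid block counts\n")
  cat("  T_hat =", x$T_hat, "generations (grid",
      min(x$profile$T_gen), "-", max(x$profile$T_gen), ")\n")
  if (!is.na(x$T_interp))
    cat(sprintf("  quadratic interpolation: %.2f generations\n", x$T_interp))
  invisible(x)
}

#' @export
plot.admix_dating <- function(x, curves = NULL, ...) {
  if (is.null(curves))
    curves <- unique(round(stats::quantile(x$profile$T_gen,
                                           c(0, 0.25, 0.5, 0.75, 1)))) # nocov
  zg <- seq(0, 1, length.out = 100)
  graphics::plot(x$obs$z, x$obs$count, xlab = "ancestry proportion z",
                 ylab = "diploid ancestry blocks", pch = 19,
                 col = grDevices::grey(0.4), ...)
  for (tt in curves)
    graphics::lines(zg, expected_block_count(tt, zg, x$L, x$n_chrom),
                    lty = 3)
  graphics::lines(zg, expected_block_count(x$T_hat, zg, x$L, x$n_chrom),
                  col = 2, lwd = 2)
  invisible(x)
}
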