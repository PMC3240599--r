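#' Fit a subspace PCA to masked per-allele matrices
#'
#' Estimates the subspace spanned by the leading `d` principal components of
#' a genotype matrix with massive, individual-specific missingness by low-rank
#' factorization fitted only to observed entries: find `A` (`N x d`) and `S`
#' (`M x d`) minimizing the reconstruction error
#' `R = sum_h sum_{observed (n,m)} (G^h_nm - (A S')_nm)^2`
#' over the two per-allele matrices, which share one score vector per
#' individual. Unlike covariance-based PCA with mean imputation, the fit uses
#' every observed genotype and is insensitive to per-individual observed
#' fractions.
#'
#' Columns are standardized to mean 0, variance 1 over observed entries
#' (statistics pooled across the two allele matrices, which are exchangeable);
#' columns monomorphic in their observed part are dropped from the fit and
#' reported. The default solver is alternating least squares (each half-step
#' exactly minimizes `R` in one factor, so `R` is non-increasing); a
#' gradient-descent solver with learning rate `lambda` and backtracking is
#' retained as an alternative. After convergence the factors are
#' canonicalized: columns of `A` orthonormal, columns of `S` orthogonal with
#' norms equal to the singular values of the fitted rank-`d` reconstruction.
#'
#' @param pair a `masked_pair` from [mask_to_virtual()], a single numeric
#'   matrix (`NA` = missing), or a list of one or two such matrices.
#' @param d number of leading components; must satisfy `d < N`.
#' @param solver `"als"` (default) or `"gradient"`.
#' @param lambda learning rate for the gradient solver.
#' @param max_iter,tol stop when the relative decrease of `R` falls below
#'   `tol` (default `1e-8`) or after `max_iter` iterations.
#' @param seed seed for the random initialization of `A`.
#' @param n_starts independent random initializations; the fit with the
#'   smallest `R` is returned (masked factorizations can have local minima
#'   on small problems; one start suffices for well-structured data).
#' @param track_objective record `R` after every half-step (ALS) or step.
#' @return an object of class `sspca`: canonical factors `A`, `S`, singular
#'   values `sv`, reconstruction error `R`, `iterations`, column statistics
#'   (`center`, `scale`, `keep`), `objective` trace, and bookkeeping.
#' @export
fit_sspca <- function(pair, d = 2, solver = c("als", "gradient"),
                      lambda = 1e-3, max_iter = 500, tol = 1e-8,
                      seed = 1L, n_starts = 1L, track_objective = FALSE) {
  solver <- match.arg(solver)
  if (n_starts > 1L) {
    fits <- lapply(seq_len(n_starts) - 1L, function(o)
      fit_sspca(pair, d = d, solver = solver, lambda = lambda,
                max_iter = max_iter, tol = tol, seed = seed + o,
                n_starts = 1L, track_objective = track_objective))
    return(fits[[which.min(vapply(fits, `[[`, numeric(1), "R"))]])
  }
  Gs <- if (inherits(pair, "masked_pair")) list(pair$G1, pair$G2)
        else if (is.matrix(pair)) list(pair)
        else pair
  Gs <- lapply(Gs, as.matrix)
  N <- nrow(Gs[[1]])
  M <- ncol(Gs[[1]])
  if (d >= N) stop("d must be smaller than the number of individuals (d < N)")
  # pooled column statistics over observed entries of all allele matrices
  stacked <- do.call(rbind, Gs)
  st <- standardize_columns(stacked)
  keep <- st$keep
  if (!any(keep)) stop("no informative columns after standardization")
  all_missing <- Reduce(`&`, lapply(Gs, function(g) rowSums(!is.na(g)) == 0))
  if (any(all_missing))
    stop("individual(s) with no observed entries: ",
         paste(utils::head(which(all_missing), 10), collapse = ", "))
  # only the across-allele sums enter the normal equations and the objective:
  # R = sum_obs x^2 - 2 sum(P * Xsum) + sum(P^2 * Wsum) with P = A S'
  Mk <- sum(keep)
  Wsum <- matrix(0, N, Mk)
  Xsum <- matrix(0, N, Mk)
  x_sq <- 0
  for (h in seq_along(Gs)) {
    g <- sweep(sweep(Gs[[h]][, keep, drop = FALSE], 2, st$center[keep], "-"),
               2, st$scale[keep], "/")
    w <- !is.na(g)
    g[!w] <- 0
    x_sq <- x_sq + sum(g^2)
    Xsum <- Xsum + g
    Wsum <- Wsum + w
  }
  rm(g, w)
  set.seed(seed)
  A <- matrix(stats::rnorm(N * d), N, d)
  S <- matrix(stats::rnorm(Mk * d), Mk, d) * 0.01
  recon_err <- function(A, S) {
    P <- tcrossprod(A, S)
    x_sq - 2 * sum(P * Xsum) + sum(P * P * Wsum)
  }
  obj <- numeric(0)
  R_prev <- recon_err(A, S)
  iters <- 0L
  if (solver == "als") {
    tWsum <- t(Wsum)
    tXsum <- t(Xsum)
    for (it in seq_len(max_iter)) {
      iters <- it
      # exact half-step minimizers admit the least-squares identity
      # R = sum_obs x^2 - sum(F * rhs) for the freshly solved factor F
      hs <- als_half_step(Xsum, Wsum, S, d)          # rows of A
      A <- hs$coef
      if (track_objective) obj <- c(obj, x_sq - hs$fit_ss)
      hs <- als_half_step(tXsum, tWsum, A, d)        # rows of S
      S <- hs$coef
      R_new <- x_sq - hs$fit_ss
      if (track_objective) obj <- c(obj, R_new)
      if (R_prev - R_new < tol * max(R_prev, .Machine$double.eps) ||
          R_new < 1e-12) {
        R_prev <- R_new
        break
      }
      R_prev <- R_new
    }
  } else {
    lam <- lambda
    for (it in seq_len(max_iter)) {
      iters <- it
      P <- tcrossprod(A, S)
      E1 <- Xsum - Wsum * P
      gA <- -2 * E1 %*% S
      gS <- -2 * crossprod(E1, A)
      repeat {
        A2 <- A - lam * gA
        S2 <- S - lam * gS
        R_new <- recon_err(A2, S2)
        if (R_new <= R_prev || lam < 1e-14) break
        lam <- lam / 2
      }
      A <- A2; S <- S2
      if (track_objective) obj <- c(obj, R_new)
      if (R_prev - R_new < tol * max(R_prev, .Machine$double.eps)) {
        R_prev <- R_new
        break
      }
      R_prev <- R_new
      lam <- lam * 1.1
    }
  }
  # canonicalize: A orthonormal columns, S columns scaled by singular values
  qa <- qr(A); qs <- qr(S)
  core <- qr.R(qa) %*% t(qr.R(qs))
  sv <- svd(core)
  A_c <- qr.Q(qa) %*% sv$u
  S_c <- qr.Q(qs) %*% sv$v %*% diag(sv$d, d, d)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(d)) {
    i <- which.max(abs(S_c[, j]))
    if (S_c[i, j] < 0) { S_c[, j] <- -S_c[, j]; A_c[, j] <- -A_c[, j] }
  }
  structure(list(A = A_c, S = S_c, sv = sv$d, R = R_prev, d = d,
                 iterations = iters, solver = solver,
                 center = st$center, scale = st$scale, keep = keep,
                 n_dropped = sum(!keep), objective = obj,
                 sample_ids = rownames(Gs[[1]])),
            class = "sspca")
}

# exact minimization of sum_obs (X - A S')^2 over the rows of A for fixed S
# (or, transposed, over the rows of S for fixed A). X, W: rows x cols with
# missing as 0/weight 0; S: cols x d. Returns the solved factor and its
# fitted sum of squares sum(coef * rhs) (per-row least-squares identity).
als_half_step <- function(X, W, S, d) {
  n <- nrow(X)
  rhs <- X %*% S
  if (d == 1) {
    den <- W %*% (S * S)
    out <- matrix(rhs / pmax(den, .Machine$double.eps), n, 1)
    return(list(coef = out, fit_ss = sum(out * rhs)))
  }
  pr <- which(upper.tri(matrix(0, d, d), diag = TRUE), arr.ind = TRUE)
  SS <- S[, pr[, 1], drop = FALSE] * S[, pr[, 2], drop = FALSE]
  P <- W %*% SS                                   # n x d(d+1)/2
  if (d == 2) {
    det <- P[, 1] * P[, 3] - P[, 2]^2
    ok <- det > 1e-12
    out <- matrix(0, n, 2)
    out[ok, 1] <- (P[ok, 3] * rhs[ok, 1] - P[ok, 2] * rhs[ok, 2]) / det[ok]
    out[ok, 2] <- (P[ok, 1] * rhs[ok, 2] - P[ok, 2] * rhs[ok, 1]) / det[ok]
    if (any(!ok)) out[!ok, ] <- solve_rows(P[!ok, , drop = FALSE],
                                           rhs[!ok, , drop = FALSE], pr, d)
  } else {
    out <- solve_rows(P, rhs, pr, d)
  }
  list(coef = out, fit_ss = sum(out * rhs))
}

solve_rows <- function(P, rhs, pr, d) {
  n <- nrow(P)
  out <- matrix(0, n, d)
  Mn <- matrix(0, d, d)
  for (i in seq_len(n)) {
    Mn[cbind(pr[, 1], pr[, 2])] <- P[i, ]
    Mn[cbind(pr[, 2], pr[, 1])] <- P[i, ]
    sol <- tryCatch(solve(Mn, rhs[i, ]), error = function(e) NULL)
    if (is.null(sol))
      sol <- solve(Mn + diag(1e-8 * (1 + max(diag(Mn))), d), rhs[i, ])
    out[i, ] <- sol
  }
  out
}

#' @export
print.sspca <- function(x, ...) {
  cat("sspca fit: d =", x$d, ", solver =", x$solver, "\n")
  cat("  reconstruction error R =", format(x$R), "after", x$iterations,
      "iterations\n")
  cat("  singular values:", paste(signif(x$sv, 4), collapse = ", "), "\n")
  if (x$n_dropped > 0)
    cat("  dropped", x$n_dropped, "monomorphic-in-observed column(s)\n")
  invisible(x)
}

#' @export
summary.sspca <- function(object, ...) {
  print(object)
  cat("  variance share of components:",
      paste(signif(object$sv^2 / sum(object$sv^2), 3), collapse = ", "), "\n")
  invisible(object)
}

#' Principal components from a fitted subspace PCA
#'
#' Orthogonalization of the factors (already canonical in the fitted model)
#' gives the leading PCs, ordered by explained reconstruction: scores are
#' `A diag(sv)` (the classical `U D` scale), loadings are unit-norm columns
#' over all `M` markers (zero at dropped columns), signs chosen so each
#' component's largest-magnitude loading is positive.
#'
#' @param model an [fit_sspca()] object.
#' @return list with `scores` (`N x d`), `loadings` (`M x d`), `sv`.
#' @export
pcs_from_factors <- function(model) {
  d <- model$d
  L <- matrix(0, length(model$keep), d)
  norms <- sqrt(colSums(model$S^2))
  norms[norms == 0] <- 1
  L[model$keep, ] <- sweep(model$S, 2, norms, "/")
  scores <- model$A %*% diag(model$sv, d, d)
  rownames(scores) <- model$sample_ids
  colnames(scores) <- colnames(L) <- paste0("PC", seq_len(d))
  list(scores = scores, loadings = L, sv = model$sv)
}

#' Project new rows onto fitted principal components
#'
#' Each new row is standardized with the model's column statistics and its
#' observed entries are regressed on the unit-norm loadings restricted to the
#' observed positions; for a complete row this reproduces the row's own PC
#' score.
#'
#' @param new_matrix numeric matrix (`N' x M`, `NA` = missing) with columns
#'   aligned to the training data.
#' @param model an [fit_sspca()] object.
#' @return `N' x d` score matrix; rows with fewer than `d` observed entries
#'   are `NA` and listed in attribute `flagged`.
#' @export
project_onto_pcs <- function(new_matrix, model) {
  new_matrix <- as.matrix(new_matrix)
  d <- model$d
  keep <- model$keep
  x <- sweep(sweep(new_matrix[, keep, drop = FALSE], 2,
                   model$center[keep], "-"), 2, model$scale[keep], "/")
  L <- model$S %*% diag(1 / sqrt(colSums(model$S^2)), d, d)
  out <- matrix(NA_real_, nrow(x), d)
  flagged <- integer(0)
  for (i in seq_len(nrow(x))) {
    o <- which(!is.na(x[i, ]))
    if (length(o) < d) { flagged <- c(flagged, i); next }
    Lo <- L[o, , drop = FALSE]
    out[i, ] <- tryCatch(
      drop(solve(crossprod(Lo), crossprod(Lo, x[i, o]))),
      error = function(e) { rep(NA_real_, d) })
    if (anyNA(out[i, ])) flagged <- c(flagged, i)
  }
  colnames(out) <- paste0("PC", seq_len(d))
  rownames(out) <- rownames(new_matrix)
  attr(out, "flagged") <- unique(flagged)
  out
}

#' @export
predict.sspca <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(pcs_from_factors(object)$scores)
  project_onto_pcs(newdata, object)
}

#' @export
plot.sspca <- function(x, groups = NULL, pcs = c(1, 2), ...) {
  sc <- pcs_from_factors(x)$scores
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(sc[, pcs[1]], sc[, pcs[2]],
                 xlab = paste0("PC", pcs[1]), ylab = paste0("PC", pcs[2]),
                 col = col, pch = 19, ...)
  invisible(sc)
}

#' Confusion fraction of a one-dimensional score
#'
#' The minimum fraction of individuals lying on the wrong side of the best
#' single threshold separating two labelled groups on one component score:
#' 0 = perfect separation, up to 0.5 for indistinguishable groups. All
#' midpoints between adjacent sorted scores (and both polarities) are
#' scanned.
#'
#' @param scores numeric vector (one PC's scores).
#' @param labels two-level grouping of the same length.
#' @return object of class `confusion_fraction`: `xi`, `threshold`,
#'   `polarity`.
#' @export
confusion_fraction <- function(scores, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  if (any(table(labels) == 0)) stop("one group is empty")
  if (anyNA(scores)) stop("scores contain NA")
  n <- length(scores)
  o <- order(scores)
  s <- scores[o]
  g1 <- labels[o] == levels(labels)[1]
  # threshold candidates: below all, between each pair, above all
  cum1 <- cumsum(g1)            # group-1 count at or below position i
  cum2 <- seq_len(n) - cum1
  n1 <- sum(g1); n2 <- n - n1
  # polarity A: group1 below threshold -> errors = (n1 - cum1) + cum2
  errA <- c(n1, n1 - cum1 + cum2)
  # polarity B: group2 below threshold
  errB <- c(n2, n2 - cum2 + cum1)
  cand <- c(-Inf, ifelse(seq_len(n) < n, (s + c(s[-1], Inf)) / 2, Inf))
  bestA <- which.min(errA); bestB <- which.min(errB)
  if (errA[bestA] <= errB[bestB]) {
    xi <- errA[bestA] / n; thr <- cand[bestA]; pol <- levels(labels)[1]
  } else {
    xi <- errB[bestB] / n; thr <- cand[bestB]; pol <- levels(labels)[2]
  }
  structure(list(xi = xi, threshold = thr, polarity_low_group = pol),
            class = "confusion_fraction")
}

#' @export
print.confusion_fraction <- function(x, ...) {
  cat(sprintf("confusion fraction xi = %.4f (threshold %.4g, '%s' below)\n",
              x$xi, x$threshold, x$polarity_low_group))
  invisible(x)
}

#' Confusion fraction as a function of mask-error rate
#'
#' For each error rate `epsilon`, the ground-truth ancestry labels of a
#' simulated two-subpopulation study are corrupted segment-wise, the panel is
#' masked to the target ancestry, a subspace PCA is fitted, and the confusion
#' fraction of PC1 against the true subpopulation labels is computed.
#' Reproduces the design in which substructure recovery degrades as
#' segment-level mask errors grow.
#'
#' @param epsilons vector of per-segment switch probabilities.
#' @param replicates simulated datasets per error rate.
#' @param sim_args arguments passed to [simulate_substructure_study()]
#'   (scale, FST, etc.).
#' @param d components to fit (PC1 is scored).
#' @param seed base seed; replicate r uses `seed + r`.
#' @return data.frame with one row per (epsilon, replicate) plus the per-rate
#'   mean as attribute `means`.
#' @export
mask_error_sweep <- function(epsilons = c(0.01, 0.03, 0.05, 0.08, 0.10,
                                          0.13, 0.16, 0.20),
                             replicates = 1, sim_args = list(), d = 2,
                             seed = 1L) {
  res <- list()
  for (r in seq_len(replicates)) {
    study <- do.call(simulate_substructure_study,
                     c(sim_args, list(seed = seed + r)))
    for (e in epsilons) {
      tr <- corrupt_ancestry_labels(study$track, e, markers = study$markers,
                                    seed = seed + r + round(1e4 * e))
      mp <- mask_to_virtual(study$panel, tr, target = 1)
      fit <- fit_sspca(mp, d = d, seed = seed)
      xi <- confusion_fraction(pcs_from_factors(fit)$scores[, 1],
                               study$subpop)$xi
      res[[length(res) + 1]] <- data.frame(epsilon = e, replicate = r,
                                           xi = xi)
    }
  }
  out <- do.call(rbind, res)
  attr(out, "means") <- stats::aggregate(xi ~ epsilon, out, mean)
  out
}
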