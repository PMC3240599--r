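#' Hidden Markov model parameters for local-ancestry decoding
#'
#' The decoder is a haploid HMM along each phased haplotype: hidden state =
#' ancestral population of origin, transition probability over a gap of
#' `d` Morgans is `1 - exp(-tau * d)` with the new state drawn from the
#' individual's ancestry proportions `q`, and emissions are ancestry-specific
#' allele frequencies. With `markov_order = 1` the emission at a marker is
#' conditioned on the previous observed allele through per-ancestry two-site
#' haplotype frequencies, capturing background LD within the ancestral
#' populations (a Markov-HMM).
#'
#' @param ref_freqs `K x M` ancestry-specific allele frequencies (allele 1).
#' @param q ancestry proportion vector (length `K`) or `N x K` matrix of
#'   per-individual proportions; rows must sum to 1.
#' @param tau switch intensity in generations (per Morgan), > 0.
#' @param markov_order 0 (site-independent emission) or 1 (emission
#'   conditioned on the previous allele).
#' @param cond_freqs optional `K x M x 2` array for order 1:
#'   `cond_freqs[k, m, a + 1] = P(allele_m = 1 | allele_{m-1} = a, ancestry k)`;
#'   the first marker of each chromosome uses the marginal frequency.
#' @param ancestry_names optional `K` names.
#' @param clip frequencies are clipped to `[clip, 1 - clip]` before emission
#'   to avoid zero-likelihood paths from finite reference panels.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(ref_freqs, q, tau = 12, markov_order = 0,
                       cond_freqs = NULL, ancestry_names = NULL,
                       clip = 0.001) {
  ref_freqs <- as.matrix(ref_freqs)
  K <- nrow(ref_freqs)
  if (is.matrix(q)) stopifnot(ncol(q) == K) else stopifnot(length(q) == K)
  qs <- if (is.matrix(q)) rowSums(q) else sum(q)
  if (max(abs(qs - 1)) > 1e-8) stop("q must sum to 1")
  stopifnot(tau > 0, markov_order %in% c(0, 1))
  if (markov_order == 1 && is.null(cond_freqs))
    stop("markov_order = 1 requires cond_freqs")
  ref_freqs <- pmin(pmax(ref_freqs, clip), 1 - clip)
  if (!is.null(cond_freqs))
    cond_freqs <- pmin(pmax(cond_freqs, clip), 1 - clip)
  if (is.null(ancestry_names)) ancestry_names <- paste0("anc", seq_len(K))
  structure(list(K = K, ref_freqs = ref_freqs, q = q, tau = tau,
                 markov_order = markov_order, cond_freqs = cond_freqs,
                 ancestry_names = ancestry_names, clip = clip),
            class = "hmm_params")
}

#' Estimate HMM parameters from labelled reference panels
#'
#' @param panel a [haplotype_panel()].
#' @param ref_sets list of `K` integer vectors of individual indices (one set
#'   per ancestry); both haplotypes of each individual are used.
#' @param tau,markov_order,ancestry_names,clip see [hmm_params()].
#' @param q ancestry proportions for the individuals to be decoded
#'   (default uniform).
#' @param mask optional logical `2N x M` matrix; only cells with `TRUE` enter
#'   the frequency estimates (used by [refine_reference_panel()]).
#' @return an [hmm_params()] object.
#' @export
estimate_hmm_params <- function(panel, ref_sets, tau = 12, markov_order = 0,
                                q = NULL, ancestry_names = NULL,
                                mask = NULL, clip = 0.001) {
  K <- length(ref_sets)
  M <- n_mark(panel)
  if (is.null(q)) q <- rep(1 / K, K)
  freqs <- matrix(NA_real_, K, M)
  cf <- if (markov_order == 1) array(NA_real_, c(K, M, 2)) else NULL
  chr_first <- c(TRUE, panel$markers$chrom[-1] != panel$markers$chrom[-M])
  for (k in seq_len(K)) {
    if (length(ref_sets[[k]]) == 0)
      stop("reference set for ancestry ", k, " is empty")
    rows <- as.vector(vapply(ref_sets[[k]], hap_rows, integer(2)))
    x <- panel$alleles[rows, , drop = FALSE]
    w <- if (is.null(mask)) matrix(TRUE, nrow(x), M)
         else mask[rows, , drop = FALSE]
    nobs <- colSums(w)
    if (all(nobs == 0))
      stop("reference for ancestry ", k, " has zero retained haplotypes")
    xs <- colSums(x * w)
    freqs[k, ] <- (xs + 0.5) / (nobs + 1)
    if (markov_order == 1) {
      xp <- cbind(0L, x[, -M, drop = FALSE])     # previous allele
      wp <- w & cbind(FALSE, w[, -M, drop = FALSE])
      wp[, chr_first] <- FALSE
      for (a in 0:1) {
        den <- colSums(wp & (xp == a))
        num <- colSums((x == 1L) & wp & (xp == a))
        cf[k, , a + 1] <- (num + 0.5) / (den + 1)
      }
      cf[k, chr_first, ] <- freqs[k, chr_first]
    }
  }
  hmm_params(freqs, q, tau = tau, markov_order = markov_order,
             cond_freqs = cf, ancestry_names = ancestry_names, clip = clip)
}

# emission matrix for a chunk of haplotypes at marker m: chunk x K
emission_at <- function(params, alle_chunk, m, prev_chunk, chr_first_m) {
  K <- params$K
  x <- alle_chunk[, m]
  e <- matrix(0, length(x), K)
  for (k in seq_len(K)) {
    if (params$markov_order == 1 && !chr_first_m) {
      f <- params$cond_freqs[k, m, 1L + prev_chunk]
    } else {
      f <- rep(params$ref_freqs[k, m], length(x))
    }
    e[, k] <- ifelse(x == 1L, f, 1 - f)
  }
  e
}

#' Decode locus-specific ancestry along phased haplotypes
#'
#' Runs the scaled forward-backward algorithm independently on every
#' haplotype, returning posterior ancestry probabilities, hard labels
#' (posterior argmax), and the log-likelihood of each haplotype. Underflow is
#' handled by per-marker scaling; the summed log scaling factors give the
#' exact log-likelihood.
#'
#' @param panel a [haplotype_panel()] with `pos_cm` filled.
#' @param params an [hmm_params()] whose `ref_freqs` align with the panel's
#'   markers.
#' @param store_posteriors keep the full `2N x M x K` posterior array
#'   (default `TRUE`).
#' @param chunk_size haplotypes processed per vectorized sweep.
#' @return an [ancestry_track()] with attributes `loglik` (per haplotype) and
#'   `mean_posterior` (per-individual `N x K` means over markers and both
#'   haplotypes).
#' @export
decode_ancestry <- function(panel, params, store_posteriors = TRUE,
                            chunk_size = 128L) {
  M <- n_mark(panel)
  if (ncol(params$ref_freqs) != M)
    stop("ref_freqs have ", ncol(params$ref_freqs),
         " markers but panel has ", M, " (marker misalignment)")
  K <- params$K
  H <- n_hap(panel)
  N <- n_ind(panel)
  if (anyNA(panel$markers$pos_cm)) stop("pos_cm missing; read a genetic map")
  mk <- panel$markers
  chr_first <- c(TRUE, mk$chrom[-1] != mk$chrom[-M])
  d_mo <- c(0, diff(mk$pos_cm)) / 100
  stay <- exp(-params$tau * pmax(d_mo, 0))
  stay[chr_first] <- 0
  Qall <- if (is.matrix(params$q)) params$q
          else matrix(params$q, N, K, byrow = TRUE)
  labels <- matrix(0L, H, M)
  loglik <- numeric(H)
  post <- if (store_posteriors) array(NA_real_, c(H, M, K)) else NULL
  meanp <- matrix(0, H, K)
  for (start in seq(1L, H, by = chunk_size)) {
    rows <- start:min(start + chunk_size - 1L, H)
    nh <- length(rows)
    A <- panel$alleles[rows, , drop = FALSE]
    Q <- Qall[ceiling(rows / 2), , drop = FALSE]
    alpha <- array(0, c(nh, K, M))
    logc <- matrix(0, nh, M)
    prev <- rep(0L, nh)
    a <- Q * emission_at(params, A, 1L, prev, TRUE)
    cs <- rowSums(a)
    alpha[, , 1] <- a / cs
    logc[, 1] <- log(cs)
    for (m in 2:M) {
      e <- emission_at(params, A, m, A[, m - 1L], chr_first[m])
      s <- stay[m]
      a_prev <- alpha[, , m - 1L]
      if (K == 1) a_prev <- matrix(a_prev, nh, 1)
      tot <- rowSums(a_prev)
      a <- (a_prev * s + tot * (1 - s) * Q) * e
      cs <- rowSums(a)
      alpha[, , m] <- a / cs
      logc[, m] <- log(cs)
    }
    beta <- matrix(1, nh, K)
    pm <- alpha[, , M]
    if (K == 1) pm <- matrix(pm, nh, 1)
    po <- pm / rowSums(pm)
    if (store_posteriors) post[rows, M, ] <- po
    meanp[rows, ] <- meanp[rows, ] + po
    labels[rows, M] <- max.col(po, ties.method = "first")
    for (m in (M - 1L):1L) {
      e <- emission_at(params, A, m + 1L, A[, m], chr_first[m + 1L])
      s <- stay[m + 1L]
      B <- e * beta
      beta <- s * B + (1 - s) * rowSums(Q * B)
      beta <- beta / exp(logc[, m + 1L])
      am <- alpha[, , m]
      if (K == 1) am <- matrix(am, nh, 1)
      po <- am * beta
      po <- po / rowSums(po)
      if (store_posteriors) post[rows, m, ] <- po
      meanp[rows, ] <- meanp[rows, ] + po
      labels[rows, m] <- max.col(po, ties.method = "first")
    }
    loglik[rows] <- rowSums(logc)
  }
  track <- ancestry_track(labels, params$ancestry_names,
                          posteriors = post)
  attr(track, "loglik") <- loglik
  mp <- (meanp[seq(1, H, 2), , drop = FALSE] +
           meanp[seq(2, H, 2), , drop = FALSE]) / (2 * M)
  rownames(mp) <- panel$sample_ids
  colnames(mp) <- params$ancestry_names
  attr(track, "mean_posterior") <- mp
  track
}

#' Iteratively refine a contaminated reference panel
#'
#' Reference individuals selected by a global-ancestry threshold may still
#' carry segments of foreign ancestry. This routine alternates between (1)
#' estimating ancestry-specific allele frequencies using only cells currently
#' assigned to each reference's claimed ancestry, (2) re-decoding the
#' reference haplotypes, and (3) masking segments decoded as foreign, until
#' assignments change at fewer than `tol` of cells or `max_iter` is reached.
#'
#' @param panel a [haplotype_panel()] containing the reference individuals.
#' @param initial_refs list of `K` integer vectors of individual indices.
#' @param tau,markov_order see [hmm_params()].
#' @param ref_q own-ancestry prior proportion used when decoding a reference
#'   individual (default 0.95, the selection threshold).
#' @param max_iter,tol stopping rule.
#' @return an [hmm_params()] with refined `ref_freqs`; attributes
#'   `iterations` and `changed` record convergence.
#' @export
refine_reference_panel <- function(panel, initial_refs, tau = 12,
                                   markov_order = 0, ref_q = 0.95,
                                   max_iter = 10, tol = 0.001) {
  K <- length(initial_refs)
  if (any(vapply(initial_refs, length, 1L) == 0))
    stop("empty reference set supplied")
  M <- n_mark(panel)
  H <- n_hap(panel)
  mask <- matrix(FALSE, H, M)
  claimed <- integer(H)
  for (k in seq_len(K)) {
    rows <- as.vector(vapply(initial_refs[[k]], hap_rows, integer(2)))
    mask[rows, ] <- TRUE
    claimed[rows] <- k
  }
  ref_rows <- which(claimed > 0)
  sub <- haplotype_panel(panel$alleles[ref_rows, , drop = FALSE][
    , , drop = FALSE], panel$markers,
    sample_ids = paste0("ref", seq_len(length(ref_rows) / 2)))
  # note: ref_rows are 2 per individual and contiguous by construction
  claimed_sub <- claimed[ref_rows]
  qmat <- matrix((1 - ref_q) / max(K - 1, 1),
                 length(ref_rows) / 2, K)
  for (i in seq_len(nrow(qmat)))
    qmat[i, claimed_sub[2 * i]] <- if (K == 1) 1 else ref_q
  changed <- 1
  it <- 0L
  params <- NULL
  while (it < max_iter && changed >= tol) {
    it <- it + 1L
    params <- estimate_hmm_params(panel, initial_refs, tau = tau,
                                  markov_order = markov_order,
                                  mask = mask, clip = 0.001)
    params$q <- qmat
    dec <- decode_ancestry(sub, params, store_posteriors = FALSE)
    new_mask <- mask
    new_mask[ref_rows, ] <- dec$labels == claimed_sub
    changed <- mean(new_mask[ref_rows, ] != mask[ref_rows, ])
    mask <- new_mask
    for (k in seq_len(K)) {
      rows <- as.vector(vapply(initial_refs[[k]], hap_rows, integer(2)))
      if (all(rowSums(mask[rows, , drop = FALSE]) == 0))
        stop("refinement left ancestry ", k, " with zero retained haplotypes")
    }
  }
  params$q <- rep(1 / K, K)
  attr(params, "iterations") <- it
  attr(params, "changed") <- changed
  params
}

#' Global ancestry by averaging local ancestry
#'
#' Per-individual genome-wide ancestry proportions obtained by averaging the
#' local-ancestry posterior over all markers and both haplotypes.
#'
#' @param track an [ancestry_track()] with posteriors (or produced by
#'   [decode_ancestry()], whose `mean_posterior` attribute is used directly).
#' @return `N x K` matrix; rows sum to 1.
#' @export
global_ancestry_from_local <- function(track) {
  mp <- attr(track, "mean_posterior")
  if (!is.null(mp)) return(mp)
  if (is.null(track$posteriors))
    stop("track has no posteriors; decode with store_posteriors = TRUE")
  H <- nrow(track$labels)
  K <- track$K
  out <- matrix(0, H / 2, K)
  for (k in seq_len(K)) {
    m <- rowMeans(track$posteriors[, , k])
    out[, k] <- (m[seq(1, H, 2)] + m[seq(2, H, 2)]) / 2
  }
  colnames(out) <- track$ancestry_names
  out
}

#' Scan for loci whose ancestry deviates from the genome-wide average
#'
#' Post-admixture selection shifts local ancestry away from the genome-wide
#' mean at the selected locus. For each ancestry, the per-marker mean dosage
#' across haplotypes is converted to a z-score against the distribution of
#' locus means; markers with `|z|` above the threshold are flagged.
#'
#' @param track an [ancestry_track()] with labels.
#' @param threshold flagging threshold on `|z|` (default 4).
#' @return an object of class `ancestry_deviation` with per-ancestry locus
#'   means, genome means, z-scores and flags.
#' @export
ancestry_deviation_scan <- function(track, threshold = 4) {
  K <- track$K
  lab <- track$labels
  locus_mean <- matrix(NA_real_, ncol(lab), K)
  z <- matrix(NA_real_, ncol(lab), K)
  genome_mean <- numeric(K)
  flagged <- vector("list", K)
  for (k in seq_len(K)) {
    lm_k <- colMeans(lab == k, na.rm = TRUE)
    locus_mean[, k] <- lm_k
    genome_mean[k] <- mean(lm_k)
    s <- stats::sd(lm_k)
    if (is.na(s) || s == 0) {
      flagged[[k]] <- integer(0)
    } else {
      z[, k] <- (lm_k - genome_mean[k]) / s
      flagged[[k]] <- which(abs(z[, k]) > threshold)
    }
  }
  colnames(locus_mean) <- colnames(z) <- track$ancestry_names
  structure(list(locus_mean = locus_mean, genome_mean = genome_mean,
                 z = z, flagged = flagged, threshold = threshold),
            class = "ancestry_deviation")
}

#' @export
print.ancestry_deviation <- function(x, ...) {
  cat("ancestry_deviation scan over", nrow(x$z), "markers, threshold |z| >",
      x$threshold, "\n")
  for (k in seq_along(x$genome_mean))
    cat(sprintf("  %s: genome mean %.3f, %d flagged marker(s)\n",
                colnames(x$z)[k], x$genome_mean[k], length(x$flagged[[k]])))
  invisible(x)
}
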