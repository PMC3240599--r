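#' Configuration of the ancestry-aware iHS scan
#'
#' @param freq_bounds derived-allele frequency bounds for scoring a SNP.
#' @param ehh_cutoff EHH level at which integration stops (default 0.05).
#' @param ancestry_mode `"truncate"`: a haplotype is treated as different
#'   from all others beyond its ancestry switch point; `"exclude400"`: drop
#'   haplotypes with an ancestry change within `exclude_snps` SNPs of the
#'   core. On data without ancestry switches the modes coincide.
#' @param ihs_threshold extreme-score threshold (default 2.5, about the top
#'   1% of standardized scores).
#' @param window_bp region seed/extension window (default 50,000 bp).
#' @param min_snps_region,min_prop_region region retention filters: at least
#'   20 scored SNPs and at least 10% above threshold.
#' @param qr_basis basis of the MAF quantile regressions: `"linear"`
#'   (default) or `"quadratic"` (useful when the null spread varies strongly
#'   and convexly with frequency, as it does at genome scale on sparse maps).
#' @param normal_iqr interquartile range of the standard normal
#'   (2 * qnorm(0.75) = 1.34898), converting a fitted IQR to unit SD.
#' @param maxgap_bp segments spanning larger physical gaps contribute
#'   proportionally less to the integral (standard large-gap guard).
#' @param exclude_snps window (in SNPs) for `"exclude400"` mode.
#' @param min_class minimum haplotypes per allele class (default 2).
#' @return a list of class `ihs_config`.
#' @export
ihs_config <- function(freq_bounds = c(0.05, 0.95), ehh_cutoff = 0.05,
                       ancestry_mode = c("truncate", "exclude400"),
                       ihs_threshold = 2.5, window_bp = 50000,
                       min_snps_region = 20, min_prop_region = 0.10,
                       qr_basis = c("linear", "quadratic"),
                       normal_iqr = 2 * stats::qnorm(0.75),
                       maxgap_bp = 20000, exclude_snps = 400,
                       min_class = 2) {
  ancestry_mode <- match.arg(ancestry_mode)
  qr_basis <- match.arg(qr_basis)
  stopifnot(freq_bounds[1] > 0, freq_bounds[2] < 1,
            freq_bounds[1] < freq_bounds[2], ihs_threshold > 0,
            ehh_cutoff >= 0)
  structure(list(freq_bounds = freq_bounds, ehh_cutoff = ehh_cutoff,
                 ancestry_mode = ancestry_mode,
                 ihs_threshold = ihs_threshold, window_bp = window_bp,
                 min_snps_region = min_snps_region,
                 min_prop_region = min_prop_region, qr_basis = qr_basis,
                 normal_iqr = normal_iqr,
                 maxgap_bp = maxgap_bp, exclude_snps = exclude_snps,
                 min_class = min_class),
            class = "ihs_config")
}

#' Extended haplotype homozygosity outward from a core SNP
#'
#' Reference (pure R) implementation: haplotypes carrying the core allele are
#' partitioned into identity classes over the interval from the core to each
#' successive marker; `EHH(x) = sum_g C(c_g, 2) / C(n, 2)`. Under the
#' ancestry-truncation rule, a haplotype whose ancestry switches away from the
#' target before `x` forms a singleton class from its switch point onward.
#'
#' @param haps 0/1 matrix, one row per haplotype in the core-allele subset.
#' @param core core marker column index.
#' @param direction `"right"` or `"left"`.
#' @param labels optional ancestry-label matrix aligned with `haps` rows.
#' @param target ancestry index whose departure truncates a haplotype.
#' @param last last marker column to extend to (default: matrix end).
#' @param stop_below stop extending once EHH drops below this value
#'   (default 0 = full extent).
#' @return data.frame with `marker` (column index) and `ehh`; EHH at the core
#'   itself is 1 by definition and not included.
#' @export
compute_ehh <- function(haps, core, direction = c("right", "left"),
                        labels = NULL, target = NULL, last = NULL,
                        stop_below = 0) {
  direction <- match.arg(direction)
  haps <- as.matrix(haps)
  n <- nrow(haps)
  if (n < 2) stop("EHH undefined for fewer than 2 haplotypes")
  dir <- if (direction == "right") 1L else -1L
  if (is.null(last)) last <- if (dir > 0) ncol(haps) else 1L
  grp <- rep(1L, n)
  singleton <- rep(FALSE, n)
  out_m <- integer(0); out_e <- numeric(0)
  j <- core + dir
  while (if (dir > 0) j <= last else j >= last) {
    if (!is.null(labels))
      singleton <- singleton | labels[, j] != target
    key <- ifelse(singleton, NA_integer_, grp * 2L + haps[, j])
    grp <- match(key, unique(key[!is.na(key)]))
    cnt <- table(grp[!singleton & !is.na(grp)])
    e <- sum(cnt * (cnt - 1) / 2) / (n * (n - 1) / 2)
    out_m <- c(out_m, j); out_e <- c(out_e, e)
    if (e < stop_below) break
    j <- j + dir
  }
  data.frame(marker = out_m, ehh = out_e)
}

#' Integrate an EHH curve (iHH)
#'
#' Trapezoidal integration of an EHH curve over physical distance, from the
#' core outward until the curve falls below `cutoff`, with linear
#' interpolation to the exact crossing point. Segments spanning physical gaps
#' larger than `maxgap_bp` are scaled down by `maxgap_bp / gap`. A curve that
#' never reaches the cutoff before the chromosome end is edge-flagged.
#'
#' @param ehh EHH values starting at 1 (the core itself).
#' @param pos_bp physical positions (bp) of the same points.
#' @param cutoff truncation level (default 0.05).
#' @param maxgap_bp large-gap guard (default 20,000).
#' @return list with `ihh` (bp x EHH units) and `edge` (logical).
#' @export
compute_ihh <- function(ehh, pos_bp, cutoff = 0.05, maxgap_bp = 20000) {
  stopifnot(length(ehh) == length(pos_bp), ehh[1] == 1)
  area <- 0
  edge <- TRUE
  if (length(ehh) >= 2) {
    for (i in 2:length(ehh)) {
      gap <- abs(pos_bp[i] - pos_bp[i - 1])
      scale <- if (maxgap_bp > 0 && gap > maxgap_bp) maxgap_bp / gap else 1
      if (ehh[i] < cutoff) {
        frac <- if (ehh[i - 1] > ehh[i])
          (ehh[i - 1] - cutoff) / (ehh[i - 1] - ehh[i]) else 0
        area <- area + scale * (ehh[i - 1] + cutoff) / 2 * gap * frac
        edge <- FALSE
        break
      }
      area <- area + scale * (ehh[i - 1] + ehh[i]) / 2 * gap
      if (ehh[i] == 0) { edge <- FALSE; break }
    }
  }
  list(ihh = area, edge = edge)
}

# qualified haplotype rows at a core marker under the ancestry rules
qualified_haps <- function(track, target_k, core, mk_chrom, config) {
  if (is.null(track)) return(NULL)
  ok <- track$labels[, core] == target_k
  if (config$ancestry_mode == "exclude400") {
    on_ch <- which(mk_chrom == mk_chrom[core])
    win <- on_ch[abs(on_ch - core) <= config$exclude_snps]
    ok <- ok & rowSums(track$labels[, win, drop = FALSE] != target_k) == 0
  }
  which(ok)
}

#' Raw (unstandardized) iHS at one core SNP
#'
#' Natural log ratio of the ancestral-allele iHH to the derived-allele iHH,
#' computed on the subset of haplotypes whose core SNP derives from the
#' target ancestry (when a track is supplied). Pure-R reference path built on
#' [compute_ehh()] and [compute_ihh()].
#'
#' @param core core marker index.
#' @param panel a [haplotype_panel()]; `markers$ancestral_is_ref` orients the
#'   derived allele.
#' @param track optional [ancestry_track()].
#' @param target ancestry index or name (required with `track`).
#' @param config an [ihs_config()].
#' @return list with `raw`, `ihh_a`, `ihh_d`, `daf`, `n_a`, `n_d`, `edge`,
#'   and `skipped` (reason string or `NA`).
#' @export
raw_ihs <- function(core, panel, track = NULL, target = NULL,
                    config = ihs_config()) {
  mk <- panel$markers
  target_k <- if (is.character(target)) match(target, track$ancestry_names)
              else target
  qual <- qualified_haps(track, target_k, core, mk$chrom, config)
  if (is.null(qual)) qual <- seq_len(nrow(panel$alleles))
  derived_allele <- if (mk$ancestral_is_ref[core]) 1L else 0L
  x <- panel$alleles[qual, core]
  der <- qual[x == derived_allele]
  anc <- qual[x != derived_allele]
  n_qual <- length(qual)
  if (n_qual < 2)
    return(list(raw = NA_real_, skipped = "fewer than 2 qualified haplotypes"))
  daf <- length(der) / n_qual
  if (daf < config$freq_bounds[1] || daf > config$freq_bounds[2])
    return(list(raw = NA_real_, daf = daf, skipped = "frequency out of bounds"))
  if (length(der) < config$min_class || length(anc) < config$min_class)
    return(list(raw = NA_real_, daf = daf,
                skipped = "allele class below min_class"))
  on_ch <- which(mk$chrom == mk$chrom[core])
  lab <- if (!is.null(track) && config$ancestry_mode == "truncate")
    track$labels else NULL
  side <- function(rows, dir) {
    lim <- if (dir > 0) max(on_ch) else min(on_ch)
    cv <- compute_ehh(panel$alleles[rows, , drop = FALSE], core,
                      if (dir > 0) "right" else "left",
                      labels = lab[rows, , drop = FALSE], target = target_k,
                      last = lim, stop_below = config$ehh_cutoff)
    compute_ihh(c(1, cv$ehh), c(mk$pos_bp[core], mk$pos_bp[cv$marker]),
                cutoff = config$ehh_cutoff, maxgap_bp = config$maxgap_bp)
  }
  a_l <- side(anc, -1); a_r <- side(anc, +1)
  d_l <- side(der, -1); d_r <- side(der, +1)
  ihh_a <- a_l$ihh + a_r$ihh
  ihh_d <- d_l$ihh + d_r$ihh
  edge <- a_l$edge || a_r$edge || d_l$edge || d_r$edge ||
    core == min(on_ch) || core == max(on_ch)
  raw <- if (ihh_a > 0 && ihh_d > 0) log(ihh_a / ihh_d) else NA_real_
  list(raw = raw, ihh_a = ihh_a, ihh_d = ihh_d, daf = daf,
       n_a = length(anc), n_d = length(der), edge = edge, skipped = NA)
}

#' Genome-wide iHS scan
#'
#' Computes the raw iHS at every SNP whose derived-allele frequency (among
#' qualified haplotypes) lies within the configured bounds, using the
#' compiled EHH engine, then standardizes the scores with
#' [standardize_ihs()].
#'
#' @param panel a [haplotype_panel()].
#' @param track optional [ancestry_track()] restricting haplotypes to one
#'   ancestry (with truncation or exclusion per `config$ancestry_mode`).
#' @param target ancestry index or name (required with `track`).
#' @param config an [ihs_config()].
#' @param standardize add the standardized score column (default TRUE).
#' @return data.frame with one row per SNP: `chrom`, `pos_bp`, `marker`,
#'   `daf`, `maf`, `ihh_a`, `ihh_d`, `n_a`, `n_d`, `raw`, `edge`, `skip`,
#'   and `std` when standardized.
#' @export
ihs_scan <- function(panel, track = NULL, target = NULL,
                     config = ihs_config(), standardize = TRUE) {
  mk <- panel$markers
  chrom_id <- as.integer(factor(mk$chrom, levels = unique(mk$chrom)))
  labels <- NULL
  target_k <- 0L
  if (!is.null(track)) {
    target_k <- if (is.character(target)) match(target, track$ancestry_names)
                else as.integer(target)
    if (is.na(target_k)) stop("unknown target ancestry")
    labels <- track$labels
  }
  mode <- if (!is.null(track) && config$ancestry_mode == "exclude400") 1L
          else 0L
  res <- .ihs_scan_cpp(panel$alleles, as.numeric(mk$pos_bp), chrom_id,
                       mk$ancestral_is_ref,
                       labels, target_k, mode, config$ehh_cutoff,
                       config$maxgap_bp, config$freq_bounds[1],
                       config$freq_bounds[2], config$min_class,
                       config$exclude_snps)
  out <- data.frame(chrom = mk$chrom, pos_bp = mk$pos_bp,
                    marker = seq_len(nrow(mk)), daf = res$daf,
                    ihh_a = res$ihh_a, ihh_d = res$ihh_d,
                    n_a = res$n_a, n_d = res$n_d,
                    edge = res$edge, skip = res$skip)
  out$maf <- pmin(out$daf, 1 - out$daf)
  out$raw <- ifelse(out$ihh_a > 0 & out$ihh_d > 0,
                    log(out$ihh_a / out$ihh_d), NA_real_)
  out$raw[out$skip != 0] <- NA_real_
  if (standardize) out <- standardize_ihs(out, config)
  out
}

# low-dimensional polynomial quantile (check-loss) fit: y ~ poly(x, degree)
# at quantile tau, minimized by Nelder-Mead from the least-squares start
# (restarted once; the check loss is convex piecewise linear in the
# coefficients, so the simplex converges reliably at this dimension)
fit_quantile_poly <- function(x, y, tau, degree = 1) {
  X <- qr_design(x, degree)
  loss <- function(b) {
    r <- y - drop(X %*% b)
    sum(r * (tau - (r < 0)))
  }
  b <- stats::coef(stats::lm.fit(X, y))
  for (rep in 1:2)
    b <- stats::optim(b, loss, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))$par
  unname(b)
}

qr_design <- function(x, degree) outer(x, 0:degree, "^")

#' Standardize raw iHS scores by a MAF-dependent interquartile range
#'
#' Two-stage normalization within each chromosome. The location of the raw
#' score is odd in the derived allele frequency (a low-frequency derived
#' allele is young and rides a long haplotype, giving negative scores; its
#' mirror-image SNP gives positive ones), so it cannot be captured by any
#' function of MAF: stage 1 centers each score at a fitted mid-quartile
#' polynomial in derived frequency. Stage 2 is the scale step: quantile
#' regressions estimate the 25th and 75th percentiles of the centered scores
#' as a function of minor allele frequency, and each score is recentered at
#' the fitted mid-quartile and scaled by the fitted IQR divided by the
#' standard-normal IQR (1.34898), so neutral standardized scores follow an
#' approximate standard normal. If the fitted IQR is non-positive anywhere
#' over the observed MAF range, the chromosome falls back to frequency-bin
#' normalization with a warning. Edge-flagged scores are excluded from the
#' fits and left unstandardized.
#'
#' @param scores data.frame from [ihs_scan()] (columns `chrom`, `maf`,
#'   `raw`, `edge`).
#' @param config an [ihs_config()].
#' @param min_scores minimum usable scores per chromosome for a stable fit
#'   (default 200); chromosomes below it are pooled with a warning.
#' @return the data.frame with a `std` column added.
#' @export
standardize_ihs <- function(scores, config = ihs_config(),
                            min_scores = 200) {
  scores$std <- NA_real_
  usable <- is.finite(scores$raw) & !scores$edge
  chroms <- unique(scores$chrom)
  small <- vapply(chroms, function(ch)
    sum(usable & scores$chrom == ch) < min_scores, logical(1))
  groups <- if (any(small)) {
    warning("chromosome(s) with fewer than ", min_scores,
            " usable scores are normalized jointly: ",
            paste(chroms[small], collapse = ", "))
    ifelse(scores$chrom %in% chroms[small], ".pooled", scores$chrom)
  } else scores$chrom
  basis <- if (is.null(config$qr_basis)) "linear" else config$qr_basis
  deg <- if (basis == "quadratic") 2L else 1L
  deg_center <- if (basis == "quadratic") 3L else 1L
  for (g in unique(groups)) {
    fit_i <- which(usable & groups == g)
    if (length(fit_i) < 10) next
    x <- scores$maf[fit_i]
    y <- scores$raw[fit_i]
    # stage 1: remove the location structure, which is odd in the DERIVED
    # frequency (young low-frequency derived alleles ride longer haplotypes)
    # and therefore not expressible as a function of MAF
    dafv <- scores$daf[fit_i]
    Xd <- qr_design(dafv, deg_center)
    c25 <- fit_quantile_poly(dafv, y, 0.25, deg_center)
    c75 <- fit_quantile_poly(dafv, y, 0.75, deg_center)
    y2 <- y - drop(Xd %*% (c25 + c75)) / 2
    # stage 2: the paper's scale step, an IQR fitted as a function of MAF
    b25 <- fit_quantile_poly(x, y2, 0.25, deg)
    b75 <- fit_quantile_poly(x, y2, 0.75, deg)
    Xg <- qr_design(seq(min(x), max(x), length.out = 101), deg)
    iqr_rng <- drop(Xg %*% (b75 - b25))
    if (any(iqr_rng <= 0)) {
      warning("degenerate quantile fit in ", g,
              "; falling back to frequency-bin normalization")
      br <- unique(stats::quantile(x, seq(0, 1, length.out = 11)))
      bin <- cut(x, br, include.lowest = TRUE)
      q25 <- tapply(y2, bin, stats::quantile, 0.25)
      q75 <- tapply(y2, bin, stats::quantile, 0.75)
      mid <- (q25[bin] + q75[bin]) / 2
      iqr <- pmax(q75[bin] - q25[bin], .Machine$double.eps)
      scores$std[fit_i] <- (y2 - mid) / (iqr / config$normal_iqr)
    } else {
      Xo <- qr_design(x, deg)
      q25 <- drop(Xo %*% b25)
      q75 <- drop(Xo %*% b75)
      scores$std[fit_i] <- (y2 - (q25 + q75) / 2) /
        ((q75 - q25) / config$normal_iqr)
    }
  }
  scores
}

#' Call candidate selected regions from standardized iHS scores
#'
#' A region is seeded by a window of `window_bp` around every SNP with
#' `|iHS|` above the threshold; overlapping seed windows are merged, and each
#' region is then extended outward in `window_bp` steps for as long as the
#' next window contains at least one SNP above threshold, merging neighbours
#' as they meet. Retained regions have at least `min_snps_region` scored SNPs
#' of which at least `min_prop_region` are above threshold; ranking is by the
#' maximum `|iHS|`, descending. Only `|iHS|` is used, so calls are invariant
#' to score sign and to translation of all positions.
#'
#' @param scores data.frame from [ihs_scan()] with a `std` column.
#' @param config an [ihs_config()].
#' @return data.frame of regions: `chrom`, `start_bp`, `end_bp`, `size_kb`,
#'   `n_snps`, `n_above`, `prop_above`, `max_abs_ihs`.
#' @export
call_candidate_regions <- function(scores, config = ihs_config()) {
  thr <- config$ihs_threshold
  w <- config$window_bp
  out <- list()
  sc <- scores[is.finite(scores$std), , drop = FALSE]
  for (ch in unique(sc$chrom)) {
    d <- sc[sc$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos_bp), , drop = FALSE]
    hot <- d$pos_bp[abs(d$std) > thr]
    if (length(hot) == 0) next
    start <- hot - w / 2
    end <- hot + w / 2
    merged <- merge_intervals(start, end)
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(merged))) {
        while (any(hot > merged$end[i] & hot <= merged$end[i] + w)) {
          merged$end[i] <- merged$end[i] + w
          changed <- TRUE
        }
        while (any(hot < merged$start[i] & hot >= merged$start[i] - w)) {
          merged$start[i] <- merged$start[i] - w
          changed <- TRUE
        }
      }
      merged <- merge_intervals(merged$start, merged$end)
      if (!changed) break
    }
    for (i in seq_len(nrow(merged))) {
      inreg <- d$pos_bp >= merged$start[i] & d$pos_bp <= merged$end[i]
      n <- sum(inreg)
      na <- sum(abs(d$std[inreg]) > thr)
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_bp = merged$start[i], end_bp = merged$end[i],
        size_kb = (merged$end[i] - merged$start[i]) / 1000,
        n_snps = n, n_above = na, prop_above = na / n,
        max_abs_ihs = max(abs(d$std[inreg])))
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), size_kb = numeric(0),
                      n_snps = integer(0), n_above = integer(0),
                      prop_above = numeric(0), max_abs_ihs = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[res$n_snps >= config$min_snps_region &
               res$prop_above >= config$min_prop_region, , drop = FALSE]
  res[order(-res$max_abs_ihs), , drop = FALSE]
}

merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  os <- numeric(0); oe <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { os <- c(os, ms); oe <- c(oe, me); ms <- start[i]; me <- end[i] }
  }
  data.frame(start = c(os, ms), end = c(oe, me))
}

#' Overlap enrichment between two SNP sets
#'
#' Expected overlap of two subsets of a scored-SNP universe is
#' `nA * nB / M`; significance of the observed overlap is assessed with the
#' hypergeometric upper tail and, optionally, a circular-shift block
#' permutation that preserves the local clustering of hits along the genome
#' (the indicator of set B is rotated by random offsets).
#'
#' @param set_a,set_b vectors of SNP identifiers.
#' @param universe vector of all scored SNP identifiers in genome order, or a
#'   single integer `M` (hypergeometric only).
#' @param method `"hypergeometric"` or `"permutation"`.
#' @param n_shift circular shifts for the permutation null (>= 2000).
#' @param seed RNG seed for the shifts.
#' @return object of class `overlap_stats`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe,
                               method = c("hypergeometric", "permutation"),
                               n_shift = 2000, seed = NULL) {
  method <- match.arg(method)
  if (length(universe) == 1 && is.numeric(universe)) {
    M <- as.integer(universe)
    if (method == "permutation")
      stop("permutation method needs the ordered universe, not just M")
    obs <- length(intersect(set_a, set_b))
  } else {
    M <- length(universe)
    if (!all(set_a %in% universe) || !all(set_b %in% universe))
      stop("sets must be subsets of the scored universe")
    obs <- length(intersect(set_a, set_b))
  }
  na <- length(unique(set_a)); nb <- length(unique(set_b))
  if (M < max(na, nb)) stop("universe smaller than a set")
  expected <- na * nb / M
  if (method == "hypergeometric") {
    p <- stats::phyper(obs - 1, na, M - na, nb, lower.tail = FALSE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    a <- universe %in% set_a
    b <- universe %in% set_b
    shifts <- sample.int(M - 1, n_shift, replace = TRUE)
    ge <- 0L
    for (s in shifts) {
      bs <- c(b[(s + 1):M], b[1:s])
      if (sum(a & bs) >= obs) ge <- ge + 1L
    }
    p <- (1 + ge) / (n_shift + 1)
  }
  structure(list(n_a = na, n_b = nb, observed = obs, M = M,
                 expected = expected, p_value = p, method = method),
            class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf(
    "overlap: %d of sets (%d, %d) in universe %d; expected %.1f; p = %.3g (%s)\n",
    x$observed, x$n_a, x$n_b, x$M, x$expected, x$p_value, x$method))
  invisible(x)
}
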