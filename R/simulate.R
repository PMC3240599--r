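#' Human-like autosomal genetic-map lengths
#'
#' Per-chromosome genetic lengths (cM) for 22 autosomes, proportional to a
#' sex-averaged human map and rescaled to sum exactly to `total_cm`
#' (default 3435 cM, the total autosomal length used by the dating model).
#'
#' @param total_cm total genome length in cM.
#' @return named numeric vector of 22 chromosome lengths.
#' @export
admix_chrom_lengths <- function(total_cm = 3435) {
  raw <- c(270, 257, 218, 202, 197, 186, 178, 161, 157, 169, 154, 165,
           127, 116, 117, 131, 129, 117, 108, 108, 62, 72)
  names(raw) <- paste0("chr", 1:22)
  raw * (total_cm / sum(raw))
}

#' Simulation configuration
#'
#' Collects the parameters of the synthetic-cohort generator: `K`
#' differentiated source populations at a stated FST, `M` markers spread over
#' a multi-chromosome genetic map, hybrid-isolation admixture `T` generations
#' ago with per-individual ancestry proportions from `z_dist`, and a
#' haplotype-copying process whose switch rate `ld_rho` (per cM) controls
#' background LD.
#'
#' @param K number of ancestral (source) populations.
#' @param fst differentiation of each source from the shared ancestral pool
#'   (Balding-Nichols), in (0, 1).
#' @param M marker count.
#' @param n_ind number of admixed diploid individuals.
#' @param T_gen admixing time in generations (>= 1).
#' @param z_dist per-individual proportion of ancestry 1: a scalar (fixed), a
#'   length-`n_ind` vector, or a `function(n)` returning such a vector.
#' @param ld_rho template-switch rate of the haplotype-copying process, per
#'   cM; larger values mean faster LD decay.
#' @param founder_frac fraction of each source panel drawn site-independently
#'   (the founders); the rest are mosaic copies of founders.
#' @param n_source_hap haplotypes per source population.
#' @param chrom_lengths_cm per-chromosome cM lengths (their sum is the genome
#'   length L of the dating model).
#' @param sweep optional [sweep_spec()].
#' @param seed RNG seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(K = 2, fst = 0.15, M = 20000, n_ind = 400, T_gen = 12,
                       z_dist = 0.5, ld_rho = 0.2, founder_frac = 0.25,
                       n_source_hap = 200,
                       chrom_lengths_cm = admix_chrom_lengths(),
                       sweep = NULL, seed = 1L) {
  stopifnot(fst > 0, fst < 1, T_gen >= 1, all(chrom_lengths_cm > 0),
            K >= 1, M >= 2, n_ind >= 1)
  structure(list(K = K, fst = fst, M = M, n_ind = n_ind, T_gen = T_gen,
                 z_dist = z_dist, ld_rho = ld_rho,
                 founder_frac = founder_frac, n_source_hap = n_source_hap,
                 chrom_lengths_cm = chrom_lengths_cm, sweep = sweep,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Selective-sweep specification
#'
#' @param core_marker index of the core SNP.
#' @param carrier_freq fraction of haplotypes carrying the sweep, in (0, 1).
#' @param founder_span_cm length (cM) of the shared founder segment around
#'   the core.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(core_marker, carrier_freq, founder_span_cm) {
  stopifnot(carrier_freq > 0, carrier_freq < 1, founder_span_cm > 0)
  structure(list(core_marker = as.integer(core_marker),
                 carrier_freq = carrier_freq,
                 founder_span_cm = founder_span_cm),
            class = "sweep_spec")
}

#' Lay out a random marker grid along the genome
#'
#' Markers are allocated to chromosomes proportionally to genetic length and
#' placed uniformly at random; physical positions assume 1 cM/Mb.
#'
#' @param M marker count.
#' @param chrom_lengths_cm per-chromosome cM lengths.
#' @param p_anc_range range from which ancestral allele frequencies are drawn
#'   (array-like common variants by default).
#' @return a list with `markers` ([marker_info()] table) and `p_anc`.
#' @export
simulate_marker_grid <- function(M, chrom_lengths_cm = admix_chrom_lengths(),
                                 p_anc_range = c(0.05, 0.95)) {
  n_chr <- length(chrom_lengths_cm)
  alloc <- pmax(2L, round(M * chrom_lengths_cm / sum(chrom_lengths_cm)))
  # adjust to exactly M
  while (sum(alloc) != M) {
    i <- if (sum(alloc) > M) which.max(alloc) else which.min(alloc)
    alloc[i] <- alloc[i] + sign(M - sum(alloc))
  }
  chrom <- character(0); cm <- numeric(0)
  nm <- if (is.null(names(chrom_lengths_cm))) paste0("chr", seq_len(n_chr))
        else names(chrom_lengths_cm)
  for (c_i in seq_len(n_chr)) {
    cm_i <- sort(stats::runif(alloc[c_i], 0, chrom_lengths_cm[c_i]))
    chrom <- c(chrom, rep(nm[c_i], alloc[c_i]))
    cm <- c(cm, cm_i)
  }
  bp <- as.integer(round(cm * 1e6)) + 1L
  # enforce strictly increasing bp within chromosome
  for (c_i in nm) {
    i <- which(chrom == c_i)
    b <- bp[i]
    for (j in seq_along(b)[-1]) if (b[j] <= b[j - 1]) b[j] <- b[j - 1] + 1L
    bp[i] <- b
  }
  mk <- marker_info(chrom = chrom, pos_bp = bp, pos_cm = cm)
  list(markers = mk,
       p_anc = stats::runif(M, p_anc_range[1], p_anc_range[2]))
}

#' Draw differentiated population allele frequencies (Balding-Nichols)
#'
#' Each population's frequency at each marker is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral frequency `p`, so that
#' `Var(freq) = F p (1 - p)`, then clipped to `[0.01, 0.99]`.
#'
#' @param p_anc ancestral frequency per marker, strictly inside (0, 1).
#' @param fst differentiation parameter F, in (0, 1).
#' @param K number of populations.
#' @param seed optional RNG seed.
#' @return `K x M` matrix of per-population allele frequencies.
#' @export
draw_population_freqs <- function(p_anc, fst, K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (fst <= 0 || fst >= 1) stop("fst must lie strictly in (0, 1)")
  if (any(p_anc <= 0 | p_anc >= 1))
    stop("p_anc must lie strictly in (0, 1)")
  M <- length(p_anc)
  c0 <- (1 - fst) / fst
  f <- matrix(stats::rbeta(K * M, rep(c0 * p_anc, each = K),
                           rep(c0 * (1 - p_anc), each = K)),
              nrow = K, ncol = M)
  pmin(pmax(f, 0.01), 0.99)
}

#' Simulate source-population haplotypes with LD
#'
#' A fraction of haplotypes (the founders) is drawn site-independently from
#' the population frequencies; the remainder are mosaics that copy a random
#' founder and switch template between adjacent markers with probability
#' `1 - exp(-ld_rho * d_cM)`, producing haplotype sharing that decays with
#' genetic distance. Template choice restarts at each chromosome.
#'
#' @param freqs frequency vector (length M) for one population, or a `K x M`
#'   matrix for several.
#' @param n_hap haplotypes per population.
#' @param markers marker metadata ([marker_info()]).
#' @param ld_rho template-switch rate per cM (`Inf` = no LD).
#' @param founder_frac fraction of haplotypes that are founders.
#' @param seed optional RNG seed.
#' @param sample_prefix prefix for generated sample ids.
#' @return a [haplotype_panel()] (or a list of them if `freqs` is a matrix).
#' @export
simulate_source_haplotypes <- function(freqs, n_hap, markers, ld_rho = 0.2,
                                       founder_frac = 0.25, seed = NULL,
                                       sample_prefix = "src") {
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(freqs) && nrow(freqs) > 1) {
    return(lapply(seq_len(nrow(freqs)), function(k)
      simulate_source_haplotypes(freqs[k, ], n_hap, markers, ld_rho,
                                 founder_frac, seed = NULL,
                                 sample_prefix = paste0(sample_prefix, k))))
  }
  freqs <- as.numeric(freqs)
  M <- length(freqs)
  stopifnot(M == nrow(markers), n_hap %% 2 == 0)
  n_found <- max(1L, min(n_hap, ceiling(founder_frac * n_hap)))
  founders <- matrix(stats::rbinom(n_found * M, 1L, rep(freqs, each = n_found)),
                     nrow = n_found)
  n_copy <- n_hap - n_found
  alle <- matrix(0L, nrow = n_hap, ncol = M)
  alle[seq_len(n_found), ] <- founders
  if (n_copy > 0) {
    d_cm <- c(Inf, diff(markers$pos_cm))
    d_cm[c(TRUE, markers$chrom[-1] != markers$chrom[-M])] <- Inf
    p_sw <- ifelse(is.finite(d_cm), -expm1(-ld_rho * pmax(d_cm, 0)), 1)
    if (is.infinite(ld_rho)) p_sw[] <- 1
    templ <- sample.int(n_found, n_copy, replace = TRUE)
    cp <- matrix(0L, nrow = n_copy, ncol = M)
    for (m in seq_len(M)) {
      if (p_sw[m] >= 1) {
        templ <- sample.int(n_found, n_copy, replace = TRUE)
      } else if (p_sw[m] > 0) {
        sw <- stats::runif(n_copy) < p_sw[m]
        if (any(sw)) templ[sw] <- sample.int(n_found, sum(sw), replace = TRUE)
      }
      cp[, m] <- founders[templ + (m - 1L) * n_found]
    }
    alle[(n_found + 1L):n_hap, ] <- cp
  }
  haplotype_panel(alle, markers,
                  sample_ids = paste0(sample_prefix, "_", seq_len(n_hap / 2)))
}

# Poisson ancestry-switch process for one haplotype: returns per-marker
# ancestry labels and the segment list (needed for segment-coherent copying).
sim_hap_ancestry <- function(markers, q, T_gen) {
  M <- nrow(markers)
  lab <- integer(M)
  seg_id <- integer(M)
  seg_anc <- integer(0)
  n_seg <- 0L
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    cm0 <- markers$pos_cm[idx[1]]
    len <- markers$pos_cm[idx[length(idx)]] - cm0
    n_sw <- stats::rpois(1, (T_gen / 100) * len)
    bks <- sort(stats::runif(n_sw, 0, len)) + cm0
    anc <- sample.int(length(q), n_sw + 1L, replace = TRUE, prob = q)
    seg_of <- findInterval(markers$pos_cm[idx], bks) + 1L
    lab[idx] <- anc[seg_of]
    seg_id[idx] <- n_seg + seg_of
    seg_anc <- c(seg_anc, anc)
    n_seg <- n_seg + n_sw + 1L
  }
  list(labels = lab, seg_id = seg_id, seg_anc = seg_anc)
}

#' Simulate an admixed cohort under the hybrid-isolation model
#'
#' Per haplotype, ancestry switch points are laid down as a Poisson process at
#' rate `T` per Morgan; the ancestry of each segment is drawn independently
#' from the individual's proportion vector (so a fraction `2 z (1 - z)` of
#' switch points changes ancestry, matching the diploid expectation
#' `0.04 T L z (1 - z)` for the number of ancestry switches). Alleles within
#' each ancestry segment are copied from a single random source haplotype of
#' that ancestry (segment-coherent copying).
#'
#' @param config a [sim_config()].
#' @param sources list of length `K`; element `k` is a [haplotype_panel()] for
#'   ancestry `k`, or a list of alternative panels (subpopulations) for that
#'   ancestry.
#' @param markers marker metadata shared by all source panels.
#' @param source_assignment optional `n_ind x K` integer matrix choosing which
#'   subpopulation panel supplies each individual's ancestry-`k` segments
#'   (default 1).
#' @param q optional `n_ind x K` matrix of individual ancestry proportions;
#'   built from `config$z_dist` when `NULL` (column 1 gets `z`, the remainder
#'   is split evenly).
#' @param seed optional RNG seed (default `config$seed`).
#' @return list with `panel` (the admixed [haplotype_panel()]), `track` (the
#'   ground-truth [ancestry_track()]), and `z` (realized `q` matrix).
#' @export
simulate_admixed_cohort <- function(config, sources, markers,
                                    source_assignment = NULL, q = NULL,
                                    seed = config$seed) {
  set.seed(seed)
  K <- config$K
  N <- config$n_ind
  stopifnot(length(sources) == K)
  sources <- lapply(sources, function(s)
    if (inherits(s, "haplotype_panel")) list(s) else s)
  if (is.null(source_assignment))
    source_assignment <- matrix(1L, N, K)
  if (is.null(q)) {
    z <- config$z_dist
    if (is.function(z)) z <- z(N)
    z <- rep_len(z, N)
    q <- cbind(z, matrix(rep((1 - z) / (K - 1), K - 1), ncol = max(K - 1, 1)))
    if (K == 1) q <- matrix(1, N, 1)
  }
  stopifnot(nrow(q) == N, ncol(q) == K, max(abs(rowSums(q) - 1)) < 1e-8)
  M <- config$M
  stopifnot(nrow(markers) == M)
  alle <- matrix(0L, nrow = 2L * N, ncol = M)
  lab <- matrix(0L, nrow = 2L * N, ncol = M)
  for (n in seq_len(N)) {
    for (h in 1:2) {
      row <- 2L * (n - 1L) + h
      sim <- sim_hap_ancestry(markers, q[n, ], config$T_gen)
      lab[row, ] <- sim$labels
      donors <- integer(length(sim$seg_anc))
      for (s in seq_along(sim$seg_anc)) {
        src <- sources[[sim$seg_anc[s]]][[source_assignment[n, sim$seg_anc[s]]]]
        donors[s] <- sample.int(nrow(src$alleles), 1)
      }
      for (s in unique(sim$seg_id)) {
        a <- sim$seg_anc[s]
        src <- sources[[a]][[source_assignment[n, a]]]
        cols <- which(sim$seg_id == s)
        alle[row, cols] <- src$alleles[donors[s], cols]
      }
    }
  }
  panel <- haplotype_panel(alle, markers,
                           sample_ids = paste0("adm", seq_len(N)))
  track <- ancestry_track(lab, ancestry_names = paste0("anc", seq_len(K)))
  list(panel = panel, track = track, z = q)
}

#' Simulate ancestry tracks only (no alleles)
#'
#' The Poisson switch process of [simulate_admixed_cohort()] without the
#' allele-copying step: cheap ground-truth tracks for block-count and dating
#' studies, where only the ancestry mosaic matters.
#'
#' @param markers marker metadata ([marker_info()]).
#' @param q `n_ind x K` matrix of individual ancestry proportions.
#' @param T_gen admixing time in generations.
#' @param seed optional RNG seed.
#' @return an [ancestry_track()] over `2 n_ind` haplotypes.
#' @export
simulate_ancestry_tracks <- function(markers, q, T_gen, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- as.matrix(q)
  N <- nrow(q)
  lab <- matrix(0L, 2L * N, nrow(markers))
  for (n in seq_len(N)) for (h in 1:2)
    lab[2L * (n - 1L) + h, ] <- sim_hap_ancestry(markers, q[n, ], T_gen)$labels
  ancestry_track(lab, paste0("anc", seq_len(ncol(q))))
}

#' Inject a founder-copy selective sweep
#'
#' A fraction `carrier_freq` of haplotypes has the interval
#' `[core - span/2, core + span/2]` (cM) replaced by one founder haplotype's
#' alleles, with the carried extent truncated per haplotype and per side at an
#' exponentially drawn distance with mean `founder_span_cm` (floored at
#' 0.1 cM so every carrier carries the core allele, capped at the half-span),
#' so most carriers share the full span and haplotype homozygosity decays
#' away from the core. The founder's core allele is forced to 1 (the derived
#' allele).
#'
#' @param panel a [haplotype_panel()].
#' @param spec a [sweep_spec()].
#' @param seed optional RNG seed.
#' @return the panel with sweep alleles written in; attributes `carriers`
#'   (haplotype rows) and `core` record the construction.
#' @export
inject_sweep <- function(panel, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(spec) || spec$carrier_freq == 0) return(panel)
  mk <- panel$markers
  core <- spec$core_marker
  stopifnot(core >= 1, core <= nrow(mk))
  ch <- mk$chrom[core]
  on_ch <- which(mk$chrom == ch)
  H <- nrow(panel$alleles)
  n_car <- round(spec$carrier_freq * H)
  carriers <- sample.int(H, n_car)
  founder <- panel$alleles[carriers[1], ]
  founder[core] <- 1L
  half <- spec$founder_span_cm / 2
  cm <- mk$pos_cm
  for (hh in carriers) {
    d_l <- min(half, max(0.1, stats::rexp(1, rate = 1 / spec$founder_span_cm)))
    d_r <- min(half, max(0.1, stats::rexp(1, rate = 1 / spec$founder_span_cm)))
    cols <- on_ch[cm[on_ch] >= cm[core] - d_l & cm[on_ch] <= cm[core] + d_r]
    panel$alleles[hh, cols] <- founder[cols]
  }
  attr(panel, "carriers") <- sort(carriers)
  attr(panel, "core") <- core
  panel
}

#' Corrupt ancestry labels segment-wise
#'
#' Each maximal constant-ancestry segment is independently relabeled with
#' probability `epsilon`: for `K = 2` the label is flipped; for `K > 2` it is
#' switched to a uniformly random other ancestry. Models segment-level errors
#' of the local-ancestry step.
#'
#' @param track an [ancestry_track()] (posteriors, if any, are dropped).
#' @param epsilon per-segment switch probability in `[0, 1]`.
#' @param markers optional marker table; when given, segments do not span
#'   chromosome boundaries.
#' @param seed optional RNG seed.
#' @return the corrupted [ancestry_track()]; attribute `n_flipped` counts
#'   relabeled segments.
#' @export
corrupt_ancestry_labels <- function(track, epsilon, markers = NULL,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(epsilon >= 0, epsilon <= 1)
  lab <- track$labels
  K <- track$K
  chrom <- if (is.null(markers)) rep("g", ncol(lab)) else markers$chrom
  chr_break <- c(TRUE, chrom[-1] != chrom[-length(chrom)])
  n_flip <- 0L
  for (h in seq_len(nrow(lab))) {
    x <- lab[h, ]
    new_seg <- chr_break | c(TRUE, x[-1] != x[-length(x)])
    seg_of <- cumsum(new_seg)
    n_seg <- seg_of[length(seg_of)]
    flip <- stats::runif(n_seg) < epsilon
    n_flip <- n_flip + sum(flip)
    if (any(flip)) {
      hit <- flip[seg_of]
      if (K == 2) {
        x[hit] <- 3L - x[hit]
      } else {
        for (s in which(flip)) {
          i <- seg_of == s
          x[i] <- sample(setdiff(seq_len(K), x[which(i)[1]]), 1)
        }
      }
      lab[h, ] <- x
    }
  }
  out <- ancestry_track(lab, track$ancestry_names)
  attr(out, "n_flipped") <- n_flip
  out
}

#' Two-subpopulation substructure study generator
#'
#' The package's standing test harness for the subspace-PCA stage: two source
#' populations subtly differentiated within one continent (FST
#' `fst_within`), both strongly differentiated (FST `fst_between`) from a
#' second continental source; admixed individuals draw a fixed proportion `z`
#' of their genome from their assigned within-continent source and the rest
#' from the other continent. Masking to the target continent with the true
#' labels yields virtual genomes whose leading PC should separate the two
#' subpopulations.
#'
#' @param n_ind admixed individuals (half assigned to each subpopulation).
#' @param M marker count.
#' @param n_source_hap haplotypes per source panel.
#' @param fst_within within-continent FST between the two subpopulations.
#' @param fst_between continental FST.
#' @param T_gen admixing time in generations.
#' @param z target-continent ancestry proportion per individual.
#' @param ld_rho haplotype-copying switch rate per cM.
#' @param seed RNG seed.
#' @return list with `panel`, `track` (true labels), `subpop` (factor of the
#'   within-continent source per individual), `markers`, `z`.
#' @export
simulate_substructure_study <- function(n_ind = 400, M = 20000,
                                        n_source_hap = 200,
                                        fst_within = 0.01, fst_between = 0.15,
                                        T_gen = 12, z = 0.5, ld_rho = 0.5,
                                        founder_frac = 0.25, seed = 1L) {
  set.seed(seed)
  grid <- simulate_marker_grid(M)
  mk <- grid$markers
  cont <- draw_population_freqs(grid$p_anc, fst_between, K = 2)
  subs <- draw_population_freqs(cont[1, ], fst_within, K = 2)
  src_a <- simulate_source_haplotypes(subs[1, ], n_source_hap, mk, ld_rho,
                                      founder_frac, sample_prefix = "subA")
  src_b <- simulate_source_haplotypes(subs[2, ], n_source_hap, mk, ld_rho,
                                      founder_frac, sample_prefix = "subB")
  src_amr <- simulate_source_haplotypes(cont[2, ], n_source_hap, mk, ld_rho,
                                        founder_frac, sample_prefix = "amr")
  cfg <- sim_config(K = 2, fst = fst_between, M = M, n_ind = n_ind,
                    T_gen = T_gen, z_dist = z, ld_rho = ld_rho, seed = seed)
  subpop <- rep(1:2, length.out = n_ind)
  assign <- cbind(subpop, 1L)
  sim <- simulate_admixed_cohort(cfg, list(list(src_a, src_b), src_amr), mk,
                                 source_assignment = assign,
                                 seed = seed + 1000L)
  list(panel = sim$panel, track = sim$track,
       subpop = factor(c("A", "B")[subpop]), markers = mk, z = sim$z)
}
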