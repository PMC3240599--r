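#' Mask a panel to one ancestry's virtual genomes
#'
#' Builds the two `N x M` per-allele matrices `G1`, `G2` (the unordered pair
#' of alleles per individual per SNP) in which an entry is observed only where
#' the corresponding haplotype's ancestry call equals the target ancestry
#' (and, when posteriors are available, the posterior of the call is at least
#' `posterior_threshold`); all other entries are set to missing.
#'
#' @param panel a [haplotype_panel()].
#' @param track an aligned [ancestry_track()].
#' @param target ancestry name (in `track$ancestry_names`) or index.
#' @param posterior_threshold minimum posterior for a call to be retained
#'   (default 0.9); ignored when the track has no posteriors.
#' @return an object of class `masked_pair`: `G1`, `G2` (numeric, `NA` =
#'   masked), `target_ancestry`, `obs_frac` per individual, `markers`,
#'   `sample_ids`.
#' @export
mask_to_virtual <- function(panel, track, target, posterior_threshold = 0.9) {
  if (is.character(target)) {
    k <- match(target, track$ancestry_names)
    if (is.na(k)) stop("target '", target, "' not among ancestries: ",
                       paste(track$ancestry_names, collapse = ", "))
  } else k <- as.integer(target)
  if (!identical(dim(track$labels), dim(panel$alleles)))
    stop("track not aligned to panel")
  H <- n_hap(panel)
  keep <- !is.na(track$labels) & track$labels == k
  if (!is.null(track$posteriors))
    keep <- keep & (track$posteriors[, , k] >= posterior_threshold)
  x <- panel$alleles
  storage.mode(x) <- "double"
  x[!keep] <- NA_real_
  odd <- seq(1, H, 2)
  G1 <- x[odd, , drop = FALSE]
  G2 <- x[odd + 1L, , drop = FALSE]
  rownames(G1) <- rownames(G2) <- panel$sample_ids
  obs <- (rowMeans(!is.na(G1)) + rowMeans(!is.na(G2))) / 2
  structure(list(G1 = G1, G2 = G2,
                 target_ancestry = track$ancestry_names[k],
                 obs_frac = obs, markers = panel$markers,
                 sample_ids = panel$sample_ids),
            class = "masked_pair")
}

#' @export
print.masked_pair <- function(x, ...) {
  cat("masked_pair: ancestry", x$target_ancestry, ",", nrow(x$G1),
      "individuals x", ncol(x$G1), "markers\n")
  cat(sprintf("  observed fraction per individual: median %.2f (range %.2f-%.2f)\n",
              stats::median(x$obs_frac), min(x$obs_frac), max(x$obs_frac)))
  invisible(x)
}

# merge runs shorter than min_snps into their left flank (right flank for a
# leftmost run); a chromosome consisting of a single run is kept regardless.
merge_short_runs <- function(len, val, min_snps) {
  repeat {
    if (length(len) <= 1L) break
    i <- which(len < min_snps)
    if (length(i) == 0) break
    i <- i[1]
    if (i == 1L) {
      len[2] <- len[2] + len[1]
      len <- len[-1]; val <- val[-1]
    } else {
      len[i - 1] <- len[i - 1] + len[i]
      len <- len[-i]; val <- val[-i]
    }
    # collapse now-adjacent runs of equal ancestry
    j <- which(val[-1] == val[-length(val)])
    while (length(j)) {
      j1 <- j[1]
      len[j1] <- len[j1] + len[j1 + 1]
      len <- len[-(j1 + 1)]; val <- val[-(j1 + 1)]
      j <- which(val[-1] == val[-length(val)])
    }
  }
  list(lengths = len, values = val)
}

#' Extract ancestry blocks and diploid block counts
#'
#' Decomposes each haplotype of each chromosome into maximal constant-ancestry
#' runs, removes extremely short blocks (fewer than `min_snps` SNPs, which are
#' typically artifacts of local-ancestry error) by absorbing their span into
#' the flanking block, and tallies the diploid block count per individual
#' (both haplotypes, all chromosomes). A genome with no ancestry switch has
#' one block per chromosome per haplotype.
#'
#' @param track an [ancestry_track()] with complete labels.
#' @param markers aligned marker table.
#' @param min_snps short-block threshold (default 10; 1 = plain run-length
#'   encoding).
#' @return list with `blocks` (data.frame: haplotype, individual, chrom,
#'   start/end marker indices, ancestry, n_snps, length_cm, start/end bp) and
#'   `diploid_counts` (per-individual block count).
#' @export
extract_blocks <- function(track, markers, min_snps = 10) {
  lab <- track$labels
  if (anyNA(lab)) stop("extract_blocks requires complete labels (no NA)")
  H <- nrow(lab)
  out <- vector("list", H)
  chroms <- unique(markers$chrom)
  idx_by_chr <- lapply(chroms, function(ch) which(markers$chrom == ch))
  for (h in seq_len(H)) {
    per_chr <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      idx <- idx_by_chr[[ci]]
      r <- rle(lab[h, idx])
      m <- merge_short_runs(r$lengths, r$values, min_snps)
      ends <- cumsum(m$lengths)
      starts <- ends - m$lengths + 1L
      per_chr[[ci]] <- data.frame(
        haplotype = h, individual = ceiling(h / 2), chrom = chroms[ci],
        start_idx = idx[starts], end_idx = idx[ends],
        ancestry = track$ancestry_names[m$values],
        n_snps = m$lengths,
        length_cm = markers$pos_cm[idx[ends]] - markers$pos_cm[idx[starts]],
        start_bp = markers$pos_bp[idx[starts]],
        end_bp = markers$pos_bp[idx[ends]])
    }
    out[[h]] <- do.call(rbind, per_chr)
  }
  blocks <- do.call(rbind, out)
  counts <- tabulate(blocks$individual, nbins = H / 2)
  list(blocks = blocks, diploid_counts = counts)
}

#' Select individuals by global ancestry proportion
#'
#' Individuals whose target-ancestry proportion falls below `min_prop` carry
#' too few informative segments for substructure analysis and are excluded;
#' the comparison is inclusive (proportion >= `min_prop` is retained).
#'
#' @param global_ancestry `N x K` matrix, rows summing to 1.
#' @param target ancestry column name or index.
#' @param min_prop inclusion threshold (default 0.25).
#' @return integer vector of retained individual indices.
#' @export
select_individuals <- function(global_ancestry, target, min_prop = 0.25) {
  if (max(abs(rowSums(global_ancestry) - 1)) > 1e-6)
    stop("global ancestry rows must sum to 1")
  p <- global_ancestry[, target]
  keep <- which(p >= min_prop)
  if (length(keep) == 0)
    warning("no individuals reach the ", min_prop, " ancestry threshold")
  keep
}
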