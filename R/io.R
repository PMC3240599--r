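provenance_line <- function(prefix = "#", seed = NULL) {
  ver <- as.character(utils::packageVersion("admixkit"))
  paste0(prefix, " admixkit v", ver,
         if (!is.null(seed)) paste0(" seed=", seed) else "")
}

#' Read a phased VCF into a haplotype panel
#'
#' Accepts biallelic SNPs with fully phased `GT` fields only; the panel must
#' be complete (no missing genotypes), because missingness is introduced
#' downstream by ancestry masking, never at input.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @return a [haplotype_panel()]. Haplotype rows are ordered
#'   `(sample1_hapA, sample1_hapB, sample2_hapA, ...)`.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))              # single-record VCFs collapse to a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | fix[, "ALT"] == "." | is.na(fix[, "ALT"])
  if (any(multi))
    stop("multiallelic or ALT-less record(s) at: ",
         paste(utils::head(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]), 5),
               collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  bad <- which(is.na(gt) | !grepl("^[01]\\|[01]$", gt), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    r <- bad[1, 1]; cc <- bad[1, 2]
    stop("unphased or missing GT '", gt[r, cc], "' at record ",
         fix[r, "CHROM"], ":", fix[r, "POS"], " sample ", colnames(gt)[cc])
  }
  nind <- ncol(gt)
  m <- nrow(gt)
  alle <- matrix(0L, nrow = 2L * nind, ncol = m)
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  for (j in seq_len(nind)) {
    alle[2L * j - 1L, ] <- as.integer(a1[, j])
    alle[2L * j, ] <- as.integer(a2[, j])
  }
  mk <- marker_info(chrom = fix[, "CHROM"],
                    pos_bp = as.integer(fix[, "POS"]),
                    pos_cm = NA_real_,
                    ref_allele = fix[, "REF"], alt_allele = fix[, "ALT"],
                    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                paste0(fix[, "CHROM"], "_", fix[, "POS"]),
                                fix[, "ID"]))
  haplotype_panel(alle, mk, sample_ids = colnames(gt))
}

#' Write a haplotype panel as a phased VCF
#'
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @param seed optional seed recorded in the provenance header line.
#' @export
write_phased_vcf <- function(panel, path, seed = NULL) {
  mk <- panel$markers
  nind <- n_ind(panel)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##", sub("^# ?", "", provenance_line("#", seed))),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$sample_ids), collapse = "\t"))
  gtcols <- vapply(seq_len(nind), function(j)
    paste0(panel$alleles[2L * j - 1L, ], "|", panel$alleles[2L * j, ]),
    character(n_mark(panel)))
  if (is.null(dim(gtcols))) gtcols <- matrix(gtcols, nrow = n_mark(panel))
  body <- cbind(mk$chrom, mk$pos_bp, mk$id, mk$ref_allele, mk$alt_allele,
                ".", "PASS", ".", "GT", gtcols)
  writeLines(c(hdr, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a haplotype TSV
#'
#' Simple dialect for hand-written fixtures: optional leading `#` comments, a
#' header row of marker IDs, then one row per haplotype of tab-separated 0/1
#' alleles, first column the haplotype name `<sample>_<1|2>`.
#'
#' @param path path to the TSV.
#' @param markers marker metadata ([marker_info()]); marker count must match.
#' @return a [haplotype_panel()].
#' @export
read_haplotype_tsv <- function(path, markers) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         check.names = FALSE, stringsAsFactors = FALSE)
  ids <- d[[1]]
  alle <- as.matrix(d[, -1, drop = FALSE])
  dimnames(alle) <- NULL
  samp <- unique(sub("_[12]$", "", ids))
  haplotype_panel(alle, markers, sample_ids = samp)
}

#' Write a haplotype TSV
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @param seed optional seed recorded in the provenance comment.
#' @export
write_haplotype_tsv <- function(panel, path, seed = NULL) {
  hapnames <- paste0(rep(panel$sample_ids, each = 2), "_", c(1L, 2L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line("#", seed), con)
  writeLines(paste(c("haplotype", panel$markers$id), collapse = "\t"), con)
  utils::write.table(cbind(hapnames, panel$alleles), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Interpolate genetic-map positions onto a panel
#'
#' Fills `pos_cm` for every marker by linear interpolation between map points
#' (in bp), with constant extrapolation beyond the map ends.
#'
#' @param path a 3-column whitespace/tab-separated file `(chrom, bp, cM)`,
#'   sorted by position within chromosome; `#` comments allowed.
#' @param panel a [haplotype_panel()] whose markers get `pos_cm` filled.
#' @return the panel with `markers$pos_cm` populated.
#' @export
read_genetic_map <- function(path, panel) {
  mp <- utils::read.table(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  names(mp)[1:3] <- c("chrom", "bp", "cm")
  mp$chrom <- as.character(mp$chrom)
  mk <- panel$markers
  out <- numeric(nrow(mk))
  for (ch in unique(mk$chrom)) {
    sub <- mp[mp$chrom == ch, ]
    if (nrow(sub) == 0)
      stop("chromosome ", ch, " absent from genetic map ", path)
    i <- mk$chrom == ch
    if (nrow(sub) == 1) {
      out[i] <- sub$cm
    } else {
      out[i] <- stats::approx(sub$bp, sub$cm, xout = mk$pos_bp[i],
                              rule = 2, ties = "ordered")$y
    }
  }
  panel$markers$pos_cm <- out
  validate_markers(panel$markers)
  panel
}

#' Write ancestry blocks as BED
#'
#' One record per maximal constant-ancestry run per haplotype, 0-based
#' half-open coordinates. A block spans from its first member marker's bp to
#' its last member marker's bp (no midpoint extension), so records per
#' haplotype tile the marker span exactly.
#'
#' @param track an [ancestry_track()] with labels.
#' @param panel the aligned [haplotype_panel()].
#' @param path output path.
#' @param seed optional seed recorded in the provenance comment.
#' @export
write_ancestry_bed <- function(track, panel, path, seed = NULL) {
  mk <- panel$markers
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line("#", seed), con)
  writeLines("#chrom\tstart\tend\tname", con)
  lab <- track$labels
  hapnames <- paste0(rep(panel$sample_ids, each = 2), "_", c(1L, 2L))
  for (h in seq_len(nrow(lab))) {
    for (ch in unique(mk$chrom)) {
      idx <- which(mk$chrom == ch)
      r <- rle(lab[h, idx])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- !is.na(r$values)
      if (!any(keep)) next
      bed <- data.frame(
        chrom = ch,
        start = mk$pos_bp[idx[starts[keep]]] - 1L,
        end = mk$pos_bp[idx[ends[keep]]],
        name = paste0(hapnames[h], "_",
                      track$ancestry_names[r$values[keep]]))
      utils::write.table(bed, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Standardize matrix columns ignoring missing entries
#'
#' Centers and scales each column to mean 0 and sample variance 1 (n - 1
#' denominator) over its observed entries, the preprocessing contract of the
#' subspace PCA. Columns with fewer than 2 observed entries or zero observed
#' variance are flagged and excluded from downstream fitting rather than
#' imputed.
#'
#' @param x numeric matrix `N x M`, `NA` = missing.
#' @param center,scale optional per-column statistics to apply (projection of
#'   new rows through a fitted model); computed from `x` when `NULL`.
#' @return list with `x` (standardized, flagged columns untouched), `center`,
#'   `scale`, `keep` (logical, retained columns), `n_obs` per column.
#' @export
standardize_columns <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  n_obs <- colSums(!is.na(x))
  if (is.null(center)) center <- colMeans(x, na.rm = TRUE)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd, na.rm = TRUE)
  }
  keep <- n_obs >= 2L & !is.na(scale) & scale > 0
  xs <- x
  xs[, keep] <- sweep(sweep(x[, keep, drop = FALSE], 2, center[keep], "-"),
                      2, scale[keep], "/")
  list(x = xs, center = center, scale = scale, keep = keep, n_obs = n_obs)
}
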