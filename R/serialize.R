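write_tsv_prov <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line("#", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_prov <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Serialize a masked per-allele matrix pair
#'
#' Writes the observed entries of `G1`/`G2` as sparse matrix-market-style
#' triplets `(allele_matrix, individual, marker, value)` together with sample
#' and marker sidecar TSVs, under a common path prefix.
#'
#' @param pair a `masked_pair` from [mask_to_virtual()].
#' @param prefix output path prefix; files `<prefix>.mtx.tsv`,
#'   `<prefix>.samples.tsv`, `<prefix>.markers.tsv` are created.
#' @param seed optional seed recorded in provenance comments.
#' @return the prefix, invisibly.
#' @export
write_masked_pair <- function(pair, prefix, seed = NULL) {
  tri <- function(g, h) {
    w <- which(!is.na(g), arr.ind = TRUE)
    data.frame(allele_matrix = h, individual = w[, 1], marker = w[, 2],
               value = g[w])
  }
  trips <- rbind(tri(pair$G1, 1L), tri(pair$G2, 2L))
  attr(trips, "dims") <- dim(pair$G1)
  con <- file(paste0(prefix, ".mtx.tsv"), "w")
  writeLines(provenance_line("#", seed), con)
  writeLines(paste0("# dims\t", nrow(pair$G1), "\t", ncol(pair$G1),
                    "\ttarget\t", pair$target_ancestry), con)
  utils::write.table(trips, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  write_tsv_prov(data.frame(sample = pair$sample_ids,
                            obs_frac = pair$obs_frac),
                 paste0(prefix, ".samples.tsv"), seed)
  write_tsv_prov(pair$markers, paste0(prefix, ".markers.tsv"), seed)
  invisible(prefix)
}

#' Read a masked pair written by [write_masked_pair()]
#' @param prefix the path prefix used when writing.
#' @return a `masked_pair`.
#' @export
read_masked_pair <- function(prefix) {
  lines <- readLines(paste0(prefix, ".mtx.tsv"), n = 5)
  dl <- strsplit(lines[grepl("^# dims", lines)][1], "\t")[[1]]
  N <- as.integer(dl[2]); M <- as.integer(dl[3]); target <- dl[5]
  trips <- read_tsv_prov(paste0(prefix, ".mtx.tsv"))
  samples <- read_tsv_prov(paste0(prefix, ".samples.tsv"))
  markers <- read_tsv_prov(paste0(prefix, ".markers.tsv"))
  G1 <- matrix(NA_real_, N, M)
  G2 <- matrix(NA_real_, N, M)
  i1 <- trips$allele_matrix == 1
  G1[cbind(trips$individual[i1], trips$marker[i1])] <- trips$value[i1]
  G2[cbind(trips$individual[!i1], trips$marker[!i1])] <- trips$value[!i1]
  rownames(G1) <- rownames(G2) <- samples$sample
  structure(list(G1 = G1, G2 = G2, target_ancestry = target,
                 obs_frac = samples$obs_frac, markers = markers,
                 sample_ids = samples$sample),
            class = "masked_pair")
}
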