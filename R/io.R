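## Plain-text writers/readers for the standard interchange formats used by
## the pipeline: VCF (GT + DS) for genotypes, BED for peaks, TSV for
## phenotype matrices, gene tables, QTL results and truth tables.

#' Write simulated dosages as a minimal VCF (GT and DS fields)
#'
#' Dosages 0/1/2 map to genotypes 0/0, 0/1, 1/1; the DS field carries the
#' numeric dosage. Coordinates are converted from the internal 0-based
#' convention to the 1-based POS column on write.
#'
#' @param genotypes Samples x variants dosage matrix with a `"variants"`
#'   attribute or an explicit `variants` table (`id`, `chrom`, `pos`).
#' @param path Output path.
#' @param variants Optional variant table overriding the attribute.
#' @return `path` invisibly.
#' @export
write_vcf <- function(genotypes, path, variants = NULL) {
  variants <- variants %||% attr(genotypes, "variants")
  if (is.null(variants)) qtlmed_stop("variant table required to write VCF")
  samples <- rownames(genotypes) %||% paste0("S", seq_len(nrow(genotypes)))
  gt_map <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(j) {
    g <- genotypes[, j]
    cells <- paste0(gt_map[g + 1L], ":", g)
    paste(c(variants$chrom[j], variants$pos[j] + 1L, variants$id[j],
            "A", "G", ".", "PASS", ".", "GT:DS", cells), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write peaks as BED (0-based half-open, native convention)
#' @param peaks data.frame `peak_id`, `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_bed <- function(peaks, path) {
  utils::write.table(peaks[, c("chrom", "start", "end", "peak_id")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data.frame or matrix as TSV
#' @param x Object to write (matrices keep their row names in a leading
#'   `id` column).
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_tsv <- function(x, path) {
  if (is.matrix(x)) {
    x <- data.frame(id = rownames(x) %||% seq_len(nrow(x)), x,
                    check.names = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path File path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
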