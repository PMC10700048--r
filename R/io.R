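# plain-text interchange: delimited genotype table + group table, and
# minimal biallelic VCF (each locus its own contig-less record)

#' Write / read a delimited genotype table
#'
#' The genotype table is tab-delimited, individuals in rows (first column
#' `id`), loci in columns, codes 0/1/2/NA.  The group table is a
#' two-column `id`/`group` file.
#'
#' @param g A [genotype_matrix()].
#' @param path,group_path File paths.
#' @return `read_geno_table()` returns a `geno_matrix`.
#' @export
write_geno_table <- function(g, path, group_path) {
  df <- data.frame(id = rownames(g$geno), g$geno, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  gdf <- data.frame(id = rownames(g$geno), group = as.character(g$groups))
  utils::write.table(gdf, group_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_geno_table
#' @export
read_geno_table <- function(path, group_path) {
  df <- utils::read.delim(path, check.names = FALSE)
  gdf <- utils::read.delim(group_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  grp <- gdf$group[match(df$id, gdf$id)]
  genotype_matrix(m, factor(grp, levels = unique(grp)))
}

#' Write a genotype matrix as a minimal biallelic VCF
#'
#' Unphased diploid GT records, one pseudo-contig per locus (GBS-style
#' tags have no genomic order), REF/ALT fixed to A/T.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path (plain text).
#' @return The path, invisibly.
#' @export
write_vcf <- function(g, path) {
  ids <- rownames(g$geno)
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=snpabc",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
             con)
  for (l in seq_len(ncol(g$geno))) {
    codes <- g$geno[, l]
    cells <- ifelse(is.na(codes), "./.", gt[codes + 1L])
    writeLines(paste(c(colnames(g$geno)[l], "1", colnames(g$geno)[l],
                       "A", "T", ".", "PASS", ".", "GT", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Genotypes are coded as counts of the first ALT allele.  Sites with more
#' than one ALT allele are retained (coded against the first ALT, other
#' alleles as missing) and flagged through the `n_alleles` slot so that
#' [filter_biallelic()] can drop them.
#'
#' @param path VCF path.
#' @param groups Named group assignment (names = sample ids), or a factor
#'   in sample order.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, groups) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- vcfR::getALT(v)
  n_alleles <- 1L + vapply(strsplit(alt, ","), length, integer(1))
  code <- function(s) {
    if (is.na(s)) return(NA_integer_)
    al <- strsplit(sub("\\|", "/", s), "/")[[1]]
    if (any(al == ".")) return(NA_integer_)
    al <- suppressWarnings(as.integer(al))
    if (anyNA(al) || any(al > 1L)) return(NA_integer_)
    sum(al)
  }
  m <- apply(gt, c(1, 2), code)
  m <- t(m)  # individuals x loci
  ids <- rownames(m)
  grp <- if (!is.null(names(groups))) groups[ids] else groups
  genotype_matrix(m, factor(as.character(grp), levels = unique(as.character(grp))),
                  n_alleles = n_alleles)
}
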