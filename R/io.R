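## Readers and writers for the delimited and VCF formats the tests consume.
## All downstream computation operates on the dosage matrix; positions and
## strand are carried only as metadata.

#' Read a genotype dosage matrix
#'
#' VCF: GT fields are mapped to minor(alternate)-allele dosage (`0/0` -> 0,
#' `0/1` or `1/0` -> 1, `1/1` -> 2, `./.` -> NA; phased separators accepted);
#' multi-allelic sites are rejected by site ID. TSV: a header row of SNP ids
#' with a leading `sample_id` column. SNPs missing in every sample are
#' dropped with a warning.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return numeric matrix samples x SNPs with row/column names.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    alt <- vcfR::getALT(v)
    multi <- grepl(",", alt)
    if (any(multi))
      stop("multi-allelic site(s): ",
           paste(vcfR::getID(v)[multi], collapse = ", "))
    gt <- vcfR::extract.gt(v, element = "GT")
    dose <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    dose[clean %in% c("0/0")] <- 0
    dose[clean %in% c("0/1", "1/0")] <- 1
    dose[clean %in% c("1/1")] <- 2
    bad <- !is.na(clean) & !clean %in% c("0/0", "0/1", "1/0", "1/1", "./.")
    if (any(bad))
      stop("malformed GT value(s): ", paste(unique(clean[bad]), collapse = ", "))
    G <- t(dose)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    G <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(G)) stop("non-numeric genotype entries in ", path)
    rownames(G) <- as.character(tab[[1]])
  }
  all_missing <- colSums(!is.na(G)) == 0
  if (any(all_missing)) {
    warning("dropping all-missing SNP(s): ",
            paste(colnames(G)[all_missing], collapse = ", "))
    G <- G[, !all_missing, drop = FALSE]
  }
  G
}

#' Write a genotype dosage matrix
#'
#' TSV mirrors the [read_genotypes()] layout. VCF writes a minimal
#' plain-text VCFv4.2 with one biallelic site per SNP (placeholder
#' chromosome/position/alleles) and dosage encoded in GT.
#'
#' @param G dosage matrix (samples x SNPs); values 0/1/2 or NA.
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @export
write_genotypes <- function(G, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  G <- as.matrix(G)
  if (is.null(rownames(G))) rownames(G) <- paste0("sample", seq_len(nrow(G)))
  if (is.null(colnames(G))) colnames(G) <- paste0("snp", seq_len(ncol(G)))
  if (format == "tsv") {
    tab <- data.frame(sample_id = rownames(G), G, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(G)), collapse = "\t"))
  for (j in seq_len(ncol(G))) {
    gts <- ifelse(is.na(G[, j]), "./.", gt_code[as.character(G[, j])])
    lines <- c(lines, paste(c("1", j, colnames(G)[j], "A", "C", ".", "PASS",
                              ".", "GT", gts), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Two-column delimited file (`sample_id`, `value`). Trait type is inferred:
#' values all in {0, 1} mean binary unless `trait` overrides.
#'
#' @param path file path.
#' @param trait `"auto"`, `"binary"` or `"continuous"`.
#' @return list with `phenotype` (named numeric vector) and `trait_type`.
#' @export
read_phenotype <- function(path, trait = c("auto", "binary", "continuous")) {
  trait <- match.arg(trait)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("phenotype file needs columns sample_id, value")
  ids <- as.character(tab[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  val <- tab[[2]]
  if (!is.numeric(val)) stop("non-numeric phenotype values in ", path)
  if (trait == "auto")
    trait <- if (all(val %in% c(0, 1))) "binary" else "continuous"
  list(phenotype = stats::setNames(as.numeric(val), ids), trait_type = trait)
}

#' Write a phenotype table
#'
#' @param phenotype named numeric vector (names are sample ids).
#' @param path output path.
#' @export
write_phenotype <- function(phenotype, path) {
  if (is.null(names(phenotype)))
    names(phenotype) <- paste0("sample", seq_along(phenotype))
  utils::write.table(data.frame(sample_id = names(phenotype),
                                value = as.numeric(phenotype)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align genotypes, phenotype and covariates by sample id
#'
#' Inner join on sample ids; samples missing from any component are dropped
#' and logged via `message()`.
#'
#' @param G genotype matrix with rownames.
#' @param phenotype named phenotype vector.
#' @param covariates optional covariate matrix/data.frame with rownames.
#' @return list with aligned `genotypes`, `phenotype`, `covariates`.
#' @export
align_samples <- function(G, phenotype, covariates = NULL) {
  ids <- intersect(rownames(G), names(phenotype))
  if (!is.null(covariates)) ids <- intersect(ids, rownames(covariates))
  dropped <- setdiff(union(rownames(G), names(phenotype)), ids)
  if (length(dropped))
    message("align_samples: dropped ", length(dropped), " sample(s): ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ...")
  if (!length(ids)) stop("no overlapping sample ids")
  list(genotypes = G[ids, , drop = FALSE],
       phenotype = phenotype[ids],
       covariates = if (!is.null(covariates))
         as.matrix(covariates)[ids, , drop = FALSE])
}
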