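#' Read a genotype table
#'
#' Reads a delimited genotype table: one row per individual, first column the
#' sample identifier, remaining columns one SNP each with additive allele
#' counts in \{0, 1, 2\} (missing as empty/NA). Any other value is rejected
#' with the offending row and column named. An optional `family` column
#' (second position) carries family labels for [impute_family_mean()].
#'
#' @param path File path.
#' @param delim Field delimiter; tab by default, use `","` for CSV.
#' @return A list of class `genejam_genotypes` with `values` (N x p numeric
#'   matrix, possibly with NAs), `sample_ids`, `snp_ids` and `family_ids`
#'   (NULL if absent).
#' @export
read_genotypes <- function(path, delim = "\t") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (ncol(tab) < 2) abort("Genotype table needs a sample-id column and at least one SNP.")
  sample_ids <- as.character(tab[[1]])
  family_ids <- NULL
  snp_start <- 2
  if (ncol(tab) >= 2 && identical(tolower(names(tab)[2]), "family")) {
    family_ids <- as.character(tab[[2]])
    snp_start <- 3
  }
  G <- as.matrix(tab[, snp_start:ncol(tab), drop = FALSE])
  storage.mode(G) <- "double"
  bad <- which(!is.na(G) & !(G %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Invalid genotype code %s at row %d (sample %s), column %s: expected 0/1/2 or missing.",
      format(G[bad[1, , drop = FALSE]]), bad[1, 1], sample_ids[bad[1, 1]],
      colnames(G)[bad[1, 2]]
    ))
  }
  rownames(G) <- sample_ids
  structure(list(values = G, sample_ids = sample_ids,
                 snp_ids = colnames(G), family_ids = family_ids),
            class = "genejam_genotypes")
}

#' Read a trait or score table
#'
#' Delimited table with sample ids in the first column and one numeric
#' column per trait.
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return Numeric matrix with sample ids as rownames.
#' @export
read_traits <- function(path, delim = "\t") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (ncol(tab) < 2) abort("Trait table needs a sample-id column and at least one trait.")
  M <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- as.character(tab[[1]])
  M
}

#' Write a sample-by-variable matrix as a delimited table
#'
#' @param m Matrix with rownames as sample ids.
#' @param path Output path.
#' @param delim Field delimiter.
#' @param id_col Name for the identifier column.
#' @export
write_matrix <- function(m, path, delim = "\t", id_col = "sample") {
  df <- tibble::as_tibble(m, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(!!id_col := rownames(m) %||%
                                  default_ids(nrow(m), "s")), df)
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Impute missing genotypes by within-family SNP means
#'
#' Each missing allele count is replaced by the mean genotype of that SNP in
#' the individual's family; a family with no observed value for the SNP
#' falls back to the overall SNP mean (reported via a message). Imputed
#' values are real-valued, not rounded.
#'
#' @param genotypes A `genejam_genotypes` object (with `family_ids`) or a
#'   numeric matrix plus `family_ids`.
#' @param family_ids Character/factor vector of family labels (ignored when
#'   `genotypes` carries its own).
#' @return Same shape as the input, with no missing values (a
#'   `genejam_genotypes` in, `genejam_genotypes` out; matrix in, matrix out).
#' @export
impute_family_mean <- function(genotypes, family_ids = NULL) {
  is_obj <- inherits(genotypes, "genejam_genotypes")
  G <- if (is_obj) genotypes$values else as_num_matrix(genotypes, "genotypes")
  fam <- if (is_obj && !is.null(genotypes$family_ids)) genotypes$family_ids
         else family_ids
  if (anyNA(G)) {
    if (is.null(fam)) abort("Family labels are required for family-mean imputation.")
    if (length(fam) != nrow(G)) abort("`family_ids` length must equal the number of samples.")
    fam <- as.character(fam)
    n_fallback <- 0L
    overall <- colMeans(G, na.rm = TRUE)
    for (f in unique(fam)) {
      rows <- which(fam == f)
      blk <- G[rows, , drop = FALSE]
      miss_cols <- which(colSums(is.na(blk)) > 0)
      for (j in miss_cols) {
        fm <- mean(blk[, j], na.rm = TRUE)
        if (is.nan(fm)) {
          fm <- overall[j]
          n_fallback <- n_fallback + 1L
        }
        blk[is.na(blk[, j]), j] <- fm
      }
      G[rows, ] <- blk
    }
    if (n_fallback > 0) {
      inform(sprintf(
        "%d SNP-family cell(s) had no observed genotypes: overall SNP mean used.",
        n_fallback
      ))
    }
  }
  if (is_obj) {
    genotypes$values <- G
    genotypes
  } else G
}

#' Filter SNPs on variance and minor-allele frequency
#'
#' Drops SNPs with no variation across individuals, then SNPs whose
#' estimated minor-allele frequency min(f, 1 - f) with f = mean/2 is at or
#' below `maf_min` (retained SNPs have MAF strictly above the threshold).
#'
#' @param genotypes Numeric genotype matrix (no missing values) or a
#'   `genejam_genotypes` object.
#' @param maf_min MAF threshold; default 0.01 ("above 1 percent").
#' @return List with `values` (filtered matrix, same class handling as
#'   [impute_family_mean()]) and `dropped` (tibble: `snp`, `reason`, `maf`).
#' @export
filter_snps <- function(genotypes, maf_min = 0.01) {
  is_obj <- inherits(genotypes, "genejam_genotypes")
  G <- if (is_obj) genotypes$values else as_num_matrix(genotypes, "genotypes")
  if (anyNA(G)) abort("Impute missing genotypes before filtering.")
  vars <- apply(G, 2, var)
  freqs <- colMeans(G) / 2
  mafs <- pmin(freqs, 1 - freqs)
  zero_var <- vars <= .Machine$double.eps
  low_maf <- !zero_var & mafs <= maf_min
  drop_idx <- which(zero_var | low_maf)
  dropped <- tibble(
    snp = (colnames(G) %||% default_ids(ncol(G), "snp"))[drop_idx],
    reason = unname(ifelse(zero_var[drop_idx], "zero_variance", "low_maf")),
    maf = unname(mafs[drop_idx])
  )
  keep <- !(zero_var | low_maf)
  Gf <- G[, keep, drop = FALSE]
  if (is_obj) {
    genotypes$values <- Gf
    genotypes$snp_ids <- colnames(Gf)
    list(values = genotypes, dropped = dropped)
  } else {
    list(values = Gf, dropped = dropped)
  }
}
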