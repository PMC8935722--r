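#' SNP genotype matrices
#'
#' A `snp_matrix` is an N x p integer matrix of minor-allele counts with
#' entries in \{0, 1, 2\}, carrying unique sample and SNP identifiers as
#' dimnames. Missing genotypes are not representable: validation rejects
#' them so that downstream learners never have to impute.
#'
#' @param values integer-like N x p matrix with entries in \{0, 1, 2\}.
#' @param sample_ids optional character vector of N unique sample ids;
#'   defaults to existing rownames or `sample_1..N`.
#' @param snp_ids optional character vector of p unique SNP ids; defaults to
#'   existing colnames or `snp_1..p`.
#' @return An integer matrix of class `snp_matrix`.
#' @examples
#' g <- snp_matrix(rbind(c(0, 1), c(2, 0), c(1, 1)))
#' encode_dominant_recessive(g)
#' @export
snp_matrix <- function(values, sample_ids = NULL, snp_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("genotype matrix must have at least one sample and one SNP")
  }
  bad <- which(is.na(values) | !(values %in% c(0, 1, 2)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(values)) + 1L
    stop(sprintf(
      "invalid genotype at row %d, column %d: %s (entries must be 0, 1 or 2)",
      i, j, deparse(values[i, j])
    ))
  }
  storage.mode(values) <- "integer"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(values)))
  }
  if (is.null(snp_ids)) {
    snp_ids <- colnames(values)
    if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(ncol(values)))
  }
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  if (length(sample_ids) != nrow(values) || anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique and match the number of rows")
  }
  if (length(snp_ids) != ncol(values) || anyDuplicated(snp_ids)) {
    stop("snp_ids must be unique and match the number of columns")
  }
  dimnames(values) <- list(sample_ids, snp_ids)
  class(values) <- c("snp_matrix", class(values))
  values
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d samples x %d SNPs\n", nrow(x), ncol(x)))
  print(head(unclass(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more samples\n", nrow(x) - 6L))
  invisible(x)
}

as_snp_matrix <- function(x) {
  if (inherits(x, "snp_matrix")) x else snp_matrix(x)
}

#' Validate a binary phenotype vector against a genotype matrix
#'
#' @param y vector coercible to 0/1.
#' @param g optional `snp_matrix` whose sample count must match.
#' @return An integer 0/1 vector.
#' @export
phenotype_vector <- function(y, g = NULL) {
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop("phenotype must be a binary 0/1 vector without missing values")
  }
  if (!is.null(g) && length(y) != nrow(g)) {
    stop("phenotype length does not match the number of samples")
  }
  y
}

#' Dominant/recessive binarization of SNP genotypes
#'
#' Each SNP is split into two indicator features: a dominant indicator
#' `SNP_D = 1(genotype != 0)` and a recessive indicator
#' `SNP_R = 1(genotype == 2)`. Feature order is (snp1_D, snp1_R, snp2_D, ...)
#' so that the recessive column always implies its dominant partner.
#'
#' @param g a `snp_matrix` (or coercible matrix).
#' @return An N x 2p integer 0/1 matrix with attributes `source_snp` (column
#'   index of the originating SNP) and `mode` (`"dominant"` or
#'   `"recessive"`), of class `binary_encoded`.
#' @seealso [decode_dominant_recessive()] for the inverse map.
#' @export
encode_dominant_recessive <- function(g) {
  g <- as_snp_matrix(g)
  p <- ncol(g)
  out <- matrix(0L, nrow(g), 2L * p)
  out[, 2L * seq_len(p) - 1L] <- (unclass(g) != 0L) + 0L
  out[, 2L * seq_len(p)] <- (unclass(g) == 2L) + 0L
  storage.mode(out) <- "integer"
  ids <- rep(colnames(g), each = 2L)
  colnames(out) <- paste0(ids, c("_D", "_R"))
  rownames(out) <- rownames(g)
  attr(out, "source_snp") <- rep(seq_len(p), each = 2L)
  attr(out, "mode") <- rep(c("dominant", "recessive"), p)
  class(out) <- c("binary_encoded", class(out))
  out
}

#' Reconstruct genotypes from dominant/recessive indicators
#'
#' Inverse of [encode_dominant_recessive()]: R = 1 maps to genotype 2,
#' D = 1, R = 0 to genotype 1, and D = 0 to genotype 0.
#'
#' @param b a `binary_encoded` matrix.
#' @return A `snp_matrix`.
#' @export
decode_dominant_recessive <- function(b) {
  stopifnot(inherits(b, "binary_encoded"))
  p <- ncol(b) %/% 2L
  d <- b[, 2L * seq_len(p) - 1L, drop = FALSE]
  r <- b[, 2L * seq_len(p), drop = FALSE]
  g <- matrix(0L, nrow(b), p)
  g[d == 1L] <- 1L
  g[r == 1L] <- 2L
  snp_matrix(g,
    sample_ids = rownames(b),
    snp_ids = sub("_D$", "", colnames(b)[2L * seq_len(p) - 1L])
  )
}

#' Additive (allele-count) encoding
#'
#' Passes the \{0,1,2\} minor-allele counts through as ordered numeric
#' features — the default input coding for the random forest and elastic
#' net learners.
#'
#' @param g a `snp_matrix`.
#' @return A numeric matrix with the same dimnames.
#' @export
encode_additive <- function(g) {
  g <- as_snp_matrix(g)
  out <- unclass(g)
  storage.mode(out) <- "double"
  out
}

#' Read a genotype table from delimited text
#'
#' Two dialects are supported. `"table"` expects a header of SNP ids, one
#' row per sample, optionally a first id column (non-numeric) and optionally
#' a phenotype column named in `phenotype_col` with 0/1 entries. `"raw"`
#' expects the PLINK .raw additive layout: columns FID IID PAT MAT SEX
#' PHENOTYPE followed by per-SNP allele counts; PHENOTYPE uses the
#' 1 = control / 2 = case convention and is recoded to 0/1 (0 or -9 is
#' treated as missing and rejected).
#'
#' @param path file path.
#' @param dialect `"table"` or `"raw"`.
#' @param sep field separator; guessed from the extension for `"table"`
#'   (`","` for .csv, whitespace otherwise).
#' @param phenotype_col name of the phenotype column in the `"table"`
#'   dialect, or NULL if none.
#' @return A list with elements `genotypes` (a `snp_matrix`), `phenotype`
#'   (0/1 integer vector or NULL) and `environment` (NULL; reserved).
#' @export
read_genotype_table <- function(path, dialect = c("table", "raw"), sep = NULL,
                                phenotype_col = "phenotype") {
  dialect <- match.arg(dialect)
  if (dialect == "raw") {
    tab <- read.table(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(tab)[seq_along(meta)])) {
      stop("not a PLINK .raw-style table: expected leading columns ",
           paste(meta, collapse = " "))
    }
    ph <- tab$PHENOTYPE
    if (anyNA(ph) || any(ph %in% c(0, -9)) || !all(ph %in% c(1, 2))) {
      stop("PHENOTYPE must be 1 (control) or 2 (case); missing codes are rejected")
    }
    gcols <- setdiff(names(tab), meta)
    g <- snp_matrix(as.matrix(tab[gcols]),
                    sample_ids = as.character(tab$IID), snp_ids = gcols)
    return(list(genotypes = g, phenotype = as.integer(ph == 2), environment = NULL))
  }
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  sample_ids <- NULL
  if (ncol(tab) && !is.numeric(tab[[1L]])) {
    sample_ids <- as.character(tab[[1L]])
    tab <- tab[-1L]
  }
  phenotype <- NULL
  if (!is.null(phenotype_col) && phenotype_col %in% names(tab)) {
    phenotype <- phenotype_vector(tab[[phenotype_col]])
    tab <- tab[setdiff(names(tab), phenotype_col)]
  }
  g <- snp_matrix(as.matrix(tab), sample_ids = sample_ids, snp_ids = names(tab))
  list(genotypes = g, phenotype = phenotype, environment = NULL)
}

#' Write a genotype table mirroring [read_genotype_table()]
#'
#' @param g a `snp_matrix`.
#' @param path output path; `.csv` selects comma separation.
#' @param phenotype optional 0/1 vector written as a `phenotype` column.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(g, path, phenotype = NULL) {
  g <- as_snp_matrix(g)
  df <- data.frame(sample_id = rownames(g), unclass(g), check.names = FALSE)
  if (!is.null(phenotype)) df$phenotype <- phenotype_vector(phenotype, g)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
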