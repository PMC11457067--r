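#' Marker quality control, imputation and the realized relationship matrix
#'
#' A dosage matrix is a plain numeric matrix of diploid-coded allele dosages
#' (0/1/2, fractional values allowed after imputation) with individuals as
#' rows and markers as columns, both dimensions named. Switchgrass tetraploids
#' show disomic inheritance, so diploid coding is the appropriate
#' parameterisation for kinship estimation. Missing calls are `NA`.
#'
#' @name markers
NULL

check_dosage <- function(dosage) {
  if (!is.matrix(dosage) || !is.numeric(dosage)) {
    stop("`dosage` must be a numeric matrix (individuals x markers)", call. = FALSE)
  }
  if (nrow(dosage) == 0L || ncol(dosage) == 0L) {
    stop("`dosage` is empty", call. = FALSE)
  }
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    stop("`dosage` needs individual (row) and marker (column) names", call. = FALSE)
  }
  if (anyDuplicated(rownames(dosage)) || anyDuplicated(colnames(dosage))) {
    stop("duplicated individual or marker identifiers in `dosage`", call. = FALSE)
  }
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  invisible(dosage)
}

#' Filter markers on missingness and minor allele frequency
#'
#' Retains markers with a missing-call fraction strictly below
#' `max_missing` and a minor allele frequency strictly above `min_maf`,
#' the QC rule used for the switchgrass diversity-panel marker set
#' (<20% missing, MAF > 0.005). MAF is computed from non-missing calls as
#' `min(p, 1 - p)` with `p = mean(dosage) / 2`.
#'
#' @param dosage Numeric matrix, individuals x markers, dosages in
#'   \[0, 2\] with `NA` for missing calls.
#' @param max_missing Markers with missing fraction `>= max_missing` are
#'   dropped. Default 0.2.
#' @param min_maf Markers with MAF `<= min_maf` are dropped. Default 0.005.
#' @return The dosage matrix restricted to surviving markers, order
#'   preserved; individuals untouched.
#' @export
filter_markers <- function(dosage, max_missing = 0.2, min_maf = 0.005) {
  check_dosage(dosage)
  stopifnot(max_missing >= 0, max_missing < 1, min_maf >= 0, min_maf <= 0.5)
  miss <- colMeans(is.na(dosage))
  p <- colMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  # fully-missing markers have maf NaN; they fail the missingness rule anyway
  keep <- miss < max_missing & !is.na(maf) & maf > min_maf
  if (!any(keep)) stop("no markers survive QC", call. = FALSE)
  dosage[, keep, drop = FALSE]
}

#' Impute missing dosages to the marker mean
#'
#' Each missing call is replaced by the mean of that marker's non-missing
#' dosages (population-mean imputation). Non-missing entries are unchanged.
#'
#' @inheritParams filter_markers
#' @return A complete dosage matrix.
#' @export
impute_missing <- function(dosage) {
  check_dosage(dosage)
  if (!anyNA(dosage)) return(dosage)
  mu <- colMeans(dosage, na.rm = TRUE)
  bad <- !is.finite(mu)
  if (any(bad)) {
    stop("marker(s) with no non-missing calls: ",
         paste(colnames(dosage)[bad], collapse = ", "), call. = FALSE)
  }
  idx <- which(is.na(dosage), arr.ind = TRUE)
  dosage[idx] <- mu[idx[, 2]]
  dosage
}

#' Realized (genomic) relationship matrix
#'
#' VanRaden method-1 estimator with observed allele frequencies:
#' `G = W W' / (2 * sum(p * (1 - p)))` where `W` is the dosage matrix with
#' each marker centered at twice its allele frequency. This is the
#' centered-crossproduct kinship behind `rrBLUP::A.mat` defaults (no
#' shrinkage, no internal MAF floor — QC is [filter_markers()]'s job).
#'
#' If the smallest eigenvalue falls below `-1e-8` the matrix is bent by
#' adding `|lambda_min| + 1e-6` to the diagonal so downstream REML and
#' Gibbs machinery can factorise it; the adjustment is recorded in the
#' `"bending"` attribute.
#'
#' @param dosage Complete numeric dosage matrix (run [impute_missing()]
#'   first); at least 2 individuals and 1 polymorphic marker.
#' @return An n x n symmetric matrix of class `"grm"` with individual IDs as
#'   dimnames and attributes `denominator` (2 * sum p(1-p)) and `bending`
#'   (0 when no repair was needed).
#' @export
realized_relationship <- function(dosage) {
  check_dosage(dosage)
  if (anyNA(dosage)) stop("dosage has missing values; run impute_missing() first", call. = FALSE)
  if (nrow(dosage) < 2L) stop("need at least 2 individuals", call. = FALSE)
  p <- colMeans(dosage) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers are monomorphic: zero VanRaden denominator", call. = FALSE)
  W <- sweep(dosage, 2L, 2 * p, "-")
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  bend <- 0
  if (ev_min < -1e-8) {
    bend <- abs(ev_min) + 1e-6
    diag(G) <- diag(G) + bend
  }
  structure(G, class = c("grm", "matrix", "array"),
            denominator = denom, bending = bend)
}

# The sample-frequency-centered GRM is singular by construction (the
# all-ones vector sits in its null space), so model code adds a tiny ridge
# before factorising. Indefinite input is a user error: bending belongs in
# realized_relationship().
regularize_grm <- function(Gm, ridge = 1e-6) {
  ev_min <- min(eigen(Gm, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    stop("G is not positive semidefinite; bend it first (see realized_relationship)",
         call. = FALSE)
  }
  if (ev_min < 1e-8) Gm <- Gm + diag(ridge, nrow(Gm))
  Gm
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d individuals; mean diagonal %.3f; bending %g\n",
              nrow(x), mean(diag(x)), attr(x, "bending")))
  invisible(x)
}

#' Read a dosage matrix from delimited text
#'
#' Expects individuals as rows, a header row of marker IDs, and the first
#' column holding individual IDs. Empty fields, `NA` and `.` parse as
#' missing.
#'
#' @param path File path (any delimiter readr can guess via `delim`).
#' @param delim Field delimiter, default tab.
#' @return A numeric dosage matrix with dimnames.
#' @export
read_dosage <- function(path, delim = "\t") {
  df <- readr::read_delim(path, delim = delim, na = c("", "NA", "."),
                          show_col_types = FALSE, progress = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  check_dosage(m)
}

#' Write a dosage matrix as delimited text
#'
#' @param dosage Dosage matrix.
#' @param path Output path.
#' @param delim Field delimiter, default tab.
#' @export
write_dosage <- function(dosage, path, delim = "\t") {
  df <- tibble::as_tibble(dosage, rownames = "individual_id")
  readr::write_delim(df, path, delim = delim, na = "NA")
  invisible(path)
}

#' Read dosages from a VCF
#'
#' Converts GT fields of biallelic SNPs to ALT-allele counts (0/1/2).
#' Multiallelic or non-SNP records are skipped with a message reporting the
#' count.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return A numeric dosage matrix, individuals x markers.
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_dosage_vcf() needs the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ref <- vcfR::getREF(v)
  alt <- vcfR::getALT(v)
  biallelic_snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE)
  n_skip <- sum(!biallelic_snp)
  if (n_skip > 0) message(n_skip, " non-biallelic-SNP record(s) skipped")
  v <- v[biallelic_snp, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | grepl("\\.", g), NA_real_,
           vapply(strsplit(gsub("\\|", "/", g), "/", fixed = FALSE),
                  function(a) sum(a == "1"), numeric(1)))
  }
  m <- t(apply(gt, 1L, count_alt))
  colnames(m) <- colnames(gt)
  m <- t(m)
  ids <- vcfR::getID(v)
  if (anyNA(ids) || anyDuplicated(ids)) {
    ids <- paste0(vcfR::getCHROM(v), "_", vcfR::getPOS(v))
  }
  colnames(m) <- ids
  check_dosage(m)
}

#' Write / read a relationship matrix as delimited text
#'
#' Full-precision square matrix with a header row and an ID column, so a
#' write/read round trip is lossless to at least 10 significant digits.
#'
#' @param G Relationship matrix (class `"grm"` or plain symmetric matrix).
#' @param path File path.
#' @return `read_grm()` returns a `"grm"` object.
#' @export
write_grm <- function(G, path) {
  df <- tibble::as_tibble(unclass(G), rownames = "individual_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m <- (m + t(m)) / 2
  structure(m, class = c("grm", "matrix", "array"),
            denominator = NA_real_, bending = 0)
}
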