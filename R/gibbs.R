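#' Bayesian multisite prediction with Kronecker genetic covariance
#'
#' Mean genotype performance at each site (and, optionally, yield
#' surrogates measured at reference sites) is modelled as a set of
#' correlated response columns: `y_ij = mu_j + g_ij + e_ij` with
#' `vec(g) ~ N(0, Ta (x) G)`, `Ta` unstructured across columns and `G`
#' the realized relationship matrix. The model is fitted by Gibbs
#' sampling; missing cells contribute nothing to the likelihood, so
#' genotypes with few (or zero) observed columns are predicted through
#' their relatives and the estimated inter-column covariance. This is the
#' prediction engine behind the sparse-testing cross-validation.
#'
#' @name gibbs
NULL

#' Build the genotype-by-column response matrix
#'
#' One column of standardized mean biomass per site, plus (optionally) one
#' column per yield surrogate built from the reference-site means of
#' [surrogate_site_means()]. Standardization is per column over observed
#' cells.
#'
#' @param table Aggregated phenotype tibble.
#' @param sites Site codes to use as biomass columns (default: all sites
#'   present).
#' @param surrogates Surrogate traits to append (`NULL` for none).
#' @param surrogate_sites Reference sites for the surrogate means.
#' @param scale Standardize each column to mean 0, sd 1.
#' @return Numeric matrix (class `"response_matrix"`) genotypes x columns
#'   with `NA` for unobserved cells and attributes `center`/`scale`;
#'   columns with fewer than 2 observations are dropped with a warning.
#' @export
build_response <- function(table, sites = NULL, surrogates = NULL,
                           surrogate_sites = c("KBSM", "CLMB"),
                           scale = TRUE) {
  check_phenotypes(table)
  bio <- dplyr::filter(table, .data$trait == "biomass")
  if (is.null(sites)) sites <- sort(unique(bio$site))
  bio <- dplyr::filter(bio, .data$site %in% sites)
  cells <- bio |>
    dplyr::summarise(value = mean(.data$value),
                     .by = c("genotype_id", "site")) |>
    dplyr::rename(column = "site")
  if (!is.null(surrogates)) {
    sur <- surrogate_site_means(table, sites = surrogate_sites,
                                traits = surrogates) |>
      dplyr::rename(column = "trait")
    cells <- dplyr::bind_rows(cells, sur)
  }
  ids <- sort(unique(cells$genotype_id))
  cols <- c(sites, surrogates)
  wide <- tidyr::pivot_wider(cells, names_from = "column", values_from = "value")
  m <- matrix(NA_real_, length(ids), length(cols),
              dimnames = list(ids, cols))
  for (cl in intersect(cols, names(wide))) m[wide$genotype_id, cl] <- wide[[cl]]
  thin_cols <- colSums(!is.na(m)) < 2L
  if (any(thin_cols)) {
    warning("dropping column(s) with < 2 observations: ",
            paste(colnames(m)[thin_cols], collapse = ", "))
    m <- m[, !thin_cols, drop = FALSE]
  }
  ctr <- rep(0, ncol(m)); scl <- rep(1, ncol(m))
  if (scale) {
    ctr <- colMeans(m, na.rm = TRUE)
    scl <- apply(m, 2L, stats::sd, na.rm = TRUE)
    m <- sweep(sweep(m, 2L, ctr, "-"), 2L, scl, "/")
  }
  structure(m, class = c("response_matrix", "matrix", "array"),
            center = setNames(ctr, colnames(m)),
            scale = setNames(scl, colnames(m)))
}

#' Run the Gibbs sampler
#'
#' Full-conditional updates cycle over column intercepts, breeding-value
#' rows (sampled genotype-by-genotype from their multivariate normal
#' conditional under the `Ta (x) G` prior, using the precision structure
#' of `G^-1` so no `nt x nt` matrix is formed), `Ta` from its
#' inverse-Wishart conditional, and per-column residual variances from
#' scaled inverse-chi-square conditionals. Priors are weakly informative:
#' `Ta ~ IW(nu = t + 2, S = 0.5 * nu * I)` and residuals
#' `~ scaled-inv-chisq(df = 5, scale = 0.5)`, appropriate for standardized
#' columns. Draws are retained after `burn_in`, every `thin`-th
#' iteration: `floor((n_iter - burn_in) / thin)` of them.
#'
#' @param Y Response matrix from [build_response()] (or any numeric
#'   genotype x column matrix with rownames); at least 2 columns.
#' @param G Relationship matrix containing every row of `Y`.
#' @param n_iter,burn_in,thin Chain settings. The full-scale analysis
#'   used 25,000/200/5; the default 3,000/200/5 is a scaled-down chain
#'   suited to the few-hundred-genotype problems in this package's tests.
#' @param seed Integer seed (chains are exactly reproducible).
#' @return Object of class `"gibbs"`: posterior means `g_mean` (n x t) and
#'   `mu`, retained draws of `Ta`, residual variances and intercepts,
#'   chain metadata, and split-R-hat diagnostics for the `Ta` diagonal.
#' @export
run_gibbs <- function(Y, G, n_iter = 3000L, burn_in = 200L, thin = 5L,
                      seed = 1L) {
  stopifnot(is.matrix(Y), ncol(Y) >= 2L, n_iter > burn_in, thin >= 1L)
  ids <- rownames(Y)
  if (is.null(ids)) stop("Y needs genotype rownames", call. = FALSE)
  absent <- setdiff(ids, rownames(G))
  if (length(absent)) {
    stop("genotype(s) absent from G: ", paste(head(absent, 5), collapse = ", "),
         call. = FALSE)
  }
  # the sampler's single-site updates need G^-1 with a bounded condition
  # number: a singular direction (the centered GRM always has one) would
  # freeze the chain, so the ridge here is deliberately larger than the
  # REML one
  Gm <- regularize_grm(unclass(G)[ids, ids], ridge = 0.01)
  Ginv <- chol2inv(chol(Gm))
  t <- ncol(Y)
  nu0 <- t + 2
  S0 <- diag(0.5 * nu0, t)
  set.seed(as.integer(seed))
  out <- gibbs_mtm_cpp(unclass(Y), Ginv, as.integer(n_iter),
                       as.integer(burn_in), as.integer(thin),
                       nu0, S0, df_e = 5, scale_e = 0.5)
  dimnames(out$g_mean) <- dimnames(Y)
  colnames(out$mu_draws) <- colnames(Y)
  colnames(out$sigma2_draws) <- colnames(Y)
  structure(list(
    g_mean = out$g_mean,
    mu = colMeans(out$mu_draws),
    Ta_mean = matrix(colMeans(out$Ta_draws), t, t,
                     dimnames = list(colnames(Y), colnames(Y))),
    Ta_draws = out$Ta_draws,
    sigma2_draws = out$sigma2_draws,
    mu_draws = out$mu_draws,
    n_retained = out$n_retained,
    chain = list(n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed),
    columns = colnames(Y),
    center = attr(Y, "center"),
    scale = attr(Y, "scale")
  ), class = "gibbs")
}

#' @export
print.gibbs <- function(x, ...) {
  cat(sprintf("Gibbs posterior: %d genotypes x %d columns; %d retained draws (%d/%d/%d, seed %d)\n",
              nrow(x$g_mean), length(x$columns), x$n_retained,
              x$chain$n_iter, x$chain$burn_in, x$chain$thin, x$chain$seed))
  rh <- split_rhat(x)
  cat(sprintf("  split-Rhat on diag(Ta): max %.3f\n", max(rh)))
  invisible(x)
}

#' Split-R-hat for the Ta diagonal
#'
#' Splits the retained chain in halves and computes the usual
#' between/within variance ratio per diagonal element of `Ta`; values
#' near 1 indicate the chain has mixed.
#'
#' @param post A `"gibbs"` object.
#' @return Named numeric vector, one value per response column.
#' @export
split_rhat <- function(post) {
  stopifnot(inherits(post, "gibbs"))
  t <- length(post$columns)
  di <- (seq_len(t) - 1L) * t + seq_len(t)
  vapply(seq_len(t), function(j) {
    x <- post$Ta_draws[, di[j]]
    n2 <- floor(length(x) / 2)
    a <- x[seq_len(n2)]; b <- x[n2 + seq_len(n2)]
    W <- (var(a) + var(b)) / 2
    B <- n2 * var(c(mean(a), mean(b)))
    sqrt(((n2 - 1) / n2 * W + B / n2) / W)
  }, numeric(1)) |> setNames(post$columns)
}

#' Predictions for masked genotype-by-column cells
#'
#' The prediction for genotype `j` in column `i` is the posterior mean
#' `mu_i + g_mean[j, i]`, on the standardized scale (predictive ability
#' is a correlation, so the scale drops out); set `rescale = TRUE` to map
#' back to the data scale using the stored column constants.
#'
#' @param post A `"gibbs"` object fitted to the masked training response.
#' @param mask Logical matrix (genotypes x columns, same shape/dimnames
#'   as the training response) with `TRUE` for the cells to predict, or a
#'   tibble with columns `genotype_id`, `column`.
#' @param rescale Return predictions on the original data scale.
#' @return Tibble `genotype_id`, `column`, `predicted`.
#' @export
predict_masked <- function(post, mask, rescale = FALSE) {
  stopifnot(inherits(post, "gibbs"))
  if (is.matrix(mask)) {
    idx <- which(mask, arr.ind = TRUE)
    cells <- tibble::tibble(genotype_id = rownames(mask)[idx[, 1]],
                            column = colnames(mask)[idx[, 2]])
  } else {
    cells <- tibble::as_tibble(mask)[, c("genotype_id", "column")]
  }
  absent <- setdiff(cells$genotype_id, rownames(post$g_mean))
  if (length(absent)) {
    stop("genotype(s) not in the fitted response/G: ",
         paste(head(absent, 5), collapse = ", "), call. = FALSE)
  }
  cells <- dplyr::filter(cells, .data$column %in% post$columns)
  pred <- post$mu[cells$column] +
    post$g_mean[cbind(cells$genotype_id, cells$column)]
  if (rescale && !is.null(post$center)) {
    pred <- pred * post$scale[cells$column] + post$center[cells$column]
  }
  dplyr::mutate(cells, predicted = as.numeric(pred))
}

#' @exportS3Method generics::tidy
tidy.gibbs <- function(x, ...) {
  tibble::as_tibble(x$g_mean, rownames = "genotype_id") |>
    tidyr::pivot_longer(-"genotype_id", names_to = "column",
                        values_to = "g_mean")
}

#' @exportS3Method generics::glance
glance.gibbs <- function(x, ...) {
  tibble::tibble(
    n_genotypes = nrow(x$g_mean),
    n_columns = length(x$columns),
    n_retained = x$n_retained,
    max_split_rhat = max(split_rhat(x)),
    mean_genetic_var = mean(diag(x$Ta_mean)),
    mean_residual_var = mean(colMeans(x$sigma2_draws))
  )
}
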