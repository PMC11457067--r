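#' AMMI decomposition of genotype-by-site biomass means
#'
#' The additive main effects and multiplicative interaction model writes
#' the cell mean for row i (genotype or subpopulation) at site j as
#' `Y_ij = mu + g_i + l_j + sum_k lambda_k * alpha_ik * gamma_jk + E_ij`:
#' ANOVA main effects plus a singular value decomposition of the
#' double-centered interaction residuals. Principal-component scores place
#' rows and sites on a biplot whose leading axis, in this panel, tracks the
#' north–south site gradient.
#'
#' @name ammi
NULL

#' Genotype-by-site cell-mean matrix for AMMI
#'
#' Builds the two-way table of biomass means, either at the individual
#' level (admixed genotypes optionally removed, as in the panel's AMMI run)
#' or aggregated to the four subpopulations.
#'
#' @param table Aggregated phenotype tibble ([aggregate_phenotypes()]).
#' @param info Genotype metadata tibble: `genotype_id`, `subpopulation`,
#'   `admixed` (logical). Needed when `level = "subpopulation"` or
#'   `drop_admixed = TRUE`.
#' @param level `"individual"` rows or `"subpopulation"` rows.
#' @param drop_admixed Remove admixed genotypes first (individual level).
#' @return Numeric matrix (rows x sites) of biomass means, `NA` for empty
#'   cells.
#' @export
build_cell_means <- function(table, info = NULL,
                             level = c("individual", "subpopulation"),
                             drop_admixed = FALSE) {
  level <- match.arg(level)
  check_phenotypes(table)
  bio <- dplyr::filter(table, .data$trait == "biomass")
  if (level == "subpopulation" || drop_admixed) {
    if (is.null(info)) stop("`info` metadata required", call. = FALSE)
    bio <- dplyr::inner_join(bio, info, by = "genotype_id")
  }
  if (drop_admixed && "admixed" %in% names(bio)) {
    bio <- dplyr::filter(bio, !.data$admixed)
  }
  row_var <- if (level == "individual") "genotype_id" else "subpopulation"
  cells <- bio |>
    dplyr::summarise(value = mean(.data$value),
                     .by = dplyr::all_of(c(row_var, "site")))
  wide <- tidyr::pivot_wider(cells, names_from = "site", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide[[1]])
  keep_r <- rowSums(!is.na(m)) > 0
  keep_c <- colSums(!is.na(m)) > 0
  m <- m[keep_r, keep_c, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("cell-mean matrix needs at least 2 non-empty rows and columns", call. = FALSE)
  }
  m
}

#' Complete a two-way table by additive EM fill
#'
#' AMMI needs a complete table but multi-site trials are unbalanced.
#' Missing cells are filled with the additive expectation
#' `mu + g_i + l_j`, the margins re-estimated from the completed table, and
#' the cycle repeated until the largest fill change drops below `tol`.
#' Observed cells are never touched. Interaction structure in the filled
#' cells is deliberately absent: the fill is the minimum-assumption
#' completion and its fraction is recorded.
#'
#' @param m Cell-mean matrix, possibly with `NA` cells; every row and
#'   column needs at least one observation.
#' @param tol Convergence tolerance on the largest fill change.
#' @param max_iter Iteration cap.
#' @return The completed matrix with attributes `fill_mask` (logical
#'   matrix of filled cells), `fill_fraction` and `iterations`.
#' @export
complete_matrix <- function(m, tol = 1e-8, max_iter = 500L) {
  stopifnot(is.matrix(m), nrow(m) >= 2L, ncol(m) >= 2L)
  if (any(rowSums(!is.na(m)) == 0L) || any(colSums(!is.na(m)) == 0L)) {
    stop("every row and column needs at least one observed cell", call. = FALSE)
  }
  mask <- is.na(m)
  if (!any(mask)) {
    return(structure(m, fill_mask = mask, fill_fraction = 0, iterations = 0L))
  }
  mu <- mean(m, na.rm = TRUE)
  g <- rowMeans(m, na.rm = TRUE) - mu
  l <- colMeans(m, na.rm = TRUE) - mu
  x <- m
  x[mask] <- (mu + outer(g, l, "+"))[mask]
  it <- 0L
  repeat {
    it <- it + 1L
    mu <- mean(x)
    g <- rowMeans(x) - mu
    l <- colMeans(x) - mu
    fill <- (mu + outer(g, l, "+"))[mask]
    delta <- max(abs(fill - x[mask]))
    x[mask] <- fill
    if (delta < tol || it >= max_iter) break
  }
  structure(x, fill_mask = mask, fill_fraction = mean(mask), iterations = it)
}

#' Fit the AMMI model
#'
#' Main effects are the centered marginal means; the interaction residual
#' `Z = Y - mu - g - l` is decomposed by SVD into `K` multiplicative
#' components. The per-component share of interaction variance is
#' `lambda_k^2 / sum(lambda^2)` (the GxE sum of squares is the
#' denominator). Signs are pinned per component so the site score of
#' largest magnitude is positive, making biplots reproducible.
#'
#' @param m Complete cell-mean matrix (see [complete_matrix()]).
#' @param K Number of multiplicative components,
#'   `1 <= K <= min(dim(m)) - 1`.
#' @return An object of class `"ammi"`: list with `grand_mean`,
#'   `row_effects`, `col_effects`, `singular_values`, `row_scores`
#'   (rows x K), `col_scores` (sites x K), `variance_fraction`,
#'   `residuals`, `zero_interaction` flag, `degenerate_pairs`.
#' @export
fit_ammi <- function(m, K = 2L) {
  stopifnot(is.matrix(m), nrow(m) >= 2L, ncol(m) >= 2L)
  if (anyNA(m)) stop("matrix has missing cells; run complete_matrix() first", call. = FALSE)
  K_max <- min(dim(m)) - 1L
  if (K < 1L || K > K_max) {
    stop("K must lie in [1, ", K_max, "]", call. = FALSE)
  }
  mu <- mean(m)
  g <- rowMeans(m) - mu
  l <- colMeans(m) - mu
  Z <- m - mu - outer(g, l, "+")
  sv <- svd(Z)
  lambda <- sv$d[seq_len(K_max)]
  alpha <- sv$u[, seq_len(K_max), drop = FALSE]
  gamma <- sv$v[, seq_len(K_max), drop = FALSE]
  # pin SVD sign ambiguity: largest-|.| site score positive per component
  for (k in seq_len(K_max)) {
    j <- which.max(abs(gamma[, k]))
    if (gamma[j, k] < 0) {
      gamma[, k] <- -gamma[, k]
      alpha[, k] <- -alpha[, k]
    }
  }
  ss <- sum(lambda^2)
  zero_int <- ss < 1e-12
  vf <- if (zero_int) rep(0, K_max) else lambda^2 / ss
  degen <- which(diff(lambda) != 0 &
                   abs(diff(lambda)) / pmax(lambda[-K_max], .Machine$double.eps) < 1e-6)
  approx_K <- alpha[, seq_len(K), drop = FALSE] %*%
    (lambda[seq_len(K)] * t(gamma[, seq_len(K), drop = FALSE]))
  dimnames(alpha) <- list(rownames(m), paste0("PC", seq_len(K_max)))
  dimnames(gamma) <- list(colnames(m), paste0("PC", seq_len(K_max)))
  structure(list(
    grand_mean = mu,
    row_effects = g,
    col_effects = l,
    singular_values = lambda,
    row_scores = alpha,
    col_scores = gamma,
    variance_fraction = vf,
    residuals = Z - approx_K,
    K = as.integer(K),
    zero_interaction = zero_int,
    degenerate_pairs = degen,
    fitted_cells = m
  ), class = "ammi")
}

#' @export
print.ammi <- function(x, ...) {
  cat(sprintf("AMMI fit: %d rows x %d sites, K = %d\n",
              length(x$row_effects), length(x$col_effects), x$K))
  if (x$zero_interaction) {
    cat("  interaction sum of squares ~ 0 (additive table)\n")
  } else {
    vf <- x$variance_fraction[seq_len(x$K)]
    cat(sprintf("  GxE variance explained: %s\n",
                paste(sprintf("PC%d %.1f%%", seq_along(vf), 100 * vf),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Tidy AMMI scores
#'
#' @param x An `"ammi"` fit.
#' @param ... Unused.
#' @return Tibble with one row per (id, axis): `id`, `type`
#'   (`"row"`/`"site"`), `mean_effect`, `axis`, `score`.
#' @exportS3Method generics::tidy
tidy.ammi <- function(x, ...) {
  K <- x$K
  rows <- tibble::as_tibble(x$row_scores[, seq_len(K), drop = FALSE],
                            rownames = "id") |>
    dplyr::mutate(type = "row", mean_effect = x$grand_mean + x$row_effects)
  sites <- tibble::as_tibble(x$col_scores[, seq_len(K), drop = FALSE],
                             rownames = "id") |>
    dplyr::mutate(type = "site", mean_effect = x$grand_mean + x$col_effects)
  dplyr::bind_rows(rows, sites) |>
    tidyr::pivot_longer(dplyr::starts_with("PC"),
                        names_to = "axis", values_to = "score") |>
    dplyr::select("id", "type", "mean_effect", "axis", "score")
}

#' @exportS3Method generics::glance
glance.ammi <- function(x, ...) {
  tibble::tibble(
    n_rows = length(x$row_effects),
    n_sites = length(x$col_effects),
    K = x$K,
    gxe_ss = sum(x$singular_values^2),
    pc1_fraction = x$variance_fraction[1],
    pc2_fraction = if (length(x$variance_fraction) > 1) x$variance_fraction[2] else NA_real_,
    zero_interaction = x$zero_interaction
  )
}

#' AMMI biplot
#'
#' Mean performance against PC1 score (`axes = 1`), or a PC1 x PC2 score
#' biplot (`axes = c(1, 2)`), rows and sites overlaid.
#'
#' @param object An `"ammi"` fit.
#' @param axes One or two component indices.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ammi <- function(object, axes = 1L, ...) {
  td <- tidy(object)
  ax <- paste0("PC", axes)
  if (length(axes) == 1L) {
    d <- dplyr::filter(td, .data$axis == ax)
    ggplot2::ggplot(d, ggplot2::aes(.data$mean_effect, .data$score,
                                    colour = .data$type, label = .data$id)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_text(size = 3) +
      ggplot2::labs(x = "mean biomass (sqrt g)", y = ax, colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    d <- td |>
      dplyr::filter(.data$axis %in% ax) |>
      tidyr::pivot_wider(names_from = "axis", values_from = "score")
    ggplot2::ggplot(d, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                                    colour = .data$type, label = .data$id)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_text(size = 3) +
      ggplot2::labs(colour = NULL) +
      ggplot2::theme_minimal()
  }
}
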