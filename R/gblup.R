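#' Single- and multi-trait GBLUP by REML
#'
#' Fits `y_ijk = mu + s_i + g_j + e_ijk` per trait, with site as a fixed
#' effect and genotype effects covarying according to the realized
#' relationship matrix: for `t` traits jointly,
#' `vec(g) ~ N(0, Ta (x) G)` with `Ta` the unstructured genetic
#' covariance across traits and residuals independent within and across
#' traits (diagonal residual covariance, matching the i.i.d. residual in
#' the printed model; traits are measured on the same plants, so an
#' unstructured residual is a deliberate non-goal here). Variance
#' components are REML estimates (EM warm-up, then average-information
#' updates with step-halving back to EM); BLUPs and prediction error
#' variances come from the mixed-model equations at the converged
#' components. A single-trait fit is the `t = 1` special case of the same
#' machinery.
#'
#' @param table Aggregated phenotype tibble ([aggregate_phenotypes()]).
#' @param G Relationship matrix covering every phenotyped genotype
#'   (class `"grm"` or a named symmetric matrix). BLUPs are produced for
#'   every genotype in `G`, phenotyped or not.
#' @param traits Character vector of traits to fit jointly.
#' @param method `"ai"` (default) or `"em"` (pure EM-REML; slower but with
#'   a monotone likelihood trace).
#' @param max_iter,tol Convergence controls: stop when the largest
#'   relative parameter change drops below `tol` or the restricted
#'   likelihood is flat; near-boundary problems (genetic correlations
#'   approaching 1) fall back to EM steps and may use a few hundred
#'   iterations.
#' @return Object of class `"gblup"`: list with `traits`, `Ta`, `residual`
#'   (per-trait variances), `blups` (tibble genotype_id x trait), `pev`,
#'   `beta`, `loglik` (REML log-likelihood trace), `converged`,
#'   `iterations`, and per-trait `Cgg` blocks used for Cullis
#'   heritability.
#' @export
fit_gblup <- function(table, G, traits = "biomass",
                      method = c("ai", "em"), max_iter = 500L, tol = 1e-6) {
  method <- match.arg(method)
  check_phenotypes(table)
  stopifnot(length(traits) >= 1L, all(traits %in% PHENO_TRAITS))
  ids <- rownames(G)
  dat <- table |>
    dplyr::filter(.data$trait %in% traits, !is.na(.data$value))
  missing_ids <- setdiff(unique(dat$genotype_id), ids)
  if (length(missing_ids)) {
    stop("phenotyped genotype(s) absent from G: ",
         paste(head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  zerovar <- dat |>
    dplyr::summarise(v = stats::var(.data$value), .by = "trait") |>
    dplyr::filter(is.na(.data$v) | .data$v == 0)
  if (nrow(zerovar)) {
    stop("trait(s) with zero phenotypic variance: ",
         paste(zerovar$trait, collapse = ", "), call. = FALSE)
  }

  Gm <- regularize_grm(unclass(G))
  ev <- eigen(Gm, symmetric = TRUE)
  logdetG <- sum(log(ev$values))
  Ginv <- ev$vectors %*% (t(ev$vectors) / ev$values)

  t_idx <- match(dat$trait, traits) - 1L
  g_idx <- match(dat$genotype_id, ids) - 1L
  # trait-specific fixed effects: intercept + site deviations per trait,
  # assembled block-diagonally so each trait has its own site profile
  blocks <- lapply(traits, function(tr) {
    rows <- dat$trait == tr
    s <- factor(dat$site[rows])
    Xt <- if (nlevels(s) > 1L) {
      stats::model.matrix(~s)
    } else {
      matrix(1, sum(rows), 1)
    }
    list(rows = which(rows), X = Xt)
  })
  p_tot <- sum(vapply(blocks, function(b) ncol(b$X), integer(1)))
  X <- matrix(0, nrow(dat), p_tot)
  off <- 0L
  for (b in blocks) {
    X[b$rows, off + seq_len(ncol(b$X))] <- b$X
    off <- off + ncol(b$X)
  }

  # warm starts from phenotypic (co)variances of genotype means
  wide <- dat |>
    dplyr::summarise(value = mean(.data$value),
                     .by = c("genotype_id", "trait")) |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value")
  P <- stats::cov(as.matrix(wide[, traits, drop = FALSE]),
                  use = "pairwise.complete.obs")
  P[!is.finite(P)] <- 0
  Ta0 <- P / 2 + diag(diag(P) / 4 + 1e-4, length(traits))
  R0 <- pmax(diag(P) / 2, 1e-4)

  fit <- reml_fit_cpp(dat$value, t_idx, g_idx, X, Gm, Ginv, logdetG,
                      Ta0, R0, as.integer(max_iter), tol,
                      n_em = 3L, use_ai = (method == "ai"))
  if (!fit$converged) {
    stop("REML did not converge in ", max_iter, " iterations; ",
         "log-likelihood trace: ",
         paste(sprintf("%.4f", utils::tail(fit$loglik, 5)), collapse = ", "),
         call. = FALSE)
  }
  Ta <- fit$Ta
  dimnames(Ta) <- list(traits, traits)
  blups <- tibble::as_tibble(fit$g, .name_repair = ~traits) |>
    dplyr::mutate(genotype_id = ids, .before = 1)
  pev <- tibble::as_tibble(fit$pev, .name_repair = ~traits) |>
    dplyr::mutate(genotype_id = ids, .before = 1)
  structure(list(
    traits = traits,
    Ta = Ta,
    residual = setNames(as.numeric(fit$sigma2), traits),
    beta = as.numeric(fit$beta),
    blups = blups,
    pev = pev,
    Cgg = setNames(fit$Cgg, traits),
    loglik = as.numeric(fit$loglik),
    converged = fit$converged,
    iterations = fit$iterations,
    method = method,
    n_records = nrow(dat)
  ), class = "gblup")
}

#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("GBLUP fit (%s-REML): %s; %d records, %d genotypes\n",
              toupper(x$method), paste(x$traits, collapse = " + "),
              x$n_records, nrow(x$blups)))
  cat(sprintf("  converged in %d iterations; logL %.4f\n",
              x$iterations, utils::tail(x$loglik, 1)))
  for (tr in x$traits) {
    cat(sprintf("  %s: sigma2_g = %.4f, sigma2_e = %.4f, H2 = %.3f\n",
                tr, x$Ta[tr, tr], x$residual[tr], heritability(x, tr)))
  }
  invisible(x)
}

#' Genetic correlations from a multitrait fit
#'
#' `r_ab = Ta_ab / sqrt(Ta_aa * Ta_bb)`. Traits whose genetic variance is
#' (numerically) zero get missing correlations with a warning.
#'
#' @param fit A `"gblup"` fit with at least 2 traits.
#' @return t x t correlation matrix with unit diagonal.
#' @export
genetic_correlations <- function(fit) {
  stopifnot(inherits(fit, "gblup"))
  if (length(fit$traits) < 2L) stop("need a multitrait fit", call. = FALSE)
  v <- diag(fit$Ta)
  r <- fit$Ta / sqrt(outer(v, v))
  diag(r) <- 1
  bad <- v <= 1e-12
  if (any(bad)) {
    warning("zero genetic variance for: ",
            paste(fit$traits[bad], collapse = ", "),
            "; correlations undefined")
    r[bad, ] <- NA_real_
    r[, bad] <- NA_real_
    diag(r) <- 1
  }
  r
}

#' Cullis-style heritability on a genotype-difference basis
#'
#' `H2 = 1 - vbar_delta / (2 * sigma2_g)` where `vbar_delta` is the mean
#' prediction error variance of a BLUP difference,
#' `mean_{i<j}(PEV_ii + PEV_jj - 2 PEV_ij)`, taken from the genotype block
#' of the inverse mixed-model-equation coefficient matrix. The value is
#' clipped to `[0, 1]`.
#'
#' @param fit A converged `"gblup"` fit.
#' @param trait Trait name (default: first fitted trait).
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(fit, trait = fit$traits[1]) {
  stopifnot(inherits(fit, "gblup"), trait %in% fit$traits)
  sg2 <- fit$Ta[trait, trait]
  if (sg2 <= 1e-12) {
    warning("zero genetic variance for ", trait, "; heritability 0")
    return(0)
  }
  P <- fit$Cgg[[trait]]
  q <- nrow(P)
  vbar <- 2 * (q * sum(diag(P)) - sum(P)) / (q * (q - 1))
  min(max(1 - vbar / (2 * sg2), 0), 1)
}

#' Tidy a GBLUP fit: breeding values with prediction error variances
#'
#' @param x A `"gblup"` fit.
#' @param ... Unused.
#' @return Tibble `genotype_id`, `trait`, `blup`, `pev`, `reliability`.
#' @exportS3Method generics::tidy
tidy.gblup <- function(x, ...) {
  b <- tidyr::pivot_longer(x$blups, -"genotype_id",
                           names_to = "trait", values_to = "blup")
  p <- tidyr::pivot_longer(x$pev, -"genotype_id",
                           names_to = "trait", values_to = "pev")
  dplyr::left_join(b, p, by = c("genotype_id", "trait")) |>
    dplyr::mutate(reliability = pmax(0, 1 - .data$pev / diag(x$Ta)[.data$trait]))
}

#' @exportS3Method generics::glance
glance.gblup <- function(x, ...) {
  tibble::tibble(
    traits = paste(x$traits, collapse = "+"),
    n_records = x$n_records,
    n_genotypes = nrow(x$blups),
    logLik = utils::tail(x$loglik, 1),
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Multitrait fits per region-by-subpopulation combination
#'
#' The panel-level analysis runs the single-/multitrait model within each
#' breeding region x subpopulation cell to keep genotype-by-environment
#' interaction out of the genetic correlations. This driver splits the
#' aggregated phenotypes accordingly, fits each combination with
#' [fit_gblup()] on the matching slice of `G`, and collects genetic
#' correlations and biomass heritability. Combinations with fewer than
#' `min_genotypes` phenotyped genotypes are skipped with a warning, as are
#' combinations whose fit fails.
#'
#' @param table Aggregated phenotype tibble.
#' @param info Genotype metadata (`genotype_id`, `subpopulation`).
#' @param sites Site metadata (`site`, `region`), e.g.
#'   [switchgrass_sites()].
#' @param G Relationship matrix covering all genotypes.
#' @param traits Traits for the joint fit.
#' @param min_genotypes Minimum phenotyped genotypes per combination.
#' @param ... Passed to [fit_gblup()].
#' @return Tibble with one row per fitted combination: `region`,
#'   `subpopulation`, `n_genotypes`, `h2_biomass`, one `rg_*` column per
#'   trait pair, and the `"gblup"` object in a `fit` list-column.
#' @export
fit_gblup_grouped <- function(table, info, sites, G,
                              traits = c("biomass", "fall_height",
                                         "flowering_time"),
                              min_genotypes = 30L, ...) {
  check_phenotypes(table)
  dat <- table |>
    dplyr::inner_join(dplyr::select(info, "genotype_id", "subpopulation"),
                      by = "genotype_id") |>
    dplyr::inner_join(dplyr::select(sites, "site", "region"), by = "site")
  combos <- dat |>
    dplyr::distinct(.data$region, .data$subpopulation, .data$genotype_id) |>
    dplyr::count(.data$region, .data$subpopulation, name = "n_genotypes")
  small <- dplyr::filter(combos, .data$n_genotypes < min_genotypes)
  if (nrow(small)) {
    warning("skipping combination(s) with < ", min_genotypes, " genotypes: ",
            paste(small$region, small$subpopulation, sep = ":",
                  collapse = ", "))
  }
  combos <- dplyr::filter(combos, .data$n_genotypes >= min_genotypes)
  purrr::pmap(combos, function(region, subpopulation, n_genotypes) {
    sub <- dplyr::filter(dat, .data$region == region,
                         .data$subpopulation == subpopulation)
    ids <- sort(unique(sub$genotype_id))
    fit <- tryCatch(
      fit_gblup(sub[, c("genotype_id", "site", "trait", "value")],
                unclass(G)[ids, ids], traits = traits, ...),
      error = function(e) {
        warning(region, ":", subpopulation, " fit failed: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(fit)) return(NULL)
    out <- tibble::tibble(region = region, subpopulation = subpopulation,
                          n_genotypes = n_genotypes,
                          h2_biomass = if ("biomass" %in% traits)
                            heritability(fit, "biomass") else NA_real_)
    if (length(traits) > 1) {
      rg <- genetic_correlations(fit)
      for (a in seq_along(traits)) for (b in seq_len(a - 1)) {
        out[[paste0("rg_", traits[b], "_", traits[a])]] <- rg[traits[b], traits[a]]
      }
    }
    out$fit <- list(fit)
    out
  }) |> purrr::list_rbind()
}
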