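# small balanced single-trait dataset used by several oracle checks
toy_gblup_data <- function(q = 6, seed = 5, sg = 1.2, se = 1) {
  set.seed(seed)
  ids <- sprintf("g%02d", seq_len(q))
  W <- matrix(rbinom(q * 80, 2, 0.5), q, 80,
              dimnames = list(ids, sprintf("m%02d", 1:80)))
  G <- realized_relationship(W)
  gt <- draw_gvalues(G, scale = sg, seed = seed + 1)
  tab <- tidyr::expand_grid(genotype_id = ids, site = c("S1", "S2")) |>
    dplyr::mutate(trait = "biomass",
                  value = 10 + (site == "S2") * 2 +
                    gt[genotype_id, 1] + rnorm(2 * q, 0, se))
  list(tab = tab, G = G, ids = ids)
}

# direct REML likelihood on the V matrix: the independent oracle
profile_reml_oracle <- function(tab, G, ids) {
  Gm <- unclass(G) + diag(1e-6, length(ids))
  y <- tab$value
  Z <- stats::model.matrix(~ 0 + factor(genotype_id, levels = ids), tab)
  X <- stats::model.matrix(~ factor(site), tab)
  negll <- function(p) {
    V <- exp(p[1]) * Z %*% Gm %*% t(Z) + exp(p[2]) * diag(length(y))
    Vi <- solve(V)
    B <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(B, t(X) %*% Vi)
    0.5 * (determinant(V)$modulus + determinant(B)$modulus + t(y) %*% P %*% y)[1]
  }
  o <- stats::optim(c(0, 0), negll, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))
  exp(o$par)
}

test_that("single-trait REML matches profile-likelihood maximisation", {
  d <- toy_gblup_data()
  fit <- fit_gblup(d$tab, d$G, traits = "biomass", tol = 1e-8)
  oracle <- profile_reml_oracle(d$tab, d$G, d$ids)
  expect_lt(abs(fit$Ta[1, 1] - oracle[1]), 1e-4)
  expect_lt(abs(fit$residual[["biomass"]] - oracle[2]), 1e-4)
})

test_that("EM and AI optimizers agree and EM likelihood is monotone", {
  d <- toy_gblup_data(seed = 8)
  ai <- fit_gblup(d$tab, d$G, traits = "biomass", method = "ai", tol = 1e-8)
  em <- fit_gblup(d$tab, d$G, traits = "biomass", method = "em",
                  tol = 1e-8, max_iter = 2000)
  expect_lt(abs(ai$Ta[1, 1] - em$Ta[1, 1]), 1e-4)
  expect_lt(abs(ai$residual - em$residual), 1e-4)
  expect_true(all(diff(em$loglik) > -1e-8))
})

test_that("pure-noise phenotypes give near-zero heritability", {
  set.seed(31)
  n <- 200
  d <- random_dosage(n, 1000, seed = 31)
  G <- realized_relationship(d)
  tab <- tidyr::expand_grid(genotype_id = rownames(G),
                            site = c("S1", "S2", "S3")) |>
    dplyr::mutate(trait = "biomass", value = rnorm(3 * n, 15, 2))
  fit <- fit_gblup(tab, G, traits = "biomass")
  ratio <- fit$Ta[1, 1] / (fit$Ta[1, 1] + fit$residual[["biomass"]])
  expect_lt(ratio, 0.05)
})

test_that("a duplicated trait shows near-unit genetic correlation", {
  set.seed(17)
  n <- 120
  G <- realized_relationship(random_dosage(n, 800, seed = 18))
  gt <- draw_gvalues(G, scale = 2, seed = 19)
  base <- tidyr::expand_grid(genotype_id = rownames(G),
                             site = c("S1", "S2")) |>
    dplyr::mutate(value = 20 + gt[genotype_id, 1] + rnorm(2 * n, 0, 1))
  tab <- dplyr::bind_rows(
    dplyr::mutate(base, trait = "biomass"),
    dplyr::mutate(base, trait = "fall_height",
                  value = value + rnorm(2 * n, 0, 0.05)))
  fit <- fit_gblup(tab, G, traits = c("biomass", "fall_height"))
  r <- genetic_correlations(fit)
  expect_gt(r["biomass", "fall_height"], 0.99)
  expect_equal(diag(r), c(biomass = 1, fall_height = 1))

  # diagonal Ta arithmetic for the correlation rule
  fake <- fit
  fake$Ta <- matrix(c(4, 2, 2, 4), 2,
                    dimnames = list(fit$traits, fit$traits))
  expect_equal(genetic_correlations(fake)["biomass", "fall_height"], 0.5)
  fake$Ta <- diag(c(3, 5)); dimnames(fake$Ta) <- list(fit$traits, fit$traits)
  expect_equal(genetic_correlations(fake),
               diag(2), ignore_attr = TRUE)
})

test_that("PEV and Cullis heritability match a from-scratch MME computation", {
  d <- toy_gblup_data(seed = 23)
  fit <- fit_gblup(d$tab, d$G, traits = "biomass", tol = 1e-8)
  # rebuild the mixed-model equations at the converged components
  sg2 <- fit$Ta[1, 1]; se2 <- fit$residual[["biomass"]]
  Gm <- unclass(d$G) + diag(1e-6, length(d$ids))
  Z <- stats::model.matrix(~ 0 + factor(genotype_id, levels = d$ids), d$tab)
  X <- stats::model.matrix(~ factor(site), d$tab)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + se2 / sg2 * solve(Gm)))
  Cinv <- solve(C) * se2
  P <- Cinv[-(1:2), -(1:2)]
  expect_equal(fit$pev$biomass, unname(diag(P)), tolerance = 1e-6)
  q <- length(d$ids)
  vbar <- 2 * (q * sum(diag(P)) - sum(P)) / (q * (q - 1))
  expect_equal(heritability(fit), 1 - vbar / (2 * sg2), tolerance = 1e-6)
})

test_that("heritability limits behave: perfect information and zero variance", {
  d <- toy_gblup_data(seed = 29)
  fit <- fit_gblup(d$tab, d$G, traits = "biomass")
  # PEV -> 0 limit pushes H2 -> 1
  fake <- fit
  fake$Cgg$biomass <- fit$Cgg$biomass * 1e-8
  expect_gt(heritability(fake), 0.999)
  # zero genetic variance reports 0 with a warning
  fake2 <- fit
  fake2$Ta[1, 1] <- 0
  expect_warning(h <- heritability(fake2), "zero genetic variance")
  expect_equal(h, 0)
  # zero-variance input trait errors up front
  tab0 <- dplyr::mutate(d$tab, value = 5)
  expect_error(fit_gblup(tab0, d$G), "zero phenotypic variance")
})

test_that("multitrait fits beat single-trait fits for biomass information", {
  # directional: with correlated traits, the multitrait machinery yields
  # higher biomass heritability than the biomass-only fit
  fx <- small_fixture()
  agg <- aggregate_phenotypes(fx$phenotypes)
  f1 <- fit_gblup(agg, fx$truth$G, traits = "biomass")
  f3 <- fit_gblup(agg, fx$truth$G,
                  traits = c("biomass", "fall_height", "flowering_time"))
  expect_gt(heritability(f3, "biomass"), heritability(f1, "biomass"))

  td <- tidy(f3)
  expect_setequal(names(td), c("genotype_id", "trait", "blup", "pev",
                               "reliability"))
  expect_true(all(td$reliability >= 0 & td$reliability <= 1))
  expect_true(glance(f3)$converged)
})

test_that("region-by-subpopulation driver fits large cells and skips small ones", {
  fx <- small_fixture()
  agg <- aggregate_phenotypes(fx$phenotypes)
  suppressWarnings(
    out <- fit_gblup_grouped(agg, fx$info, switchgrass_sites(), fx$truth$G,
                             min_genotypes = 30)
  )
  expect_gt(nrow(out), 0)
  expect_true(all(out$n_genotypes >= 30))
  expect_true(all(out$h2_biomass >= 0 & out$h2_biomass <= 1))
  expect_true(all(abs(out$rg_biomass_fall_height) <= 1))
  expect_s3_class(out$fit[[1]], "gblup")
  # a tight threshold drops every combination, with a warning naming them
  expect_warning(
    none <- fit_gblup_grouped(agg, fx$info, switchgrass_sites(), fx$truth$G,
                              min_genotypes = 10000),
    "skipping")
  expect_equal(nrow(none), 0L)
})
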