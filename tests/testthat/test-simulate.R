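test_that("Balding-Nichols divergence behaves in both limits", {
  # F -> 0: subpopulation frequencies collapse onto the ancestral ones
  # enough individuals per subpopulation that binomial sampling noise in
  # the realized frequencies stays below the divergence being tested
  cfg0 <- sim_config(n_genotypes = c(Texas = 250, Coastal = 250,
                                     Midwest = 250, Gulf = 250),
                     n_markers = 2000L, fst = 1e-4, missing_rate = 0)
  gen0 <- simulate_genotypes(cfg0, seed = 7)
  p_by_pop <- sapply(split(seq_len(nrow(gen0$dosage)),
                           gen0$info$subpopulation),
                     function(ix) colMeans(gen0$dosage[ix, , drop = FALSE]) / 2)
  dp <- abs(p_by_pop - rowMeans(p_by_pop))
  expect_lt(mean(dp), 0.02)

  # F = 0.15: Hudson FST estimator lands near the target
  cfg <- sim_config(n_genotypes = c(Texas = 60, Coastal = 60,
                                    Midwest = 60, Gulf = 60),
                    n_markers = 5000L, fst = 0.15, missing_rate = 0)
  gen <- simulate_genotypes(cfg, seed = 8)
  pops <- split(seq_len(nrow(gen$dosage)), gen$info$subpopulation)
  hudson_fst <- function(d1, d2) {
    p1 <- colMeans(d1) / 2; p2 <- colMeans(d2) / 2
    n1 <- 2 * nrow(d1); n2 <- 2 * nrow(d2)
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    mean(num) / mean(den)
  }
  pairs <- utils::combn(names(pops), 2)
  fsts <- apply(pairs, 2, function(pr) {
    hudson_fst(gen$dosage[pops[[pr[1]]], ], gen$dosage[pops[[pr[2]]], ])
  })
  expect_lt(abs(mean(fsts) - 0.15), 0.03)

  # determinism
  gen2 <- simulate_genotypes(cfg, seed = 8)
  expect_identical(gen$dosage, gen2$dosage)
})

test_that("the noiseless limit preserves breeding-value rankings per site", {
  cfg <- sim_config(n_genotypes = c(Texas = 15, Coastal = 15,
                                    Midwest = 15, Gulf = 15),
                    n_markers = 400L,
                    h2 = c(biomass = 1, fall_height = 1, flowering_time = 1),
                    decay = 0, missing_rate = 0,
                    dead_threshold = -Inf)
  gen <- simulate_genotypes(cfg, seed = 9)
  sim <- simulate_phenotypes(gen$dosage, gen$info, cfg, seed = 10)
  agg <- aggregate_phenotypes(sim$phenotypes)
  bio <- dplyr::filter(agg, trait == "biomass")
  for (s in unique(bio$site)) {
    sub <- dplyr::filter(bio, site == s)
    bv <- sim$truth$bv[sub$genotype_id, s]
    # sqrt-scale truncation at 0 never triggers here (means >> 0)
    expect_equal(order(sub$value), order(bv))
  }
})

test_that("trait genetic correlations are realized near their targets", {
  cfg <- sim_config(n_genotypes = c(Texas = 150, Coastal = 190,
                                    Midwest = 85, Gulf = 75),
                    n_markers = 1000L, missing_rate = 0)
  # population structure shrinks the effective sample size well below 500,
  # so the realized correlation is averaged over a few draws
  rr <- sapply(1:3, function(k) {
    gen <- simulate_genotypes(cfg, seed = 12 + k)
    sim <- simulate_phenotypes(gen$dosage, gen$info, cfg, seed = 112 + k)
    b <- sim$truth$biomass_factor
    c(cor(b, sim$truth$bv[, "fall_height"]),
      cor(b, sim$truth$bv[, "flowering_time"]))
  })
  expect_lt(abs(mean(rr[1, ]) - 0.85), 0.05)
  expect_lt(abs(mean(rr[2, ]) - 0.45), 0.08)

  gen <- simulate_genotypes(cfg, seed = 12)
  sim <- simulate_phenotypes(gen$dosage, gen$info, cfg, seed = 13)

  # the recorded truth covariance is exactly the one used to draw BVs
  expect_equal(dim(sim$truth$Ta), c(12L, 12L))
  expect_equal(diag(sim$truth$Ta)[1:10],
               rep(cfg$sigma_g[["biomass"]]^2, 10), ignore_attr = TRUE)
  off_scale <- sim$truth$Ta["KING", "fall_height"] /
    sqrt(sim$truth$Ta["KING", "KING"] * sim$truth$Ta["fall_height", "fall_height"])
  expect_lt(abs(off_scale), 0.85)  # site-specific BV correlates below the factor-level target
})

test_that("year-level noise hits the target heritability per column", {
  cfg <- sim_config(n_genotypes = c(Texas = 100, Coastal = 100,
                                    Midwest = 100, Gulf = 100),
                    n_markers = 800L, missing_rate = 0,
                    dead_threshold = -Inf)
  gen <- simulate_genotypes(cfg, seed = 14)
  sim <- simulate_phenotypes(gen$dosage, gen$info, cfg, seed = 15)
  # ANOVA-style oracle on the truth: per site, var(genetic) / var(year obs)
  ph <- dplyr::filter(sim$phenotypes, trait == "biomass", value > 0)
  h2_site <- vapply(unique(ph$site), function(s) {
    sub <- dplyr::filter(ph, site == s)
    gv <- sim$truth$bv[sub$genotype_id, s]
    var(gv[!duplicated(sub$genotype_id)]) / var(sub$value)
  }, numeric(1))
  expect_lt(abs(mean(h2_site) - cfg$h2[["biomass"]]), 0.1)
})

test_that("replication profile and site correlations follow the design", {
  fx <- paperlike_fixture()
  expect_equal(unname(table(fx$info$subpopulation)[c("Texas", "Coastal",
                                                     "Midwest", "Gulf")]),
               c(119L, 147L, 67L, 51L), ignore_attr = TRUE)
  counts <- fx$phenotypes |>
    dplyr::filter(trait == "biomass") |>
    dplyr::summarise(n = dplyr::n_distinct(site), .by = genotype_id)
  expect_lt(abs(mean(counts$n >= 8) - 0.53), 0.08)
  expect_lt(abs(mean(counts$n <= 5) - 0.36), 0.08)

  # configured decay: North-South correlations ~0.15, within-region ~0.8
  C <- fx$truth$site_cor
  s <- switchgrass_sites()
  expect_lt(abs(C["KING", "BRKG"] - exp(-0.12 * abs(s$latitude[s$site == "KING"] -
                                                      s$latitude[s$site == "BRKG"]))), 1e-12)
  expect_lt(C["KING", "BRKG"], 0.2)
  expect_gt(C["KING", "PKLE"], 0.65)
})

test_that("fixtures are self-contained and parse back losslessly", {
  fx <- tiny_fixture()
  expect_true(all(file.exists(unlist(fx$paths))))
  d <- read_dosage(fx$paths$dosage)
  expect_equal(d, fx$dosage)
  ph <- read_phenotypes(fx$paths$phenotypes)
  expect_equal(ph$value, fx$phenotypes$value, tolerance = 1e-12)
  st <- read_sites(fx$paths$sites)
  expect_equal(st$site, fx$config$sites$site)
  skip_if_not_installed("jsonlite")
  truth <- jsonlite::read_json(fx$paths$truth, simplifyVector = TRUE)
  expect_equal(as.numeric(truth$Ta[1, 1]), unname(fx$truth$Ta[1, 1]),
               tolerance = 1e-12)
})

test_that("invalid correlation targets are rejected", {
  expect_error(sim_config(r_bh = 0.99, r_bf = 0.99, r_hf = -0.9), "PSD")
})
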