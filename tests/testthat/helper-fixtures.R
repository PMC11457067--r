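# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_fixture <- function() {
  cached("tiny", function() make_fixture("tiny", seed = 101, dir = tempfile()))
}

small_fixture <- function() {
  cached("small", function() make_fixture("small", seed = 202, dir = tempfile()))
}

paperlike_fixture <- function() {
  cached("paperlike", function() make_fixture("paperlike", seed = 303,
                                              dir = tempfile()))
}

# random dosage matrix with optional missingness
random_dosage <- function(n, m, p = NULL, missing = 0, seed = 1) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.9)
  d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m,
              dimnames = list(sprintf("ind%03d", seq_len(n)),
                              sprintf("mk%04d", seq_len(m))))
  if (missing > 0) d[sample(length(d), round(missing * length(d)))] <- NA
  d
}

# genetic values drawn from N(0, G) (names attached)
draw_gvalues <- function(G, ncol = 1, scale = 1, seed = 1) {
  set.seed(seed)
  n <- nrow(G)
  L <- chol(unclass(G) + diag(1e-6, n))
  x <- crossprod(L, matrix(rnorm(n * ncol), n, ncol)) * scale
  rownames(x) <- rownames(G)
  x
}

# long phenotype tibble from a genotype x site matrix of one trait
pheno_from_matrix <- function(M, trait = "biomass") {
  tibble::as_tibble(M, rownames = "genotype_id") |>
    tidyr::pivot_longer(-"genotype_id", names_to = "site",
                        values_to = "value") |>
    dplyr::mutate(trait = trait) |>
    dplyr::filter(!is.na(.data$value))
}
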