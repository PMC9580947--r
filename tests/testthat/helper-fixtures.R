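# Small deterministic fixtures shared across the suite.

# binary genotype matrix with independent markers
rand_geno <- function(n, m, seed, p = 0.5) {
  set.seed(seed)
  matrix(rbinom(n * m, 1L, p), n, m)
}

# a trait with a couple of strong, known effects
two_marker_trait <- function(X, b1 = 2, b2 = -1.5, sd = 0.3, seed = 99) {
  set.seed(seed)
  drop(X[, 3] * b1 + X[, 7] * b2) + rnorm(nrow(X), sd = sd)
}

# hand-built basis rvm holding given marker indices / weights, for tests of
# ranking arithmetic that must not depend on the fitting path
fake_basis_model <- function(markers, weights, n_basis = 100L) {
  structure(list(basis_kind = "linear_basis",
                 active = as.integer(markers) + 1L,  # column 1 = intercept
                 weights = as.numeric(weights),
                 alpha = rep(1, length(markers)),
                 sigma2 = 1, target_mean = 0,
                 n_train = 10L, n_basis = n_basis, notes = NULL),
            class = "rvm")
}

# genotype/phenotype tables on disk for io tests
write_toy_tables <- function(dir, n = 5, m = 4, seed = 11, missing_at = NULL) {
  X <- rand_geno(n, m, seed)
  rownames(X) <- paste0("ind", seq_len(n))
  colnames(X) <- sprintf("chr%d:%d", rep(1:2, length.out = m),
                         5000L * seq_len(m))
  t <- rnorm(n)
  P <- matrix(t, ncol = 1, dimnames = list(rownames(X), "growth"))
  if (!is.null(missing_at)) P[missing_at, 1] <- NA
  gpath <- file.path(dir, "geno.tsv")
  ppath <- file.path(dir, "pheno.tsv")
  write_genotypes(X, gpath)
  write_phenotypes(P, ppath)
  list(X = X, P = P, gpath = gpath, ppath = ppath)
}
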