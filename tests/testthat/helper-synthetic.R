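# Builders for small synthetic inputs shared across test files.

# Three-group craniometric panel with configurable mean separation
# (in pooled-SD units along distinct axes).
make_panel <- function(sep = 10, n = 40, p = 4, seed = 42) {
  means <- list(A = rep(0, p),
                B = c(sep, rep(0, p - 1)),
                C = c(0, sep, rep(0, p - 2)))
  simulate_reference_panel(
    list(list(name = "A", n = n, mean = means$A),
         list(name = "B", n = n, mean = means$B),
         list(name = "C", n = n, mean = means$C)),
    covariance = diag(p), seed = seed)
}

# Hand-built panel whose pooled within-group covariance is exactly the
# identity: two identical groups of 4 axis-aligned points scaled so that
# SS / (N - k) = I.
identity_panel <- function() {
  a <- sqrt(1.5)
  pts <- rbind(c(a, 0), c(-a, 0), c(0, a), c(0, -a))
  colnames(pts) <- c("V1", "V2")
  reference_panel(list(G1 = pts, G2 = pts))
}

# One-variable panel with W = 1 exactly and group means 0 and delta.
two_group_1d_panel <- function(delta) {
  s <- 1 / sqrt(2)
  reference_panel(list(
    A = matrix(c(-s, s), ncol = 1, dimnames = list(NULL, "V1")),
    B = matrix(delta + c(-s, s), ncol = 1, dimnames = list(NULL, "V1"))))
}

# Ordinal trait model over two groups with adjustable divergence in [0, 1].
make_trait_model <- function(divergence = 0.5, traits = c("ANS", "INA"),
                             groups = c("G1", "G2"), n_levels = 3) {
  base <- rep(1 / n_levels, n_levels)
  shift <- divergence * (seq_len(n_levels) - mean(seq_len(n_levels))) /
    sum(abs(seq_len(n_levels) - mean(seq_len(n_levels))))
  probs <- list(pmax(base - shift, 0.01), pmax(base + shift, 0.01))
  probs <- lapply(probs, function(p) p / sum(p))
  model <- list()
  for (i in seq_along(groups)) {
    model[[groups[i]]] <- stats::setNames(
      rep(list(stats::setNames(probs[[i]], as.character(seq_len(n_levels)))),
          length(traits)), traits)
  }
  model
}

# Coefficient sets with known, hand-chosen equations for decision tests.
# Positive linear score = male-ward.
make_sets <- function() {
  eq <- function(name, a, b) list(name = name, intercept = a,
                                  coefficients = b)
  strong_male <- coefficient_set(list(
    eq("g_m", -6, c(glabella = 1, mastoid_process = 1)),
    eq("n_m", -6, c(nuchal_crest = 1, mastoid_process = 1)),
    eq("g_me", -9, c(glabella = 1, mastoid_process = 1,
                     mental_eminence = 1))), "SA-White")
  list(sa_white = strong_male,
       sa_black = coefficient_set(strong_male$equations, "SA-Black"),
       pooled = coefficient_set(strong_male$equations, "pooled"))
}

# Random pseudo-haploid matrix with given missingness.
random_genotypes <- function(n = 4, m = 10, missing = 0, seed = 7) {
  set.seed(seed)
  calls <- matrix(stats::rbinom(n * m, 1, 0.5), n, m)
  if (missing > 0) calls[stats::runif(n * m) < missing] <- NA_integer_
  genotype_matrix(calls, sprintf("s%d", seq_len(n)),
                  sprintf("snp%d", seq_len(m)))
}
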