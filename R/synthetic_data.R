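#' Simulate a craniometric reference panel
#'
#' Draws per-group inter-landmark measurement vectors (in mm) from
#' multivariate normal distributions with group-specific means and a shared
#' positive-definite covariance, mirroring the equal-covariance assumption of
#' pooled within-group Mahalanobis classification.
#'
#' @param groups List of group specs, each a list with `name`, `n`
#'   (individuals, at least 2) and `mean` (numeric vector of length `p`).
#' @param covariance Shared `p x p` positive-definite covariance matrix.
#' @param seed Integer seed.
#' @param variables Optional measurement names; defaults to `M01..Mp`.
#' @return A [reference_panel()] object.
#' @examples
#' cov2 <- diag(2)
#' pan <- simulate_reference_panel(
#'   list(list(name = "A", n = 30, mean = c(0, 0)),
#'        list(name = "B", n = 30, mean = c(4, 0))),
#'   cov2, seed = 1)
#' @export
simulate_reference_panel <- function(groups, covariance, seed,
                                     variables = NULL) {
  covariance <- as.matrix(covariance)
  p <- ncol(covariance)
  if (!isSymmetric(covariance, tol = 1e-10)) {
    stop("covariance must be symmetric")
  }
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance must be positive-definite")
  if (is.null(variables)) variables <- sprintf("M%02d", seq_len(p))

  set.seed(seed)
  mats <- list()
  for (g in groups) {
    if (is.null(g$name) || is.null(g$n) || is.null(g$mean)) {
      stop("each group needs name, n and mean")
    }
    if (g$n < 2L) stop("group '", g$name, "' needs n >= 2")
    if (length(g$mean) != p) {
      stop("group '", g$name, "' mean has length ", length(g$mean),
           " but covariance is ", p, " x ", p)
    }
    x <- MASS::mvrnorm(g$n, mu = g$mean, Sigma = covariance)
    x <- matrix(x, nrow = g$n, ncol = p)
    colnames(x) <- variables
    mats[[g$name]] <- x
  }
  reference_panel(mats)
}

#' Simulate ordinal morphoscopic trait scores
#'
#' Draws, independently per trait, ordinal scores from each group's category
#' probabilities (the generative model behind naive-Bayes trait
#' classification).
#'
#' @param model Named list: group -> named list of traits -> probability
#'   vector whose names are the ordinal levels. Each vector must sum to 1.
#' @param n_per_group Number of individuals drawn per group.
#' @param seed Integer seed.
#' @return Data frame with columns `group`, `individual` and one integer
#'   column per trait.
#' @export
simulate_morphoscopic <- function(model, n_per_group, seed) {
  traits <- names(model[[1]])
  for (g in names(model)) {
    if (!identical(names(model[[g]]), traits)) {
      stop("group '", g, "' does not score the same traits as the first group")
    }
    for (tr in traits) {
      pv <- model[[g]][[tr]]
      if (is.null(names(pv))) {
        stop("probability vector for trait '", tr, "' in group '", g,
             "' must have level names")
      }
      if (abs(sum(pv) - 1) > 1e-12) {
        stop("probabilities for trait '", tr, "' in group '", g,
             "' sum to ", sum(pv), ", not 1")
      }
    }
  }
  set.seed(seed)
  rows <- list()
  for (g in names(model)) {
    scores <- sapply(traits, function(tr) {
      pv <- model[[g]][[tr]]
      as.integer(sample(names(pv), n_per_group, replace = TRUE, prob = pv))
    })
    scores <- matrix(scores, nrow = n_per_group,
                     dimnames = list(NULL, traits))
    rows[[g]] <- data.frame(group = g, individual = seq_len(n_per_group),
                            scores, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate structured pseudo-haploid genotypes (Balding-Nichols model)
#'
#' Per SNP, an ancestral allele frequency `p` is drawn uniformly from
#' `ancestral_freq_range`; each population's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F` the population's drift (FST)
#' parameter; haploid calls are Bernoulli draws, then masked missing
#' uniformly at rate `missingness`. This yields continental-style clusters
#' separable by genotype PCA.
#'
#' @param populations List of population specs, each a list with `name`, `n`
#'   and `fst` (in `(0, 1)`).
#' @param n_snps Number of SNPs.
#' @param ancestral_freq_range Interval within `(0, 1)` for ancestral
#'   frequencies.
#' @param missingness Fraction of calls masked missing, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A [genotype_matrix()] with `population_labels` set.
#' @export
simulate_genotypes <- function(populations, n_snps,
                               ancestral_freq_range = c(0.05, 0.95),
                               missingness = 0, seed = 1) {
  for (pop in populations) {
    if (is.null(pop$fst) || pop$fst <= 0 || pop$fst >= 1) {
      stop("fst must lie in (0, 1) for population '", pop$name, "'")
    }
  }
  if (missingness < 0 || missingness >= 1) {
    stop("missingness must lie in [0, 1)")
  }
  if (ancestral_freq_range[1] <= 0 || ancestral_freq_range[2] >= 1 ||
      ancestral_freq_range[1] >= ancestral_freq_range[2]) {
    stop("ancestral_freq_range must be an interval within (0, 1)")
  }

  set.seed(seed)
  p_anc <- stats::runif(n_snps, ancestral_freq_range[1],
                        ancestral_freq_range[2])
  n_total <- sum(vapply(populations, function(x) as.integer(x$n), 1L))
  calls <- matrix(NA_integer_, nrow = n_total, ncol = n_snps)
  labels <- character(n_total)
  ids <- character(n_total)
  row0 <- 0L
  for (pop in populations) {
    f <- pop$fst
    p_pop <- stats::rbeta(n_snps, p_anc * (1 - f) / f,
                          (1 - p_anc) * (1 - f) / f)
    idx <- row0 + seq_len(pop$n)
    calls[idx, ] <- matrix(
      stats::rbinom(pop$n * n_snps, 1L, rep(p_pop, each = pop$n)),
      nrow = pop$n)
    labels[idx] <- pop$name
    ids[idx] <- sprintf("%s_%03d", pop$name, seq_len(pop$n))
    row0 <- row0 + as.integer(pop$n)
  }
  if (missingness > 0) {
    mask <- stats::runif(length(calls)) < missingness
    calls[mask] <- NA_integer_
  }
  genotype_matrix(calls, ids, sprintf("snp%06d", seq_len(n_snps)),
                  population_labels = labels)
}

#' Simulate X/Y chromosome alignment counts
#'
#' Draws the number of sex-chromosome alignments hitting the Y as a binomial
#' with success probability set by the individual's true sex, the generative
#' model behind the Ry sexing statistic.
#'
#' @param true_sex Character vector of `"M"`/`"F"`.
#' @param n_total Total alignments to X+Y per individual (recycled).
#' @param p_y_male,p_y_female Probability an alignment hits the Y for males
#'   (default 0.09) and females (default 0.005).
#' @param seed Integer seed.
#' @return Data frame with columns `true_sex`, `n_y`, `n_x`.
#' @export
simulate_read_counts <- function(true_sex, n_total, p_y_male = 0.09,
                                 p_y_female = 0.005, seed = 1) {
  if (p_y_male < 0 || p_y_male > 1 || p_y_female < 0 || p_y_female > 1) {
    stop("p_y_male and p_y_female must lie in [0, 1]")
  }
  if (any(n_total < 0)) stop("n_total must be nonnegative")
  if (!all(true_sex %in% c("M", "F"))) stop("true_sex entries must be M or F")
  n <- length(true_sex)
  n_total <- rep_len(as.integer(n_total), n)
  p <- ifelse(true_sex == "M", p_y_male, p_y_female)
  set.seed(seed)
  n_y <- stats::rbinom(n, n_total, p)
  data.frame(true_sex = true_sex, n_y = n_y, n_x = n_total - n_y)
}
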