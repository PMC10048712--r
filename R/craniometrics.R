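#' Craniometric reference panel
#'
#' Bundles labeled reference groups of inter-landmark measurement vectors
#' and derives the sufficient statistics for pooled-covariance Mahalanobis
#' classification: group means, the grand mean, and the pooled within-group
#' covariance `W` (each group centered on its own mean before pooling,
#' divisor `N - k`).
#'
#' @param groups Named list of numeric matrices (individuals x measurements,
#'   mm), all with the same columns; at least 2 individuals per group.
#' @return An object of class `reference_panel` with elements `groups`,
#'   `variables`, `group_means`, `grand_mean`, `pooled_cov`, `n_per_group`.
#' @export
reference_panel <- function(groups) {
  if (length(groups) < 1L || is.null(names(groups))) {
    stop("groups must be a named list of measurement matrices")
  }
  groups <- lapply(groups, as.matrix)
  p <- ncol(groups[[1]])
  variables <- colnames(groups[[1]])
  if (is.null(variables)) {
    variables <- sprintf("M%02d", seq_len(p))
    groups <- lapply(groups, function(x) { colnames(x) <- variables; x })
  }
  n_g <- vapply(groups, nrow, 1L)
  if (any(n_g < 2L)) {
    stop("each reference group needs at least 2 individuals")
  }
  if (!all(vapply(groups, ncol, 1L) == p)) {
    stop("all groups must share the same measurement set")
  }

  group_means <- do.call(rbind, lapply(groups, colMeans))
  dimnames(group_means) <- list(names(groups), variables)
  pooled <- do.call(rbind, groups)
  grand_mean <- colMeans(pooled)
  N <- sum(n_g)
  k <- length(groups)
  if (N - k < 1L) stop("too few individuals to pool a covariance")
  ss <- matrix(0, p, p)
  for (g in names(groups)) {
    xc <- sweep(groups[[g]], 2, group_means[g, ])
    ss <- ss + crossprod(xc)
  }
  W <- ss / (N - k)
  dimnames(W) <- list(variables, variables)

  structure(list(groups = groups, variables = variables,
                 group_means = group_means, grand_mean = grand_mean,
                 pooled_cov = W, n_per_group = n_g),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("reference_panel:", length(x$groups), "groups,",
      length(x$variables), "measurements\n")
  print(x$n_per_group)
  invisible(x)
}

#' Within-group principal components of a reference panel
#'
#' Eigendecomposes the pooled within-group covariance `W` and builds a
#' whitened score transform: measurement vectors (centered on the panel
#' grand mean) are rotated onto the eigenvectors and scaled by
#' `1/sqrt(eigenvalue)`, so squared Euclidean distance in score space equals
#' Mahalanobis distance under `W`.
#'
#' @param panel A [reference_panel()].
#' @param retain Components to keep: `NULL` (default) keeps every component
#'   with eigenvalue above `1e-10` times the largest; a value in `(0, 1]` is
#'   a variance fraction; an integer `> 1` is a component count.
#' @return An object of class `cranio_pca` with the rotation, eigenvalues,
#'   centering vector and whitened group-mean scores.
#' @export
fit_within_group_pca <- function(panel, retain = NULL) {
  stopifnot(inherits(panel, "reference_panel"))
  e <- eigen(panel$pooled_cov, symmetric = TRUE)
  tol <- 1e-10 * max(e$values)
  if (is.null(retain)) {
    k <- sum(e$values > tol)
  } else if (retain > 1) {
    k <- as.integer(retain)
    if (k > length(e$values)) {
      stop("cannot retain ", k, " components from ",
           length(e$values), " measurements")
    }
    if (any(e$values[seq_len(k)] <= tol)) {
      stop("within-group covariance is singular over the requested ",
           "components; reduce the measurement set or retain fewer ",
           "components")
    }
  } else {
    cum <- cumsum(e$values) / sum(e$values)
    k <- which(cum >= retain)[1]
    k <- min(k, sum(e$values > tol))
  }
  vals <- e$values[seq_len(k)]
  vecs <- e$vectors[, seq_len(k), drop = FALSE]
  rotation <- sweep(vecs, 2, sqrt(vals), "/")  # p x k, whitening
  rownames(rotation) <- panel$variables

  model <- structure(list(rotation = rotation, eigenvalues = e$values,
                          retained_k = k, center = panel$grand_mean,
                          variables = panel$variables,
                          group_names = rownames(panel$group_means)),
                     class = "cranio_pca")
  model$group_scores <- pca_scores(model, panel$group_means)
  model
}

#' Whitened principal component scores
#'
#' @param model A `cranio_pca` model from [fit_within_group_pca()].
#' @param x Measurement vector, or matrix with one row per cranium.
#' @return Score matrix (rows = crania, columns = retained components).
#' @export
pca_scores <- function(model, x) {
  stopifnot(inherits(model, "cranio_pca"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && all(model$variables %in% colnames(x))) {
    x <- x[, model$variables, drop = FALSE]
  }
  if (ncol(x) != length(model$variables)) {
    stop("measurement vector has ", ncol(x), " variables; panel has ",
         length(model$variables))
  }
  na_col <- colSums(is.na(x)) > 0
  if (any(na_col)) {
    stop("missing measurement(s): ",
         paste(model$variables[na_col], collapse = ", "))
  }
  sweep(x, 2, model$center) %*% model$rotation
}

#' Classify a cranium's population affinity
#'
#' Computes the Mahalanobis generalized distance D-squared from the cranium
#' to every reference group mean (via whitened scores) and converts the
#' distances to posterior probabilities with an equal-prior softmax,
#' `exp(-D2/2) / sum(exp(-D2/2))`. Affinity is assigned to the group with
#' the lowest distance; exact ties are broken by group-name order with a
#' warning.
#'
#' @param x Measurement vector (named, or in panel variable order).
#' @param model A `cranio_pca` model.
#' @param id Optional cranium identifier.
#' @return An object of class `ancestry_classification` with elements
#'   `cranium_id`, `distances` (D-squared per group), `posteriors`,
#'   `assigned`.
#' @export
classify_ancestry <- function(x, model, id = NULL) {
  s <- pca_scores(model, x)
  d2 <- rowSums(sweep(model$group_scores, 2, as.numeric(s))^2)
  names(d2) <- model$group_names
  post <- softmax_posteriors(d2)
  winners <- names(d2)[d2 - min(d2) < 1e-12]
  if (length(winners) > 1L) {
    warning("tied minimal distances (", paste(winners, collapse = ", "),
            "); assigned by group-name order")
  }
  structure(list(cranium_id = id, distances = d2, posteriors = post,
                 assigned = sort(winners)[1]),
            class = "ancestry_classification")
}

# Equal-prior softmax over exp(-D2/2); shifted by the minimum for stability
# (assignment is invariant to adding a constant to all D2).
softmax_posteriors <- function(d2) {
  w <- exp(-(d2 - min(d2)) / 2)
  w / sum(w)
}

#' @export
print.ancestry_classification <- function(x, ...) {
  cat("ancestry:", x$assigned,
      sprintf("(posterior %.2f)\n", x$posteriors[x$assigned]))
  print(round(rbind(D2 = x$distances, posterior = x$posteriors), 3))
  invisible(x)
}

#' Classify a batch of crania
#'
#' @param X Matrix of measurement vectors (one row per cranium).
#' @param model A `cranio_pca` model.
#' @return Data frame with `id`, `assigned`, `posterior` and one `D2.<group>`
#'   column per reference group.
#' @export
classify_crania <- function(X, model) {
  X <- as.matrix(X)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  res <- lapply(seq_len(nrow(X)), function(i)
    classify_ancestry(X[i, ], model, id = ids[i]))
  d2 <- t(vapply(res, function(r) r$distances,
                 numeric(length(model$group_names))))
  colnames(d2) <- paste0("D2.", model$group_names)
  data.frame(id = ids,
             assigned = vapply(res, function(r) r$assigned, ""),
             posterior = vapply(res, function(r)
               unname(r$posteriors[r$assigned]), 1.0),
             d2, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Pairwise Mahalanobis distances among crania
#'
#' Distance (D, not D-squared) of each cranium from every other cranium,
#' computed as Euclidean distance between whitened scores.
#'
#' @param X Measurement matrix, one row per cranium (at least 2).
#' @param model A `cranio_pca` model.
#' @return Symmetric `n x n` matrix with zero diagonal.
#' @export
pairwise_mahalanobis <- function(X, model) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 crania")
  s <- pca_scores(model, X)
  D <- as.matrix(stats::dist(s))
  if (!is.null(rownames(X))) dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Principal coordinates analysis (Gower)
#'
#' Embeds a distance matrix into Euclidean axes: the squared distances are
#' double-centered, `B = -1/2 J (D o D) J` with `J = I - 11'/n`, and `B` is
#' eigendecomposed. Coordinates are eigenvectors scaled by the square root
#' of their (strictly positive) eigenvalues; axes with non-positive
#' eigenvalues are dropped. Axis signs are fixed deterministically: each
#' column's largest-magnitude entry is made positive.
#'
#' @param D Symmetric nonnegative distance matrix with zero diagonal.
#' @param tol Relative eigenvalue tolerance for retaining an axis.
#' @return An object of class `pcoord_result` with `coordinates`
#'   (`n x retained_k`), `eigenvalues` (all, descending) and `retained_k`.
#' @export
principal_coordinates <- function(D, tol = 1e-9) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n != ncol(D) || !isSymmetric(unname(D), tol = 1e-8)) {
    stop("D must be a symmetric distance matrix")
  }
  if (any(D < 0) || any(abs(diag(D)) > 1e-12)) {
    stop("D must be nonnegative with a zero diagonal")
  }
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D * D) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values), .Machine$double.eps)
  k <- sum(pos)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = k)
  for (j in seq_len(k)) {
    i0 <- which.max(abs(coords[, j]))
    if (coords[i0, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(D)
  colnames(coords) <- if (k > 0) paste0("PC", seq_len(k)) else character(0)
  structure(list(coordinates = coords, eigenvalues = e$values,
                 retained_k = k),
            class = "pcoord_result")
}

#' Pooled two-sample t-test on PC1 scores
#'
#' Tests whether principal-coordinate scores separate two affinity clusters,
#' using the pooled-variance two-sample t statistic with
#' `df = n1 + n2 - 2`.
#'
#' @param scores Numeric vector of PC1 scores.
#' @param labels Two-level grouping vector parallel to `scores`.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
pc1_group_ttest <- function(scores, labels) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) stop("labels must define exactly two groups")
  x <- scores[labels == lv[1]]
  y <- scores[labels == lv[2]]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 scores")
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Train a metric sex discriminant
#'
#' Two-class linear discriminant with pooled covariance over highly
#' dimorphic cranial dimensions (default: glabellar projection GLS,
#' bizygomatic breadth ZYB, mastoid height MDH), trained on a known-sex
#' reference sample. Posteriors use the same equal-prior `exp(-D2/2)`
#' normalization as ancestry classification.
#'
#' @param data Matrix or data frame of measurements (mm) with the
#'   discriminant variables as columns.
#' @param sex Character vector of `"M"`/`"F"` parallel to rows of `data`.
#' @param variables Discriminant variables, default `c("GLS","ZYB","MDH")`.
#' @return An object of class `sex_discriminant`.
#' @export
train_sex_discriminant <- function(data, sex,
                                   variables = c("GLS", "ZYB", "MDH")) {
  data <- as.matrix(data)
  if (!all(variables %in% colnames(data))) {
    stop("data lacks variable(s): ",
         paste(setdiff(variables, colnames(data)), collapse = ", "))
  }
  if (!all(sex %in% c("M", "F"))) stop("sex entries must be M or F")
  if (length(unique(sex)) < 2L) {
    stop("both sexes must be present in the training panel")
  }
  X <- data[, variables, drop = FALSE]
  mu <- rbind(M = colMeans(X[sex == "M", , drop = FALSE]),
              F = colMeans(X[sex == "F", , drop = FALSE]))
  n_m <- sum(sex == "M"); n_f <- sum(sex == "F")
  ss <- crossprod(sweep(X[sex == "M", , drop = FALSE], 2, mu["M", ])) +
        crossprod(sweep(X[sex == "F", , drop = FALSE], 2, mu["F", ]))
  W <- ss / (n_m + n_f - 2)
  Winv <- solve(W)
  w <- Winv %*% (mu["M", ] - mu["F", ])     # discriminant weights
  threshold <- sum(w * (mu["M", ] + mu["F", ])) / 2
  structure(list(variables = variables, class_means = mu,
                 pooled_cov = W, pooled_cov_inv = Winv,
                 weights = drop(w), threshold = threshold),
            class = "sex_discriminant")
}

#' Metric sex classification
#'
#' Classifies a cranium as male or female from the discriminant's
#' Mahalanobis distances to the class means. When the winning posterior is
#' within `ambiguity_margin` of 0.5, the call becomes a leaning category
#' (`"M/F"` or `"F/M"`, first letter = leaning side).
#'
#' @param x Measurement vector containing the discriminant variables.
#' @param discriminant A [train_sex_discriminant()] model.
#' @param ambiguity_margin Posterior margin below which a call is flagged as
#'   leaning; default 0.05.
#' @return An object of class `sex_call` with `category`
#'   (`M`, `F`, `M/F` or `F/M`), `posterior` (of the winning side) and
#'   `p_male`.
#' @export
classify_sex_metric <- function(x, discriminant, ambiguity_margin = 0.05) {
  stopifnot(inherits(discriminant, "sex_discriminant"))
  v <- discriminant$variables
  if (!is.null(names(x))) {
    if (!all(v %in% names(x))) {
      stop("missing variable(s): ",
           paste(setdiff(v, names(x)), collapse = ", "))
    }
    x <- x[v]
  }
  if (length(x) != length(v) || any(is.na(x))) {
    stop("measurement vector must supply ",
         paste(v, collapse = ", "), " without missing values")
  }
  d2 <- apply(discriminant$class_means, 1, function(mu) {
    d <- as.numeric(x) - mu
    drop(t(d) %*% discriminant$pooled_cov_inv %*% d)
  })
  post <- softmax_posteriors(d2)
  p_male <- unname(post["M"])
  if (p_male > 0.5) { side <- "M"; top <- p_male }
  else if (p_male < 0.5) { side <- "F"; top <- 1 - p_male }
  else {
    # exactly on the boundary: lean by the linear score's side
    score <- sum(discriminant$weights * as.numeric(x)) -
      discriminant$threshold
    side <- if (score >= 0) "M" else "F"
    top <- 0.5
  }
  category <- if (top >= 0.5 + ambiguity_margin) side
  else if (side == "M") "M/F" else "F/M"
  structure(list(category = category, posterior = top, p_male = p_male),
            class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("%s(%.2f)\n", x$category, x$posterior))
  invisible(x)
}
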