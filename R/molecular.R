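#' Ry statistic from X/Y alignment counts
#'
#' Fraction of sex-chromosome alignments hitting the Y,
#' `ry = n_y / (n_x + n_y)`, with a normal-approximation 95% confidence
#' interval `ry +/- 1.96 sqrt(ry (1 - ry) / n_total)` clipped to `[0, 1]`.
#' With zero total alignments a sentinel (`NA` ry) is returned rather than
#' an error.
#'
#' @param n_y,n_x Nonnegative integer alignment counts.
#' @return Object of class `ry_result` with `ry`, `ci` (length-2) and
#'   `n_total`.
#' @export
compute_ry <- function(n_y, n_x) {
  if (length(n_y) != 1L || length(n_x) != 1L ||
      is.na(n_y) || is.na(n_x) || n_y < 0 || n_x < 0 ||
      n_y != round(n_y) || n_x != round(n_x)) {
    stop("n_y and n_x must be single nonnegative integers")
  }
  n_total <- n_x + n_y
  if (n_total == 0) {
    return(structure(list(ry = NA_real_, ci = c(NA_real_, NA_real_),
                          n_total = 0L), class = "ry_result"))
  }
  ry <- n_y / n_total
  half <- 1.96 * sqrt(ry * (1 - ry) / n_total)
  ci <- c(max(0, ry - half), min(1, ry + half))
  structure(list(ry = ry, ci = ci, n_total = n_total), class = "ry_result")
}

#' Molecular sex call from the Ry statistic
#'
#' Thresholds the Ry estimate and its confidence interval into an XY / XX /
#' indeterminate call: XY when the CI lower bound clears the female cutoff
#' and the estimate reaches the male cutoff; XX when the CI upper bound is
#' below the male cutoff and the estimate is at or below the female cutoff;
#' anything else (including zero coverage) is indeterminate. Default
#' cutoffs are the published values of the ratio method
#' (`t_xx = 0.016`, `t_xy = 0.075`).
#'
#' @param ry_result A [compute_ry()] result.
#' @param t_xx,t_xy Female and male cutoffs, `t_xx < t_xy`.
#' @return Object of class `sex_assignment` with `category`
#'   (`"XY"`, `"XX"` or `"indeterminate"`), `ry` and `ci`.
#' @export
call_sex <- function(ry_result, t_xx = 0.016, t_xy = 0.075) {
  stopifnot(inherits(ry_result, "ry_result"))
  if (!(t_xx < t_xy)) stop("config error: t_xx must be below t_xy")
  ry <- ry_result$ry
  ci <- ry_result$ci
  category <- if (is.na(ry)) "indeterminate"
  else if (ci[1] > t_xx && ry >= t_xy) "XY"
  else if (ci[2] < t_xy && ry <= t_xx) "XX"
  else "indeterminate"
  structure(list(category = category, ry = ry, ci = ci),
            class = "sex_assignment")
}

#' Fit a reference genotype PCA
#'
#' PCA of a labeled reference panel of pseudo-haploid genotypes, in the
#' style of the standard population-genetics tools: SNPs are filtered on
#' call rate and minor-allele count, each surviving SNP is centered on its
#' mean call `p` and scaled by `sqrt(p (1 - p))`, missing entries contribute
#' zero after centering, and the top `k` right singular vectors give the
#' loadings.
#'
#' @param refs A [genotype_matrix()] with `population_labels` covering at
#'   least two populations.
#' @param k Components to retain (default 3).
#' @param min_call_rate Minimum fraction of non-missing calls per SNP.
#' @param min_mac Minimum minor-allele count per SNP (removes monomorphic
#'   SNPs).
#' @return Object of class `geno_pca` with loadings, per-SNP centering and
#'   scale, reference scores and population labels.
#' @export
fit_reference_pca <- function(refs, k = 3, min_call_rate = 0.5,
                              min_mac = 1) {
  stopifnot(inherits(refs, "genotype_matrix"))
  if (is.null(refs$population_labels) ||
      length(unique(refs$population_labels)) < 2L) {
    stop("reference panel needs population labels for >= 2 populations")
  }
  fully_missing <- sample_missingness(refs) >= 1
  if (any(fully_missing)) {
    stop("fully missing reference sample(s): ",
         paste(refs$sample_ids[fully_missing], collapse = ", "))
  }
  calls <- refs$calls
  called <- colSums(!is.na(calls))
  ones <- colSums(calls == 1L, na.rm = TRUE)
  mac <- pmin(ones, called - ones)
  keep <- (called / nrow(calls)) >= min_call_rate & mac >= min_mac
  if (sum(keep) < k) {
    stop("only ", sum(keep), " SNPs survive filtering; need at least ", k)
  }
  calls <- calls[, keep, drop = FALSE]
  p_bar <- colMeans(calls, na.rm = TRUE)
  scale <- sqrt(p_bar * (1 - p_bar))
  X <- sweep(sweep(calls, 2, p_bar), 2, scale, "/")
  X[is.na(X)] <- 0
  sv <- svd(X, nu = k, nv = k)
  loadings <- sv$v
  rownames(loadings) <- refs$snp_ids[keep]
  scores <- X %*% loadings
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- refs$sample_ids

  structure(list(snp_ids = refs$snp_ids[keep], center = p_bar,
                 scale = scale, loadings = loadings, scores = scores,
                 labels = list(continental = refs$population_labels),
                 sample_ids = refs$sample_ids, k = k),
            class = "geno_pca")
}

#' Project pseudo-haploid samples onto a reference PCA
#'
#' Least-squares projection using only each sample's observed SNPs (the
#' loadings restricted to the observed set), with centering and scaling
#' taken from the model; robust to the heavy, sample-specific missingness
#' of pseudo-haploid data. Samples whose overlap with the model SNPs falls
#' below `min_overlap` are skipped (scores `NA`) with a warning.
#'
#' @param model A [fit_reference_pca()] model.
#' @param unknowns A [genotype_matrix()].
#' @param min_overlap Minimum number of observed model SNPs per sample.
#' @return Score matrix (`n x k`) with attributes `n_overlap` (per-sample
#'   observed model SNPs) and `skipped` (ids of skipped samples).
#' @export
project_samples <- function(model, unknowns, min_overlap = 100) {
  stopifnot(inherits(model, "geno_pca"),
            inherits(unknowns, "genotype_matrix"))
  idx <- match(model$snp_ids, unknowns$snp_ids)
  if (all(is.na(idx))) stop("unknowns share no SNPs with the model")
  n <- length(unknowns$sample_ids)
  scores <- matrix(NA_real_, n, model$k,
                   dimnames = list(unknowns$sample_ids,
                                   paste0("PC", seq_len(model$k))))
  n_overlap <- integer(n)
  skipped <- character(0)
  for (i in seq_len(n)) {
    g <- rep(NA_integer_, length(model$snp_ids))
    has <- !is.na(idx)
    g[has] <- unknowns$calls[i, idx[has]]
    obs <- which(!is.na(g))
    n_overlap[i] <- length(obs)
    if (length(obs) < min_overlap) {
      skipped <- c(skipped, unknowns$sample_ids[i])
      next
    }
    xt <- (g[obs] - model$center[obs]) / model$scale[obs]
    L <- model$loadings[obs, , drop = FALSE]
    scores[i, ] <- qr.solve(crossprod(L), crossprod(L, xt))
  }
  if (length(skipped)) {
    warning("skipped sample(s) with < ", min_overlap, " observed model ",
            "SNPs: ", paste(skipped, collapse = ", "))
  }
  attr(scores, "n_overlap") <- stats::setNames(n_overlap,
                                               unknowns$sample_ids)
  attr(scores, "skipped") <- skipped
  scores
}

#' Assign projected samples to population clusters
#'
#' Nearest population-centroid assignment in the retained score space, with
#' the distances to the two nearest centroids reported for transparency.
#' Exact ties are broken lexicographically and flagged.
#'
#' @param scores Score matrix from [project_samples()].
#' @param model A `geno_pca` model.
#' @param level Label level to use (`"continental"` by default; further
#'   levels can be attached to `model$labels`).
#' @param labels Optional label vector overriding `model$labels[[level]]`.
#' @return Data frame with `sample`, `label`, `dist`, `runner_up`,
#'   `dist_runner_up`, `tie`.
#' @export
assign_cluster <- function(scores, model, level = "continental",
                           labels = NULL) {
  stopifnot(inherits(model, "geno_pca"))
  if (is.null(labels)) {
    labels <- model$labels[[level]]
    if (is.null(labels)) {
      stop("config error: model carries no labels at level '", level, "'")
    }
  }
  cent <- rowsum(model$scores, labels) / as.vector(table(labels)[
    sort(unique(labels))])
  out <- lapply(seq_len(nrow(scores)), function(i) {
    s <- scores[i, ]
    if (any(is.na(s))) {
      return(data.frame(sample = rownames(scores)[i], label = NA_character_,
                        dist = NA_real_, runner_up = NA_character_,
                        dist_runner_up = NA_real_, tie = NA))
    }
    d <- sqrt(rowSums(sweep(cent, 2, s)^2))
    ord <- order(d, names(d))
    data.frame(sample = rownames(scores)[i], label = names(d)[ord[1]],
               dist = d[ord[1]],
               runner_up = if (length(d) > 1) names(d)[ord[2]] else
                 NA_character_,
               dist_runner_up = if (length(d) > 1) d[ord[2]] else NA_real_,
               tie = length(d) > 1 &&
                 abs(d[ord[1]] - d[ord[2]]) < 1e-12)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Parse a haplogroup label to its macrohaplogroup
#'
#' For mitochondrial labels the text before any parenthetical is used; the
#' macro is the leading letter, except for the African L lineages where it
#' is the letter plus first digit (`L0`..`L6`). With `fine = TRUE` non-L
#' labels also keep a following digit (`U2d` -> `U2`). For Y labels in
#' SNP-based `X-M123` form the letter before the hyphen is used; otherwise
#' the leading letter of the alphanumeric haplogroup string.
#'
#' @param labels Character vector of raw haplogroup labels.
#' @param system `"mt"` or `"Y"`.
#' @param fine Mitochondrial only: report letter+digit for non-L macros.
#' @return Character vector of macro labels.
#' @examples
#' parse_macrohaplogroup("E1b1b1b2a1a1a1a", "Y")   # "E"
#' parse_macrohaplogroup("L2a (L2a1c)", "mt")      # "L2"
#' parse_macrohaplogroup("T1a", "mt")              # "T"
#' @export
parse_macrohaplogroup <- function(labels, system = c("mt", "Y"),
                                  fine = FALSE) {
  system <- match.arg(system)
  vapply(labels, function(raw) {
    lab <- trimws(sub("\\s*\\(.*$", "", raw))
    if (!nzchar(lab) || !grepl("^[A-Za-z]", lab)) {
      stop("unparseable haplogroup label: '", raw, "'")
    }
    if (system == "Y") {
      if (grepl("^[A-Za-z]+-", lab)) {
        return(toupper(sub("-.*$", "", lab)))
      }
      return(toupper(substr(lab, 1, 1)))
    }
    letter <- toupper(substr(lab, 1, 1))
    digit <- substr(lab, 2, 2)
    if (letter == "L") {
      if (!grepl("^[0-9]$", digit)) {
        stop("unparseable haplogroup label: '", raw,
             "' (L lineage without a clade digit)")
      }
      return(paste0(letter, digit))
    }
    if (fine && grepl("^[0-9]$", digit)) return(paste0(letter, digit))
    letter
  }, "", USE.NAMES = FALSE)
}

#' Macrohaplogroup frequency table
#'
#' Counts and percentages (2 decimals) of macrohaplogroups in a set of
#' labels. With `within`, the table is restricted to macros starting with
#' that prefix and percentages are taken within that subset (e.g. the share
#' of L3 among L carriers).
#'
#' @param labels Character vector of raw haplogroup labels.
#' @param system `"mt"` or `"Y"`.
#' @param within Optional macro prefix conditioning the denominator.
#' @param fine Passed to [parse_macrohaplogroup()].
#' @return Data frame with `macro`, `count`, `percent`, sorted by
#'   decreasing count.
#' @export
haplogroup_frequencies <- function(labels, system = c("mt", "Y"),
                                   within = NULL, fine = FALSE) {
  if (length(labels) < 1L) stop("need at least one label")
  macro <- parse_macrohaplogroup(labels, system, fine = fine)
  if (!is.null(within)) macro <- macro[startsWith(macro, within)]
  tab <- table(macro)
  out <- data.frame(macro = names(tab), count = as.integer(tab),
                    percent = round(100 * as.integer(tab) / sum(tab), 2),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$macro), , drop = FALSE]
}
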