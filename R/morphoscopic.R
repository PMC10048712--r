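# The 11 ordinal cranial nonmetric traits and the 5 sexually dimorphic
# traits used by the trait-equation framework.
.hefner_traits <- c("ANS", "INA", "IOB", "MT", "NAW", "NBC",
                    "NO", "PBD", "SPS", "TPS", "ZS")
.walker_traits <- c("nuchal_crest", "mastoid_process",
                    "supraorbital_margin", "glabella", "mental_eminence")

#' Default OSSA dichotomization config
#'
#' Recode tables mapping each of the six OSSA traits (ANS, INA, IOB, NAW,
#' NBC, PBD) onto `{0, 1}`, and the summed-score threshold (inclusive) above
#' which a cranium is classified White. These defaults follow the published
#' OSSA method and are fully overridable; they are not derived from any
#' particular case sample.
#'
#' @return List with elements `recode` (named list of level -> 0/1 maps)
#'   and `threshold` (default 4).
#' @export
default_ossa_config <- function() {
  list(
    recode = list(
      ANS = c("1" = 0, "2" = 0, "3" = 1),
      INA = c("1" = 0, "2" = 0, "3" = 0, "4" = 1, "5" = 1),
      IOB = c("1" = 0, "2" = 0, "3" = 1),
      NAW = c("1" = 0, "2" = 0, "3" = 1),
      NBC = c("0" = 0, "1" = 0, "2" = 0, "3" = 1, "4" = 1),
      PBD = c("0" = 1, "1" = 0)
    ),
    threshold = 4
  )
}

#' Optimized summed scored attributes (OSSA)
#'
#' Dichotomizes six morphoscopic trait scores via the recode tables, sums
#' them to a 0-6 score, and thresholds the sum into a binary Black/White
#' classification (score at or above the threshold is White).
#'
#' @param traits Named list or vector of ordinal trait scores containing at
#'   least the six OSSA traits.
#' @param config A config as returned by [default_ossa_config()].
#' @return List with `score` (integer 0-6) and `class`
#'   (`"Black"` or `"White"`).
#' @export
ossa_score <- function(traits, config = default_ossa_config()) {
  recode <- config$recode
  vals <- integer(length(recode))
  names(vals) <- names(recode)
  for (tr in names(recode)) {
    sc <- traits[[tr]]
    if (is.null(sc) || is.na(sc)) stop("missing OSSA trait: ", tr)
    key <- as.character(sc)
    if (!key %in% names(recode[[tr]])) {
      stop("config error: level ", key, " of trait ", tr,
           " has no recode entry")
    }
    vals[tr] <- recode[[tr]][[key]]
  }
  score <- sum(vals)
  list(score = score,
       class = if (score >= config$threshold) "White" else "Black")
}

#' Naive-Bayes morphoscopic ancestry classifier
#'
#' Four-group trait classifier in the style of web decision-support systems:
#' posterior for each group is proportional to
#' `prior * prod_t freq_g(level_t)` over the scored traits, with additive
#' (Jeffreys-style) smoothing of the level frequencies. Absent traits are
#' skipped.
#'
#' @param traits Named vector/list of ordinal scores (`NA` or missing
#'   entries are skipped).
#' @param model Named list: group -> named list of traits -> named vector of
#'   level counts (or frequencies).
#' @param priors Optional named prior over groups; default uniform.
#' @param smoothing Additive smoothing constant, default 0.5.
#' @return List with `posteriors` (named, summing to 1) and `top`.
#' @export
hefner_classify <- function(traits, model, priors = NULL, smoothing = 0.5) {
  groups <- names(model)
  if (is.null(groups)) stop("model must be a named list of groups")
  scored <- names(traits)[!vapply(traits, function(v)
    is.null(v) || is.na(v), TRUE)]
  scored <- intersect(scored, names(model[[1]]))
  if (length(scored) == 0L) stop("no scored trait is covered by the model")

  if (is.null(priors)) {
    priors <- stats::setNames(rep(1 / length(groups), length(groups)),
                              groups)
  }
  loglik <- stats::setNames(log(priors[groups]), groups)
  for (g in groups) {
    for (tr in scored) {
      freqs <- model[[g]][[tr]]
      if (is.null(freqs)) {
        stop("model for group '", g, "' does not cover trait '", tr, "'")
      }
      key <- as.character(traits[[tr]])
      if (!key %in% names(freqs)) {
        stop("level ", key, " of trait '", tr,
             "' is not represented in the model for group '", g, "'")
      }
      pr <- (freqs[[key]] + smoothing) /
        (sum(freqs) + smoothing * length(freqs))
      loglik[g] <- loglik[g] + log(pr)
    }
  }
  w <- exp(loglik - max(loglik))
  post <- w / sum(w)
  list(posteriors = post, top = names(post)[which.max(post)])
}

#' Build a coefficient set of trait sex equations
#'
#' @param equations List of equations; each equation is a list with `name`,
#'   `intercept` and `coefficients` (named by trait).
#' @param source Label for the reference sample the coefficients come from
#'   (e.g. `"SA-White"`, `"SA-Black"`, `"pooled"`).
#' @return Object of class `coefficient_set`.
#' @export
coefficient_set <- function(equations, source) {
  for (eq in equations) {
    bad <- setdiff(names(eq$coefficients), .walker_traits)
    if (length(bad)) {
      stop("unknown trait(s) in equation '", eq$name, "': ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(equations = equations, source = source),
            class = "coefficient_set")
}

#' Empty coefficient-set template
#'
#' The package does not ship published equation coefficients; users paste
#' them in, or fit their own with [fit_sex_equations()]. This returns the
#' trait subsets of the five default equations with `NA` coefficients.
#'
#' @param source Source label.
#' @return A `coefficient_set` with `NA` intercepts and coefficients.
#' @export
coefficient_template <- function(source = "unset") {
  sets <- list(
    c("glabella", "mastoid_process", "mental_eminence"),
    c("glabella", "mastoid_process"),
    c("mastoid_process", "mental_eminence"),
    c("glabella", "mental_eminence"),
    c("nuchal_crest", "mastoid_process")
  )
  eqs <- lapply(seq_along(sets), function(i) {
    list(name = paste0("eq", i), intercept = NA_real_,
         coefficients = stats::setNames(rep(NA_real_, length(sets[[i]])),
                                        sets[[i]]))
  })
  coefficient_set(eqs, source)
}

#' Fit trait-combination sex equations by logistic regression
#'
#' Fits, for each trait subset, a binomial GLM of maleness on the ordinal
#' trait scores, yielding a [coefficient_set()] usable with
#' [logistic_p_male()] and [decide_sex()]. Intended for building
#' population-specific equation sets from labeled (possibly synthetic)
#' trait data.
#'
#' @param scores Data frame with the trait columns.
#' @param sex Character vector of `"M"`/`"F"` parallel to rows.
#' @param trait_sets List of character vectors of trait names; defaults to
#'   the subsets in [coefficient_template()].
#' @param source Source label for the fitted set.
#' @return A `coefficient_set`.
#' @export
fit_sex_equations <- function(scores, sex, trait_sets = NULL,
                              source = "fitted") {
  if (is.null(trait_sets)) {
    tmpl <- coefficient_template()
    trait_sets <- lapply(tmpl$equations, function(e) names(e$coefficients))
  }
  y <- as.integer(sex == "M")
  eqs <- lapply(seq_along(trait_sets), function(i) {
    tr <- trait_sets[[i]]
    df <- data.frame(y = y, scores[, tr, drop = FALSE])
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = df, family = stats::binomial()))
    cf <- stats::coef(fit)
    list(name = paste0("eq", i), intercept = unname(cf[1]),
         coefficients = stats::setNames(unname(cf[-1]), tr))
  })
  coefficient_set(eqs, source)
}

#' Probability of male from one trait equation
#'
#' Evaluates `P(male) = 1 / (1 + exp(-(a + sum b_i score_i)))`; the
#' convention is that positive linear score is male-ward.
#'
#' @param traits Named vector/list of trait scores.
#' @param equation One equation (list with `intercept` and named
#'   `coefficients`).
#' @return `P(male)` in `[0, 1]`.
#' @export
logistic_p_male <- function(traits, equation) {
  need <- names(equation$coefficients)
  for (tr in need) {
    if (is.null(traits[[tr]]) || is.na(traits[[tr]])) {
      stop("missing trait for equation: ", tr)
    }
  }
  lin <- equation$intercept +
    sum(equation$coefficients * vapply(need, function(tr)
      as.numeric(traits[[tr]]), 1.0))
  stats::plogis(lin)
}

#' Conditional trait-equation sex decision
#'
#' Implements the decision framework used when morphoscopic ancestry guides
#' the choice of sex equations: (1) the binary class maps White -> European,
#' Black -> African; if this matches the four-group classifier's top group,
#' the matching population-specific set (`sa_white` / `sa_black`) is used;
#' otherwise the ancestry is inconsistent, the pooled set is used, and the
#' procedure category is Undetermined. (2) Every applicable equation is
#' evaluated; equations needing the mental eminence are skipped when the
#' mandible is absent. (3) If all applicable equations agree on the side of
#' 0.5 the call is Determined (M or F); mixed sides give Uncertain with a
#' leaning category (`M/F` if strictly more equations favor male, `F/M` if
#' more favor female; an equal split is decided by the single most extreme
#' probability).
#'
#' @param traits Named vector/list of trait scores (1-5 ordinal).
#' @param ossa_class `"White"` or `"Black"`.
#' @param hefner_top Top group from the four-group classifier.
#' @param sets Named list of [coefficient_set()]s: `sa_white`, `sa_black`,
#'   `pooled`.
#' @param mandible_present Logical; when `FALSE`, equations using
#'   `mental_eminence` are skipped.
#' @return Object of class `morpho_sex_result` with `category`,
#'   `procedure_category` (`Determined`/`Uncertain`/`Undetermined`),
#'   `p_male` (named per equation) and `set_used`.
#' @export
decide_sex <- function(traits, ossa_class, hefner_top, sets,
                       mandible_present = TRUE) {
  map <- c(White = "European", Black = "African")
  consistent <- hefner_top %in% c("European", "African") &&
    identical(unname(map[ossa_class]), hefner_top)
  if (consistent) {
    set <- if (ossa_class == "White") sets$sa_white else sets$sa_black
  } else {
    set <- sets$pooled
  }
  stopifnot(inherits(set, "coefficient_set"))

  applicable <- Filter(function(eq) {
    need <- names(eq$coefficients)
    if (!mandible_present && "mental_eminence" %in% need) return(FALSE)
    all(vapply(need, function(tr)
      !is.null(traits[[tr]]) && !is.na(traits[[tr]]), TRUE))
  }, set$equations)
  if (length(applicable) == 0L) {
    stop("no applicable sex equation for the available traits")
  }
  p <- vapply(applicable, function(eq) logistic_p_male(traits, eq), 1.0)
  names(p) <- vapply(applicable, function(eq) eq$name, "")

  n_male <- sum(p > 0.5)
  n_female <- sum(p < 0.5)
  if (n_female == 0L && n_male > 0L) {
    category <- "M"; agreement <- TRUE
  } else if (n_male == 0L && n_female > 0L) {
    category <- "F"; agreement <- TRUE
  } else {
    agreement <- FALSE
    if (n_male > n_female) category <- "M/F"
    else if (n_female > n_male) category <- "F/M"
    else {
      extreme <- which.max(abs(p - 0.5))
      category <- if (p[extreme] > 0.5) "M/F" else "F/M"
    }
  }
  procedure <- if (!consistent) "Undetermined"
  else if (agreement) "Determined" else "Uncertain"

  structure(list(category = category, procedure_category = procedure,
                 p_male = p, set_used = set$source),
            class = "morpho_sex_result")
}

#' @export
print.morpho_sex_result <- function(x, ...) {
  cat(sprintf("%s [%s] (set: %s)\n", x$category, x$procedure_category,
              x$set_used))
  print(round(x$p_male, 3))
  invisible(x)
}
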