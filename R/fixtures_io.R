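#' @keywords internal
"_PACKAGE"

# Categories a printed sex cell may take; the two-letter forms encode the
# lean direction (first letter = majority side) and are never collapsed.
.sex_levels <- c("M", "F", "M/F", "F/M")

#' Load the packaged 21-crania profile table
#'
#' Reads the per-cranium summary table (ancestry and sex classifications from
#' four physical methods, molecular haplogroups, PCA continent and SNP call
#' counts) into one record per cranium. Cells of the form `"M(0.93)"` are
#' split into a category and a posterior probability; cells without a printed
#' posterior get an `NA` posterior.
#'
#' @param path Path to a profile CSV. `NULL` (default) loads the fixture
#'   shipped with the package.
#' @return A data frame of class `crania_records` with columns `id`,
#'   `mandible_present`, `tooth_stage`, `hefner_group`, `hefner_pp`,
#'   `ossa_class`, `cranio_group`, `cranio_pp`, `sex_sa_white`,
#'   `sex_sa_black`, `sex_walker`, `sex_cranio`, `sex_cranio_pp`, `y_hg`,
#'   `mt_hg`, `pca_continent`, `snp_count`.
#' @examples
#' crania <- load_crania_fixture()
#' nrow(crania)                       # 21
#' subset(crania, id == "003")$cranio_group
#' @export
load_crania_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "crania_profiles.csv",
                        package = "cranioprofile", mustWork = TRUE)
  }
  if (!file.exists(path)) stop("fixture file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("fixture is empty (no records): ", path)

  required <- c("id", "mandible", "tooth_stage", "hefner", "ossa_class",
                "cranio", "sex_sa_white", "sex_sa_black", "sex_walker",
                "sex_cranio", "y_hg", "mt_hg", "pca_continent", "snp_count")
  miss <- setdiff(required, names(raw))
  if (length(miss)) stop("fixture is missing column(s): ",
                         paste(miss, collapse = ", "))

  dup <- unique(raw$id[duplicated(raw$id)])
  if (length(dup)) stop("duplicate cranium id(s): ", paste(dup, collapse = ", "))

  hef <- .parse_pp_cells(raw$hefner, raw$id, "hefner")
  cra <- .parse_pp_cells(raw$cranio, raw$id, "cranio")
  sxc <- .parse_pp_cells(raw$sex_cranio, raw$id, "sex_cranio")

  for (col in c("sex_sa_white", "sex_sa_black", "sex_walker")) {
    bad <- !(raw[[col]] %in% .sex_levels)
    if (any(bad)) {
      stop("malformed cell in column '", col, "' for id '",
           raw$id[which(bad)[1]], "': ", raw[[col]][which(bad)[1]])
    }
  }
  bad <- !(sxc$category %in% .sex_levels)
  if (any(bad)) {
    stop("malformed cell in column 'sex_cranio' for id '",
         raw$id[which(bad)[1]], "': ", raw$sex_cranio[which(bad)[1]])
  }

  snp <- suppressWarnings(as.integer(raw$snp_count))
  bad <- is.na(snp) | snp < 0L
  if (any(bad)) {
    stop("malformed cell in column 'snp_count' for id '",
         raw$id[which(bad)[1]], "': ", raw$snp_count[which(bad)[1]])
  }

  out <- data.frame(
    id              = raw$id,
    mandible_present = raw$mandible == "X",
    tooth_stage     = raw$tooth_stage,
    hefner_group    = hef$category,
    hefner_pp       = hef$pp,
    ossa_class      = raw$ossa_class,
    cranio_group    = cra$category,
    cranio_pp       = cra$pp,
    sex_sa_white    = raw$sex_sa_white,
    sex_sa_black    = raw$sex_sa_black,
    sex_walker      = raw$sex_walker,
    sex_cranio      = sxc$category,
    sex_cranio_pp   = sxc$pp,
    y_hg            = raw$y_hg,
    mt_hg           = raw$mt_hg,
    pca_continent   = raw$pca_continent,
    snp_count       = snp,
    stringsAsFactors = FALSE
  )
  class(out) <- c("crania_records", "data.frame")
  out
}

# Split "West Africa(0.67)"-style cells into category + posterior.
# Cells with no trailing "(number)" keep the whole cell as category, NA pp.
.parse_pp_cells <- function(cells, ids, column) {
  m <- regmatches(cells, regexec("^(.*)\\(([0-9]*\\.?[0-9]+)\\)$", cells))
  category <- character(length(cells))
  pp <- rep(NA_real_, length(cells))
  for (i in seq_along(cells)) {
    cell <- trimws(cells[i])
    if (!nzchar(cell)) {
      stop("malformed cell in column '", column, "' for id '", ids[i],
           "': empty")
    }
    if (length(m[[i]]) == 3L) {
      category[i] <- trimws(m[[i]][2])
      pp[i] <- as.numeric(m[[i]][3])
      if (is.na(pp[i]) || pp[i] < 0 || pp[i] > 1 || !nzchar(category[i])) {
        stop("malformed cell in column '", column, "' for id '", ids[i],
             "': ", cells[i])
      }
    } else {
      category[i] <- cell
    }
  }
  list(category = category, pp = pp)
}

#' Pseudo-haploid genotype matrix
#'
#' Container for samples x SNPs calls in `{0, 1, NA}` (pseudo-haploid: a
#' single allele per site, the standard representation for low-coverage
#' degraded DNA) with optional per-sample population labels.
#'
#' @param calls Integer matrix, samples in rows, SNPs in columns, entries
#'   0, 1 or `NA` (missing).
#' @param sample_ids Character vector, one id per row of `calls`.
#' @param snp_ids Character vector, one id per column of `calls`.
#' @param population_labels Optional character vector parallel to
#'   `sample_ids`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sample_ids, snp_ids,
                            population_labels = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(sample_ids)) {
    stop("calls has ", nrow(calls), " rows but ", length(sample_ids),
         " sample ids")
  }
  if (ncol(calls) != length(snp_ids)) {
    stop("calls has ", ncol(calls), " columns but ", length(snp_ids),
         " SNP ids")
  }
  ok <- is.na(calls) | calls == 0L | calls == 1L
  if (!all(ok)) stop("genotype calls must be 0, 1 or NA")
  if (!is.null(population_labels) &&
      length(population_labels) != length(sample_ids)) {
    stop("population_labels length does not match sample_ids")
  }
  dimnames(calls) <- list(sample_ids, snp_ids)
  structure(list(calls = calls,
                 sample_ids = as.character(sample_ids),
                 snp_ids = as.character(snp_ids),
                 population_labels = population_labels),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls), "SNPs;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Per-sample missingness fraction
#' @param gm A [genotype_matrix()].
#' @return Named numeric vector of missing-call fractions in `[0, 1]`.
#' @export
sample_missingness <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  rowMeans(is.na(gm$calls))
}

#' Read a genotype triplet (geno/snp/ind)
#'
#' Reads the three-file genotype dialect used by the common ancient-DNA
#' reference panels: a `.geno` file with one row per SNP and one character
#' per sample, a `.snp` file with one row per SNP and an `.ind` file with one
#' row per sample (`id sex population`). Pseudo-haploid calls are `0`/`1`
#' with `9` as missing. Diploid-coded input (`0`/`1`/`2` alternate-allele
#' counts) is accepted when `collapse_diploid = TRUE` and collapsed to
#' pseudo-haploid by a random allele draw (homozygotes map deterministically,
#' heterozygotes by a fair coin).
#'
#' @param prefix Path prefix; `<prefix>.geno`, `<prefix>.snp` and
#'   `<prefix>.ind` are read.
#' @param collapse_diploid Accept diploid coding and collapse it.
#' @param seed Integer seed for the heterozygote allele draw (required when
#'   `collapse_diploid = TRUE`).
#' @return A [genotype_matrix()] with samples in rows.
#' @export
read_genotypes <- function(prefix, collapse_diploid = FALSE, seed = NULL) {
  geno_path <- paste0(prefix, ".geno")
  snp_path <- paste0(prefix, ".snp")
  ind_path <- paste0(prefix, ".ind")
  for (p in c(geno_path, snp_path, ind_path)) {
    if (!file.exists(p)) stop("genotype file not found: ", p)
  }

  ind <- utils::read.table(ind_path, header = FALSE,
                           colClasses = "character",
                           col.names = c("id", "sex", "population"))
  snp <- if (file.size(snp_path) == 0L) {
    data.frame(V1 = character(0), stringsAsFactors = FALSE)
  } else {
    utils::read.table(snp_path, header = FALSE, colClasses = "character")
  }
  lines <- readLines(geno_path)
  n_samp <- nrow(ind)
  n_snp <- nrow(snp)
  if (length(lines) != n_snp) {
    stop("dimension mismatch: ", length(lines), " genotype rows but ",
         n_snp, " SNPs in ", snp_path)
  }
  allowed <- if (collapse_diploid) c("0", "1", "2", "9") else c("0", "1", "9")
  calls <- matrix(NA_integer_, nrow = n_samp, ncol = n_snp)
  for (j in seq_len(n_snp)) {
    ch <- strsplit(lines[j], "", fixed = TRUE)[[1]]
    if (length(ch) != n_samp) {
      stop("dimension mismatch: genotype line ", j, " has ", length(ch),
           " calls but ", n_samp, " samples in ", ind_path)
    }
    bad <- which(!(ch %in% allowed))
    if (length(bad)) {
      stop("unknown genotype symbol '", ch[bad[1]], "' at line ", j,
           ", column ", bad[1], " of ", geno_path)
    }
    v <- suppressWarnings(as.integer(ch))
    v[ch == "9"] <- NA_integer_
    calls[, j] <- v
  }

  if (collapse_diploid) {
    if (is.null(seed)) stop("collapse_diploid = TRUE requires a seed")
    set.seed(seed)
    het <- which(!is.na(calls) & calls == 1L)
    hom_alt <- which(!is.na(calls) & calls == 2L)
    calls[het] <- stats::rbinom(length(het), 1L, 0.5)
    calls[hom_alt] <- 1L
  }

  genotype_matrix(calls, ind$id, snp[[1]],
                  population_labels = ind$population)
}

#' Write a genotype triplet (geno/snp/ind)
#'
#' Inverse of [read_genotypes()]; byte-stable for identical input.
#'
#' @param gm A [genotype_matrix()].
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_genotypes <- function(gm, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  geno_path <- paste0(prefix, ".geno")
  snp_path <- paste0(prefix, ".snp")
  ind_path <- paste0(prefix, ".ind")

  ch <- matrix("9", nrow = nrow(gm$calls), ncol = ncol(gm$calls))
  ch[!is.na(gm$calls)] <- as.character(gm$calls[!is.na(gm$calls)])
  geno_lines <- if (ncol(ch) == 0L) character(0) else
    vapply(seq_len(ncol(ch)), function(j) paste0(ch[, j], collapse = ""), "")
  ok <- tryCatch({
    writeLines(geno_lines, geno_path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write genotype file: ", geno_path)

  if (length(gm$snp_ids) == 0L) {
    writeLines(character(0), snp_path)
  } else {
    snp_df <- data.frame(id = gm$snp_ids, chr = "1", gendist = "0.0",
                         pos = seq_along(gm$snp_ids), ref = "A", alt = "G")
    utils::write.table(snp_df, snp_path, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  pop <- gm$population_labels
  if (is.null(pop)) pop <- rep("Unknown", length(gm$sample_ids))
  ind_df <- data.frame(id = gm$sample_ids, sex = "U", population = pop)
  utils::write.table(ind_df, ind_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(geno_path, snp_path, ind_path))
}
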