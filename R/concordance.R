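# Craniometric reference groups counted as African in the cross-method
# audit, and the mapping from the binary morphoscopic classes to the
# four-group classifier's continental labels.
.african_cranio_groups <- c("Somali", "West Africa", "Zulu")
.ossa_to_group <- c(White = "European", Black = "African")

#' Per-method ancestry tallies
#'
#' Tallies each ancestry method's classifications over a batch of cranium
#' records, plus two derived aggregates: the African-affinity count
#' (craniometric affinity in Somali / West Africa / Zulu) and the count of
#' craniometric posteriors at or above 0.7 together with its Somali subset.
#'
#' @param records A `crania_records` data frame ([load_crania_fixture()]).
#' @return List with tables `craniometric`, `hefner`, `ossa`, `pca` and
#'   scalars `african_affinity`, `high_posterior`, `high_posterior_somali`.
#' @export
tally_ancestry <- function(records) {
  hp <- !is.na(records$cranio_pp) & records$cranio_pp >= 0.7
  list(
    craniometric = table(records$cranio_group),
    hefner = table(records$hefner_group),
    ossa = table(records$ossa_class),
    pca = table(records$pca_continent),
    african_affinity =
      sum(records$cranio_group %in% .african_cranio_groups),
    high_posterior = sum(hp),
    high_posterior_somali = sum(hp & records$cranio_group == "Somali")
  )
}

#' Crania where the two morphoscopic methods disagree
#'
#' A record disagrees when the four-group top classification differs from
#' the mapped binary class (White -> European, Black -> African); any top
#' group outside {European, African} has no binary counterpart and counts
#' as disagreement.
#'
#' @param records A `crania_records` data frame.
#' @return Character vector of discordant cranium ids.
#' @export
morphoscopic_agreement <- function(records) {
  mapped <- unname(.ossa_to_group[records$ossa_class])
  records$id[is.na(mapped) | records$hefner_group != mapped]
}

#' Partition crania by the conditional sex-estimation procedure
#'
#' Records with consistent morphoscopic ancestry take the matching
#' population-specific column (White -> `sex_sa_white`, Black ->
#' `sex_sa_black`): an unqualified M or F is Determined, a leaning M/F or
#' F/M is Uncertain. Ancestry-inconsistent records are Undetermined, and
#' their pooled (Walker) column is reported as the call.
#'
#' @param records A `crania_records` data frame.
#' @return Data frame with `id`, `procedure_category`, `call`.
#' @export
partition_sex_procedure <- function(records) {
  discordant <- morphoscopic_agreement(records)
  n <- nrow(records)
  call <- character(n)
  block <- character(n)
  for (i in seq_len(n)) {
    if (records$id[i] %in% discordant) {
      block[i] <- "Undetermined"
      call[i] <- records$sex_walker[i]
    } else {
      call[i] <- if (records$ossa_class[i] == "White")
        records$sex_sa_white[i] else records$sex_sa_black[i]
      block[i] <- if (call[i] %in% c("M", "F")) "Determined" else "Uncertain"
    }
  }
  data.frame(id = records$id, procedure_category = block, call = call,
             stringsAsFactors = FALSE)
}

#' Crania whose physical sex conflicts with molecular sex
#'
#' With molecular sexing returning XY, a record is discrepant when at least
#' one physical sex column (the two population-specific equation columns,
#' the pooled equation column, or the craniometric discriminant) gives an
#' unqualified F. Leaning F/M calls alone do not count.
#'
#' @param records A `crania_records` data frame.
#' @param molecular Molecular sex per record (recycled); default `"XY"`.
#' @return Character vector of discrepant cranium ids.
#' @export
sex_discrepancy <- function(records, molecular = "XY") {
  molecular <- rep_len(molecular, nrow(records))
  cols <- cbind(records$sex_sa_white, records$sex_sa_black,
                records$sex_walker, records$sex_cranio)
  any_f <- apply(cols == "F", 1, any)
  records$id[molecular == "XY" & any_f]
}

#' Per-method ancestry discrepancies against molecular origin
#'
#' Counts, among records whose genotype PCA places them in Africa, how many
#' each physical method classifies outside an African group: craniometric
#' affinity outside {Somali, West Africa, Zulu}; four-group top outside
#' {African}; binary class not Black.
#'
#' @param records A `crania_records` data frame.
#' @return List of counts `craniometric`, `hefner`, `ossa`.
#' @export
ancestry_discrepancy <- function(records) {
  afr <- records$pca_continent == "Africa"
  list(
    craniometric = sum(afr &
      !(records$cranio_group %in% .african_cranio_groups)),
    hefner = sum(afr & records$hefner_group != "African"),
    ossa = sum(afr & records$ossa_class != "Black")
  )
}

#' Count of craniometric female calls
#'
#' Number of craniometric sex entries whose leading letter is F
#' (unqualified F or leaning F/M).
#'
#' @param records A `crania_records` data frame.
#' @return Integer count.
#' @export
sex_female_tally_metric <- function(records) {
  sum(startsWith(records$sex_cranio, "F"))
}

#' Full cross-method concordance audit
#'
#' Assembles the per-method tallies, the morphoscopic-disagreement set, the
#' Determined/Uncertain/Undetermined partition, the physical-vs-molecular
#' sex and ancestry discrepancies, and the uniparental macrohaplogroup
#' frequency tables into one report.
#'
#' @param records A `crania_records` data frame.
#' @return Object of class `audit_report`.
#' @export
audit_report <- function(records) {
  part <- partition_sex_procedure(records)
  partition <- split(part$id, factor(part$procedure_category,
    levels = c("Determined", "Uncertain", "Undetermined")))
  mt_all <- haplogroup_frequencies(records$mt_hg, "mt")
  structure(list(
    n = nrow(records),
    tallies = tally_ancestry(records),
    morphoscopic_discordant = morphoscopic_agreement(records),
    partition = partition,
    partition_calls = part,
    sex_discrepant = sex_discrepancy(records),
    ancestry_discrepancies = ancestry_discrepancy(records),
    metric_female = sex_female_tally_metric(records),
    y_macro = haplogroup_frequencies(records$y_hg, "Y"),
    mt_macro = mt_all,
    mt_l_share = round(100 *
      sum(mt_all$count[startsWith(mt_all$macro, "L")]) /
      sum(mt_all$count), 2),
    mt_within_l = haplogroup_frequencies(records$mt_hg, "mt", within = "L")
  ), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("Concordance audit of", x$n, "crania\n")
  cat("\nCraniometric affinities:\n"); print(x$tallies$craniometric)
  cat("African affinity aggregate:", x$tallies$african_affinity, "/",
      x$n, "\n")
  cat("Posteriors >= 0.7:", x$tallies$high_posterior,
      "(Somali:", x$tallies$high_posterior_somali, ")\n")
  cat("\nBinary morphoscopic classes:\n"); print(x$tallies$ossa)
  cat("Four-group morphoscopic tops:\n"); print(x$tallies$hefner)
  cat("Morphoscopic disagreements:", length(x$morphoscopic_discordant),
      "(", paste(x$morphoscopic_discordant, collapse = ", "), ")\n")
  cat("\nSex procedure partition:",
      paste(names(x$partition), lengths(x$partition),
            sep = " = ", collapse = ", "), "\n")
  cat("Craniometric female calls:", x$metric_female, "\n")
  cat("Physical-vs-molecular sex discrepancies:",
      length(x$sex_discrepant), "\n")
  cat("Ancestry discrepancies vs African molecular origin:",
      "craniometric =", x$ancestry_discrepancies$craniometric,
      ", four-group =", x$ancestry_discrepancies$hefner,
      ", binary =", x$ancestry_discrepancies$ossa,
      "(the per-method counts are reported individually; no single",
      "figure summarizes the morphoscopic methods)\n")
  cat("\nY macrohaplogroups:\n"); print(x$y_macro, row.names = FALSE)
  cat("mt macrohaplogroups (L share", x$mt_l_share, "%):\n")
  print(x$mt_macro, row.names = FALSE)
  invisible(x)
}

#' Write an audit report as JSON
#'
#' @param report An [audit_report()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_audit_json <- function(report, path) {
  stopifnot(inherits(report, "audit_report"))
  x <- list(
    n = report$n,
    tallies = lapply(report$tallies, function(t)
      if (inherits(t, "table")) as.list(stats::setNames(as.integer(t),
                                                        names(t))) else t),
    morphoscopic_discordant = report$morphoscopic_discordant,
    partition = report$partition,
    sex_discrepant = report$sex_discrepant,
    ancestry_discrepancies = report$ancestry_discrepancies,
    metric_female = report$metric_female,
    y_macro = report$y_macro,
    mt_macro = report$mt_macro,
    mt_l_share = report$mt_l_share,
    mt_within_l = report$mt_within_l
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
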