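# Genotype-and-validate: force-call every truth-status site and classify the
# outcome against its recorded status.

#' Classify one validation outcome
#'
#' A TRUE_DE_NOVO site called polymorphic is a true positive and called
#' monomorphic a false negative; an ARTIFACT site called polymorphic is a
#' false positive and called monomorphic a true negative.
#'
#' @param truth_status `"TRUE_DE_NOVO"` or `"ARTIFACT"` (vectorised).
#' @param called_polymorphic Logical (vectorised).
#' @return Character vector over `{"TP","FN","FP","TN"}`.
#' @export
classify_record <- function(truth_status, called_polymorphic) {
  assert_that(all(truth_status %in% c("TRUE_DE_NOVO", "ARTIFACT")),
              "truth status must be TRUE_DE_NOVO or ARTIFACT")
  dplyr::case_when(
    truth_status == "TRUE_DE_NOVO" & called_polymorphic ~ "TP",
    truth_status == "TRUE_DE_NOVO" ~ "FN",
    called_polymorphic ~ "FP",
    TRUE ~ "TN"
  )
}

#' Force-call and validate a truth-status site set
#'
#' For each truth-set site the genotyper is run with the alleles restricted
#' to the reference base and the truth VCF's alternate allele (forced-allele
#' mode), and the call is classified against the recorded status. Sites
#' without usable data (zero retained depth or a filtered site) are NO_DATA
#' and excluded from metric denominators.
#'
#' @param aln Alignment tibble.
#' @param refs Reference tibble.
#' @param truth Variant tibble with `status` in
#'   `{TRUE_DE_NOVO, ARTIFACT}`.
#' @param config A [genotyper_config()].
#' @param events Precomputed event table.
#' @return A `validation_result` list: `records` (per-site tibble with call
#'   columns, `status`, `classification`), `confusion` (named counts `tp`,
#'   `fp`, `tn`, `fn`, `n_no_data`), `metrics` (tibble from
#'   [confusion_metrics()]).
#' @export
genotype_and_validate <- function(aln, refs, truth,
                                  config = genotyper_config(),
                                  events = alignment_events(aln, refs)) {
  assert_that(all(truth$status %in% c("TRUE_DE_NOVO", "ARTIFACT")),
              "truth sites must carry TRUE_DE_NOVO or ARTIFACT status")
  on_panel <- truth$contig %in% refs$name
  sites <- truth[on_panel, c("contig", "pos", "ref", "alt")]
  calls <- genotype_positions(events, sites, config)
  records <- truth |>
    left_join(calls, by = c("contig", "pos", "ref", "alt")) |>
    mutate(
      no_data = !on_panel | is.na(.data$filter) | .data$filter != "PASS",
      classification = if_else(
        .data$no_data, "NO_DATA",
        classify_record(.data$status, dplyr::coalesce(.data$polymorphic, FALSE))
      )
    )
  cls <- records$classification
  confusion <- c(tp = sum(cls == "TP"), fp = sum(cls == "FP"),
                 tn = sum(cls == "TN"), fn = sum(cls == "FN"),
                 n_no_data = sum(cls == "NO_DATA"))
  structure(list(records = records, confusion = confusion,
                 metrics = confusion_metrics(confusion[["tp"]],
                                             confusion[["fn"]],
                                             confusion[["fp"]],
                                             confusion[["tn"]])),
            class = "validation_result")
}

#' Confusion-matrix metrics as percentages
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each times
#' 100, reported at full precision and rounded to the nearest whole percent.
#' A metric with a zero denominator is undefined and reported `NA`.
#'
#' @param tp,fn,fp,tn Confusion-matrix counts.
#' @return Tibble with `metric`, `value` (percent) and `rounded`.
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  value <- c(sensitivity = pct(tp, tp + fn), specificity = pct(tn, tn + fp),
             ppv = pct(tp, tp + fp), npv = pct(tn, tn + fn))
  tibble(metric = names(value), value = unname(value),
         rounded = as.integer(round(unname(value))))
}

#' @export
tidy.validation_result <- function(x, ...) x$records

#' @export
glance.validation_result <- function(x, ...) {
  m <- setNames(x$metrics$value, x$metrics$metric)
  tibble(tp = x$confusion[["tp"]], fp = x$confusion[["fp"]],
         tn = x$confusion[["tn"]], fn = x$confusion[["fn"]],
         n_no_data = x$confusion[["n_no_data"]],
         sensitivity = m[["sensitivity"]], specificity = m[["specificity"]],
         ppv = m[["ppv"]], npv = m[["npv"]])
}

#' @export
autoplot.validation_result <- function(object, ...) {
  df <- object$records |> count(.data$status, .data$classification)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$n,
                                   fill = .data$classification)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "sites") +
    ggplot2::theme_minimal()
}
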