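#' Activity score of a diplotype
#'
#' Sums the CPIC-style activity values of the two haplotypes,
#' multiplying by the copy multiplier of duplicated alleles ("*1x2"
#' contributes twice the value of *1). The score is indeterminate as
#' soon as any constituent allele lacks a defined activity value
#' (function unknown, uncertain or unassigned).
#'
#' @param diplotype A `diplotype_call`, or a character vector of two
#'   allele names (e.g. `c("*1x2", "*4.001")`).
#' @param db An `allele_db` providing the activity values.
#' @return Object of class `activity_score`: `value` (NA when not
#'   determinate) and `determinate`.
#' @export
activity_score <- function(diplotype, db) {
  haps <- diplotype_names(diplotype)
  p <- parse_allele_name(haps)
  act <- activity_of(db, p$major_id)          # errors on unknown majors
  determinate <- !anyNA(act)
  structure(list(value = if (determinate) sum(act * p$mult) else NA_real_,
                 determinate = determinate),
            class = "activity_score")
}

diplotype_names <- function(diplotype) {
  if (inherits(diplotype, "diplotype_call")) {
    if (is.na(diplotype$hap_a))
      stop("cannot score an unresolved diplotype (filter ",
           diplotype$filter, ")")
    c(diplotype$hap_a, diplotype$hap_b)
  } else {
    stopifnot(is.character(diplotype), length(diplotype) == 2L)
    diplotype
  }
}

#' @export
print.activity_score <- function(x, ...) {
  cat("Activity score:",
      if (x$determinate) format(x$value) else "indeterminate", "\n")
  invisible(x)
}

#' Metabolizer phenotype from an activity score
#'
#' Phenotype bins: AS = 0 poor (PM); 0.25-1 intermediate (IM);
#' 1.25-2.25 normal (NM); above 2.25 ultrarapid (UM). Activity values
#' move on a quarter-step grid, so the printed closed ranges are
#' implemented as half-open intervals (0, 1], (1, 2.25], (2.25, Inf)
#' and the mapping is total for any non-negative score. An
#' indeterminate score maps to "Indeterminate".
#'
#' @param score An `activity_score` or a single non-negative number.
#' @return One of `"PM"`, `"IM"`, `"NM"`, `"UM"`, `"Indeterminate"`.
#' @export
predict_phenotype <- function(score) {
  if (inherits(score, "activity_score")) {
    if (!score$determinate) return("Indeterminate")
    score <- score$value
  }
  if (is.na(score)) return("Indeterminate")
  if (!is.numeric(score) || score < 0)
    stop("activity score must be a non-negative number")
  if (score == 0) "PM"
  else if (score <= 1) "IM"
  else if (score <= 2.25) "NM"
  else "UM"
}

#' Assemble the full phenotype report for a called sample
#'
#' Combines the diplotype call with its activity score, predicted
#' metabolizer phenotype, per-haplotype annotation (function category,
#' activity value, evidence) and population frequencies. The
#' diplotype-level frequency is the per-population product of the two
#' haplotype frequencies unless a diplotype frequency table is
#' supplied, and is labelled accordingly.
#'
#' @param diplotype A `diplotype_call` or character vector of two
#'   allele names.
#' @param db An `allele_db`.
#' @param diplotype_frequencies Optional data.frame (population,
#'   frequency) overriding the product estimate.
#' @return Object of class `phenotype_report`.
#' @export
phenotype_report <- function(diplotype, db, diplotype_frequencies = NULL) {
  haps <- diplotype_names(diplotype)
  p <- parse_allele_name(haps)
  score <- activity_score(haps, db)
  per_hap <- lapply(seq_len(2L), function(i) {
    m <- p$major_id[i]
    fr <- db$frequencies[db$frequencies$major_id == m, c("population", "frequency")]
    list(name = haps[i], major = m,
         fun = function_of(db, m),
         activity_value = activity_of(db, m),
         evidence = major_row(db, m)$evidence,
         frequencies = fr)
  })
  names(per_hap) <- c("hap_a", "hap_b")
  if (is.null(diplotype_frequencies)) {
    f1 <- per_hap$hap_a$frequencies; f2 <- per_hap$hap_b$frequencies
    shared <- intersect(f1$population, f2$population)
    dip_freq <- if (length(shared))
      data.frame(population = shared,
                 frequency = f1$frequency[match(shared, f1$population)] *
                   f2$frequency[match(shared, f2$population)])
    else NULL
    freq_method <- "product of haplotype frequencies"
  } else {
    dip_freq <- diplotype_frequencies
    freq_method <- "diplotype frequency table"
  }
  structure(list(
    diplotype = paste(haps, collapse = "/"),
    filter = if (inherits(diplotype, "diplotype_call")) diplotype$filter
             else "PASS",
    aliases = if (inherits(diplotype, "diplotype_call")) diplotype$aliases
              else NULL,
    copy_number = if (inherits(diplotype, "diplotype_call") &&
                      !is.null(diplotype$cn)) diplotype$cn$cn_called else NA,
    score = score,
    phenotype = predict_phenotype(score),
    per_haplotype = per_hap,
    diplotype_frequency = dip_freq,
    diplotype_frequency_method = freq_method),
    class = "phenotype_report")
}

#' Render a phenotype report as text or schema-stable JSON
#'
#' The text rendering prints every field group of the report
#' (diplotype and filter status, copy number, activity score,
#' phenotype, per-haplotype function/activity/evidence, per-population
#' haplotype frequencies, diplotype frequency); absent annotation is
#' rendered as "not available". The JSON rendering is schema-stable:
#' parsing it with [report_from_json()] and re-rendering is
#' byte-identical.
#'
#' @param report A `phenotype_report`.
#' @param format `"text"` or `"json"`.
#' @return A character scalar (the rendered report).
#' @export
render_report <- function(report, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json") return(render_report_json(report))
  fmt_freq <- function(fr) {
    if (is.null(fr) || nrow(fr) == 0L) return("not available")
    paste(sprintf("%s=%.4f", fr$population, fr$frequency), collapse = "  ")
  }
  hap_block <- function(h) {
    c(sprintf("  %s:", h$name),
      sprintf("    function:       %s", h$fun),
      sprintf("    activity value: %s",
              if (is.na(h$activity_value)) "not available"
              else format(h$activity_value)),
      sprintf("    evidence:       %s",
              if (is.na(h$evidence)) "not available" else h$evidence),
      sprintf("    frequencies:    %s", fmt_freq(h$frequencies)))
  }
  al <- unique(unlist(report$aliases))
  lines <- c(
    sprintf("Diplotype:        %s", report$diplotype),
    sprintf("Filter:           %s", report$filter),
    sprintf("Aliases:          %s",
            if (length(al)) paste(al, collapse = ", ") else "none"),
    sprintf("Copy number:      %s",
            if (is.na(report$copy_number)) "not available"
            else report$copy_number),
    sprintf("Activity score:   %s",
            if (report$score$determinate) format(report$score$value)
            else "indeterminate"),
    sprintf("Phenotype:        %s", report$phenotype),
    "Haplotypes:",
    hap_block(report$per_haplotype$hap_a),
    hap_block(report$per_haplotype$hap_b),
    sprintf("Diplotype freq.:  %s (%s)", fmt_freq(report$diplotype_frequency),
            report$diplotype_frequency_method))
  paste(lines, collapse = "\n")
}

render_report_json <- function(report) {
  hap <- function(h) list(
    name = h$name, major = h$major, `function` = h$fun,
    activity_value = if (is.na(h$activity_value)) NULL else h$activity_value,
    evidence = if (is.na(h$evidence)) NULL else h$evidence,
    frequencies = freq_list(h$frequencies))
  obj <- list(
    schema = "starcall-report-1",
    diplotype = report$diplotype,
    filter = report$filter,
    aliases = as.list(lapply(report$aliases, as.list)),
    copy_number = if (is.na(report$copy_number)) NULL else report$copy_number,
    activity_score = if (report$score$determinate) report$score$value else NULL,
    determinate = report$score$determinate,
    phenotype = report$phenotype,
    haplotypes = list(hap_a = hap(report$per_haplotype$hap_a),
                      hap_b = hap(report$per_haplotype$hap_b)),
    diplotype_frequency = freq_list(report$diplotype_frequency),
    diplotype_frequency_method = report$diplotype_frequency_method)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE))
}

freq_list <- function(fr) {
  if (is.null(fr) || nrow(fr) == 0L) return(NULL)
  as.list(setNames(fr$frequency, fr$population))
}

#' Reconstruct a phenotype report from its JSON rendering
#' @param txt JSON string produced by `render_report(..., "json")`.
#' @return A `phenotype_report`.
#' @export
report_from_json <- function(txt) {
  o <- jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(o$schema) || o$schema != "starcall-report-1")
    stop("not a starcall phenotype report")
  freq_df <- function(fl) {
    if (is.null(fl) || !length(fl)) return(NULL)
    data.frame(population = names(fl), frequency = as.numeric(unlist(fl)),
               stringsAsFactors = FALSE)
  }
  hap <- function(h) list(
    name = h$name, major = as.integer(h$major), fun = h$`function`,
    activity_value = if (is.null(h$activity_value)) NA_real_
                     else as.numeric(h$activity_value),
    evidence = if (is.null(h$evidence)) NA_character_ else h$evidence,
    frequencies = if (is.null(freq_df(h$frequencies)))
      data.frame(population = character(), frequency = numeric())
      else freq_df(h$frequencies))
  structure(list(
    diplotype = o$diplotype,
    filter = o$filter,
    aliases = lapply(o$aliases, function(a) as.character(unlist(a))),
    copy_number = if (is.null(o$copy_number)) NA else o$copy_number,
    score = structure(list(
      value = if (isTRUE(o$determinate)) as.numeric(o$activity_score)
              else NA_real_,
      determinate = isTRUE(o$determinate)), class = "activity_score"),
    phenotype = o$phenotype,
    per_haplotype = list(hap_a = hap(o$haplotypes$hap_a),
                         hap_b = hap(o$haplotypes$hap_b)),
    diplotype_frequency = freq_df(o$diplotype_frequency),
    diplotype_frequency_method = o$diplotype_frequency_method),
    class = "phenotype_report")
}

#' @export
print.phenotype_report <- function(x, ...) {
  cat(render_report(x, "text"), "\n")
  invisible(x)
}
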