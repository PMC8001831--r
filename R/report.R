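#' Read an algorithm configuration from a YAML file
#'
#' All tunable thresholds live in one flat YAML file: `crp_cutoff`
#' (mg/dL), `wall_cutoff` (mm), `category_threshold` and the five item
#' weights.  Keys omitted from the file keep their defaults; an empty or
#' missing `path` returns the default configuration.  A template with the
#' defaults ships at `system.file("extdata", "default-config.yaml",
#' package = "gcatriage")`.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return A [gca_config()] object.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(gca_config())
  if (!file.exists(path)) gca_stop("NO_SUCH_FILE", paste("not found:", path))
  raw <- yaml::read_yaml(path)
  raw <- raw %||% list()
  w <- gca_weights(
    age_over_70 = raw$age_over_70 %||% 1L,
    headache = raw$headache %||% 1L,
    jaw_claudication = raw$jaw_claudication %||% 1L,
    aion_unilateral = raw$aion_unilateral %||% 1L,
    aion_bilateral = raw$aion_bilateral %||% 2L,
    category_threshold = raw$category_threshold %||% 2L)
  gca_config(crp_cutoff = raw$crp_cutoff %||% 2.5,
             wall_cutoff = raw$wall_cutoff %||% 0.7,
             weights = w)
}

#' Evaluate the algorithm on a cohort
#'
#' Runs the cohort through the stepwise algorithm and computes
#' diagnostic-accuracy statistics of the sonographic test stratified by
#' probability category and by exact score, together with the patient-flow
#' summary.  Sonographic positivity is taken from the recorded result
#' where present, otherwise from the wall thickness.
#'
#' @param patients Data frame of patient records with final diagnoses.
#' @param config A [gca_config()].
#' @param roc Also compute the ROC curve of the score against the final
#'   diagnosis (default TRUE).
#' @return Object of class `gca_report`: `flow`, `strata` (named list of
#'   `list(table, metrics)`), optional `roc`, plus the `config` echo and
#'   package `version`.
#' @export
evaluate_cohort <- function(patients, config = gca_config(), roc = TRUE) {
  flow <- run_cohort(patients, config)
  cl <- flow$classified
  truth <- cl$final_diagnosis == "cGCA"
  pos <- ifelse(!is.na(cl$hrtcs_result), cl$hrtcs_result == "positive",
                hrtcs_positive(cl$wall_thickness, config$wall_cutoff))
  stratum <- function(keep) {
    tab <- build_table(pos[keep], truth[keep])
    list(table = tab, metrics = metrics(tab))
  }
  strata <- list(overall = stratum(rep(TRUE, nrow(cl))))
  for (cat in c("low", "non_low")) {
    keep <- cl$category == cat
    if (any(keep)) strata[[cat]] <- stratum(keep)
  }
  for (s in sort(unique(cl$points))) {
    keep <- cl$points == s
    strata[[paste0("score_", s)]] <- stratum(keep)
  }
  roc_obj <- NULL
  if (roc && length(unique(truth)) == 2) {
    roc_obj <- roc_auc(cl$points, truth)
  }
  structure(list(flow = flow, strata = strata, roc = roc_obj,
                 config = config,
                 version = as.character(utils::packageVersion("gcatriage"))),
            class = "gca_report")
}

#' @export
print.gca_report <- function(x, ...) {
  print(x$flow)
  for (nm in names(x$strata)) {
    m <- x$strata[[nm]]$metrics
    ppv <- m["ppv", ]; npv <- m["npv", ]
    cat(sprintf("  %-10s PPV %s  NPV %s\n", nm,
                if (ppv$defined) sprintf("%5.1f%%", 100 * ppv$estimate) else "  -  ",
                if (npv$defined) sprintf("%5.1f%%", 100 * npv$estimate) else "  -  "))
  }
  if (!is.null(x$roc)) print(x$roc)
  invisible(x)
}

report_as_list <- function(report) {
  stratum_list <- function(s) {
    m <- s$metrics
    list(
      table = list(tp = s$table$tp, fp = s$table$fp,
                   fn = s$table$fn, tn = s$table$tn),
      metrics = lapply(rownames(m), function(nm) {
        row <- m[nm, ]
        list(metric = nm,
             estimate = if (row$defined) row$estimate else NULL,
             defined = row$defined,
             printed_pct = if (row$defined)
               round_half_up(100 * row$estimate, 1) else NULL,
             lower = if (row$defined) row$lower else NULL,
             upper = if (row$defined) row$upper else NULL)
      }))
  }
  out <- list(
    version = report$version,
    config = list(
      crp_cutoff = report$config$crp_cutoff,
      wall_cutoff = report$config$wall_cutoff,
      weights = unclass(report$config$weights)),
    flow = list(
      n_total = report$flow$n_total,
      n_low = report$flow$n_low,
      n_non_low = report$flow$n_non_low,
      n_reject_no_imaging = report$flow$n_reject_no_imaging,
      n_low_imaged = report$flow$n_low_imaged,
      n_non_low_imaged = report$flow$n_non_low_imaged,
      routes = report$flow$routes),
    strata = lapply(report$strata, stratum_list))
  if (!is.null(report$roc)) {
    out$roc <- list(auc = report$roc$auc,
                    points = report$roc$points)
  }
  out
}

#' Write an evaluation report to disk
#'
#' JSON output serialises the full report (full-precision estimates plus
#' a `printed_pct` field rounded half-up to one decimal for comparison
#' with published tables) with stable key order, so identical reports
#' produce identical bytes.  CSV output holds one row per stratum metric.
#'
#' @param report A `gca_report` from [evaluate_cohort()].
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "gca_report"))
  if (format == "json") {
    jsonlite::write_json(report_as_list(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  } else {
    rows <- list()
    for (nm in names(report$strata)) {
      m <- report$strata[[nm]]$metrics
      tab <- report$strata[[nm]]$table
      for (metric in rownames(m)) {
        row <- m[metric, ]
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = nm, metric = metric,
          estimate = ifelse(row$defined, row$estimate, NA_real_),
          printed_pct = ifelse(row$defined,
                               round_half_up(100 * row$estimate, 1), NA_real_),
          lower = ifelse(row$defined, row$lower, NA_real_),
          upper = ifelse(row$defined, row$upper, NA_real_),
          tp = tab$tp, fp = tab$fp, fn = tab$fn, tn = tab$tn,
          stringsAsFactors = FALSE)
      }
    }
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                     na = "", eol = "\n", quote = FALSE)
  }
  invisible(path)
}
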