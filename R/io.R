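#' Read an incomplete dataset from CSV
#'
#' Reads a header-ed CSV, checks that the outcome is complete and that all
#' analysis columns are numeric, and builds the missingness mask and
#' per-covariate missing fractions.
#'
#' @param path CSV file path.
#' @param outcome Name of the outcome column.
#' @param covariates Covariate columns; default all remaining columns.
#' @param binary Names of binary covariates.
#' @param na_tokens Strings treated as missing (default empty field,
#'   `"NA"` and `"."`).
#' @return An [incomplete_data()] object.
#' @export
read_incomplete_data <- function(path, outcome, covariates = NULL,
                                 binary = character(0),
                                 na_tokens = c("", "NA", ".")) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, na.strings = na_tokens,
                       check.names = FALSE)
  if (!outcome %in% names(d)) stop("unknown outcome column: ", outcome)
  if (is.null(covariates)) covariates <- setdiff(names(d), outcome)
  for (cv in c(outcome, covariates))
    if (!is.numeric(d[[cv]]))
      stop("non-numeric values in column '", cv, "'")
  incomplete_data(d, outcome, covariates, binary)
}

#' Write an analysis result to disk
#'
#' Serialises package result objects with stable structure: selection
#' results (`fsp_result`, `mfp_mi_result`) as JSON including the full test
#' trail; simulation summaries (`selection_result`, `estimation_result`)
#' as CSV (rejection rates, and a companion `*_phat.csv` frequency table
#' for estimation results); imputed datasets (`mi_datasets`) as one CSV
#' per imputation plus a JSON manifest of the mask and drawn exponents.
#' Numeric values are written at full (17 significant digit) precision.
#'
#' @param x A result object.
#' @param path Output path (extension added per format where needed).
#' @param format `"json"` or `"csv"`; defaults to the natural format for
#'   the object.
#' @return Invisibly, the path(s) written.
#' @export
write_results <- function(x, path, format = NULL) {
  UseMethod("write_results")
}

#' @export
write_results.fsp_result <- function(x, path, format = "json") {
  out <- list(selected = x$selected,
              powers = if (is.numeric(x$powers)) x$powers else x$powers,
              method = x$method,
              alpha_inclusion = x$alpha_inclusion, alpha = x$alpha,
              trail = x$trail)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @export
write_results.mfp_mi_result <- function(x, path, format = "json") {
  out <- list(method = x$method, converged = x$converged,
              cycles_run = x$cycles_run, visit_order = x$visit_order,
              selection = lapply(x$selection, function(s)
                list(class = s$class, powers = s$powers)),
              trails = lapply(x$results, `[[`, "trail"),
              pooled = x$pooled)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @export
write_results.selection_result <- function(x, path, format = "csv") {
  utils::write.csv(format(x$rates, digits = 17), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.estimation_result <- function(x, path, format = "csv") {
  freq <- data.frame(method = rownames(x$p_hat_freq), x$p_hat_freq,
                     check.names = FALSE)
  utils::write.csv(freq, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_results.mi_datasets <- function(x, path, format = "csv") {
  stem <- sub("\\.csv$", "", path)
  files <- character(x$M)
  for (m in seq_len(x$M)) {
    files[m] <- paste0(stem, "_imp", m, ".csv")
    utils::write.csv(format(x$datasets[[m]], digits = 17), files[m],
                     row.names = FALSE, quote = FALSE)
  }
  manifest <- paste0(stem, "_manifest.json")
  jsonlite::write_json(
    list(M = x$M, outcome = x$outcome, covariates = x$covariates,
         fraction_missing = as.list(x$f),
         p_star = x$p_star,
         n_missing = colSums(!x$mask),
         files = basename(files)),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(files, manifest))
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run exactly: the command or
#' function, the configuration, the seed, the package version, a
#' timestamp, and any warnings collected.
#'
#' @param path Output JSON path.
#' @param command Label of the command or function run.
#' @param config Configuration list (echoed verbatim).
#' @param seed The seed used.
#' @param warnings Character vector of warnings.
#' @return Invisibly, the path written.
#' @export
run_manifest <- function(path, command, config = list(), seed = NULL,
                         warnings = character(0)) {
  jsonlite::write_json(
    list(command = command,
         config = config,
         seed = seed,
         package = "fpmi",
         version = as.character(utils::packageVersion("fpmi")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         warnings = warnings),
    path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
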