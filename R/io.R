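# CSV / JSON input-output with schema validation. CSV is the only tabular
# format (UTF-8, '.' decimal, ASCII hyphen-minus); JSON carries summaries.

check_columns <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s file '%s' lacks column(s): %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

check_numeric_cols <- function(df, cols, what, path) {
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop(sprintf("%s file '%s': column '%s' is not numeric (first bad data line: %d)",
                   what, path, col,
                   if (length(bad)) bad[1] + 1L else NA_integer_),
           call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("%s file '%s': column '%s' has missing values (first at data line %d)",
                   what, path, col, which(is.na(v))[1] + 1L), call. = FALSE)
    }
  }
  invisible(df)
}

#' Read and write consumer samples CSV
#'
#' Schema: `group,tissue,day,fish_id,d13c,d15n` (header required, UTF-8,
#' '.' decimal, ASCII minus). Round-trips are stable to full double
#' precision.
#'
#' @param path File path.
#' @return `read_samples_csv()` returns the validated data frame.
#' @export
read_samples_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  check_columns(df, c("group", "tissue", "day", "fish_id", "d13c", "d15n"),
                "samples", path)
  check_numeric_cols(df, c("day", "d13c", "d15n"), "samples", path)
  df
}

#' @param samples Samples data frame.
#' @rdname read_samples_csv
#' @export
write_samples_csv <- function(samples, path) {
  check_columns(samples, c("group", "tissue", "day", "fish_id", "d13c", "d15n"),
                "samples", path)
  utils::write.csv(format_numeric(samples), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write diet-sources CSV
#'
#' Schema: `name,mu_c,sd_c,mu_n,sd_n`.
#'
#' @param path File path.
#' @export
read_sources_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  check_columns(df, c("name", "mu_c", "sd_c", "mu_n", "sd_n"), "sources", path)
  check_numeric_cols(df, c("mu_c", "sd_c", "mu_n", "sd_n"), "sources", path)
  df
}

#' @param sources Sources data frame.
#' @rdname read_sources_csv
#' @export
write_sources_csv <- function(sources, path) {
  check_columns(sources, c("name", "mu_c", "sd_c", "mu_n", "sd_n"),
                "sources", path)
  utils::write.csv(format_numeric(sources), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write DTDF specification CSV
#'
#' Schema: `source,tissue,delta_c,sd_c,delta_n,sd_n,method`.
#'
#' @param path File path.
#' @export
read_dtdf_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  check_columns(df, c("source", "tissue", "delta_c", "sd_c", "delta_n",
                      "sd_n", "method"), "dtdf", path)
  check_numeric_cols(df, c("delta_c", "sd_c", "delta_n", "sd_n"), "dtdf", path)
  class(df) <- c("dtdf_spec", "data.frame")
  df
}

#' @param dtdf DTDF specification data frame.
#' @rdname read_dtdf_csv
#' @export
write_dtdf_csv <- function(dtdf, path) {
  check_columns(dtdf, c("source", "tissue", "delta_c", "sd_c", "delta_n",
                        "sd_n", "method"), "dtdf", path)
  utils::write.csv(format_numeric(as.data.frame(dtdf)), path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Serialise doubles at full precision so CSV round trips are lossless.
format_numeric <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  })
  df
}

#' Write a fit summary as JSON
#'
#' Serialises the summary of an `incorporation_fit` or `mixture_estimate`
#' (parameter means, credibility ranges, PSRF, DIC where applicable) along
#' with provenance metadata (seed, configuration hash, package version).
#'
#' @param fit The fit object.
#' @param path Output path.
#' @param meta Optional named list merged into the JSON's `meta` field.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path, meta = list()) {
  body <- if (inherits(fit, "incorporation_fit")) {
    list(kind = "incorporation", model = fit$model_kind,
         group = fit$group, tissue = fit$tissue, isotope = fit$isotope,
         params = fit$summary, psrf = as.list(fit$psrf), dic = fit$dic,
         converged = fit$converged)
  } else if (inherits(fit, "mixture_estimate")) {
    list(kind = "mixing", error = fit$error, isotopes = fit$isotopes,
         proportions = fit$summary, residual_sd = as.list(fit$residual_sd),
         psrf = as.list(fit$psrf))
  } else {
    stop("unsupported fit object", call. = FALSE)
  }
  body$meta <- c(meta, list(package_version = as.character(
    utils::packageVersion("dtdfmix"))))
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

# Hash a configuration (or any R object) for provenance stamps.
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}
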