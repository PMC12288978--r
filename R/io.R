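# Unified cohort CSV header; unused columns are left empty per schema.
cohort_columns <- c(
  "patient_id", "gcc_loss_pct", "rgc_loss_pct_latent", "stratum",
  "va_log_pre", "va_log_post", "interval_years", "age_years",
  "param_gcc_base", "param_gcc_follow", "param_vfi_base",
  "param_vfi_follow", "param_md_base", "param_md_follow")

cohort_schemas <- list(
  pool = c("patient_id", "gcc_loss_pct"),
  trial = c("patient_id", "gcc_loss_pct", "rgc_loss_pct_latent"),
  longitudinal = c("patient_id", "interval_years", "age_years",
                   "param_gcc_base", "param_gcc_follow", "param_vfi_base",
                   "param_vfi_follow", "param_md_base", "param_md_follow"),
  treated = c("patient_id", "gcc_loss_pct", "va_log_pre", "va_log_post"))

# columns that may carry qualitative VA tokens (NLP/LP/HM/FC)
va_token_columns <- c("va_log_pre", "va_log_post")

#' Read a cohort table from CSV
#'
#' Reads and validates a cohort CSV against one of the four record schemas
#' (`pool`, `trial`, `longitudinal`, `treated`). Numeric columns are parsed
#' with row-level error reporting (all offending cells are listed with line
#' numbers before the reader fails); the visual-acuity columns may carry
#' qualitative tokens (NLP, LP, HM, FC) which are preserved as character
#' for later mapping through a [va_scale()]. Empty files with a valid
#' header yield zero records without error.
#'
#' @param path CSV file path.
#' @param schema One of `"pool"`, `"trial"`, `"longitudinal"`, `"treated"`.
#' @return Data.frame of validated records (VA columns character when they
#'   contain tokens, numeric otherwise).
#' @export
read_cohort_table <- function(path, schema = c("pool", "trial",
                                               "longitudinal", "treated")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = c("NA", ""))
  required <- cohort_schemas[[schema]]
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("schema '", schema, "': missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  numeric_cols <- setdiff(intersect(names(df), cohort_columns),
                          c("patient_id", "stratum", va_token_columns))
  errors <- character(0)
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !is.na(df[[col]]))
    if (length(bad))
      errors <- c(errors, sprintf(
        "column '%s', line %d: non-numeric value '%s'",
        col, bad + 1L, df[[col]][bad]))
    df[[col]] <- parsed
  }
  if (length(errors))
    stop("parse error(s) in ", path, ":\n  ",
         paste(errors, collapse = "\n  "))
  for (col in intersect(va_token_columns, names(df))) {
    vals <- df[[col]]
    toks <- vals[!is.na(vals)]
    if (all(!nzchar(toks)) ||
        all(!is.na(suppressWarnings(as.numeric(toks)))))
      df[[col]] <- suppressWarnings(as.numeric(vals))
  }
  df
}

#' Write a cohort as the unified cohort CSV
#'
#' Writes records using the full unified header; columns absent from the
#' input are left empty so every cohort kind round-trips through the same
#' file format.
#'
#' @param cohort Data.frame of records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- data.frame(matrix(NA, nrow = nrow(cohort),
                           ncol = length(cohort_columns)))
  names(out) <- cohort_columns
  for (col in intersect(names(cohort), cohort_columns))
    out[[col]] <- cohort[[col]]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# Small FNV-1a hash of a config's deparsed form, for run provenance.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 2^32
  sprintf("%08x", h)
}

#' Write a results table as TSV with provenance header
#'
#' Writes a tab-separated results table preceded by commented metadata
#' lines (`# key: value`): package version, seed and any extra metadata
#' supplied. Re-running with the same configuration and seed produces a
#' byte-identical file.
#'
#' @param table Data.frame with named columns.
#' @param path Output TSV path.
#' @param meta Named list of metadata to record (e.g. `list(seed = 1)`).
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, meta = list()) {
  if (is.null(names(table)) || !length(names(table)))
    stop("table columns must be named")
  meta <- c(list(package = paste0("stratpower ",
                                  as.character(utils::packageVersion("stratpower")))),
            meta)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' Mirrors the [synthetic_config()] fields plus stage parameters; the seed
#' is mandatory so that configured runs are reproducible.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$seed))
    stop("configuration must specify a seed")
  cfg
}
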