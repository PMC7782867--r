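## Experiment tables: tibbles tagged with an experiment kind and a metadata
## list. Column headers carry explicit unit suffixes (time_s, conc_uM,
## urea_M, heat_kcal_per_mol) because unit mix-ups are the dominant failure
## mode when moving numbers between instruments and fits.

EXPT_KINDS <- c("trace", "kobs_series", "denaturation", "itc")

expt_required_cols <- function(kind) {
  switch(kind,
    trace        = c("time_s", "signal"),
    kobs_series  = c("conc_uM", "kobs_s"),
    denaturation = c("urea_M", "signal"),
    itc          = c("injection", "heat_kcal_per_mol")
  )
}

#' Construct a tagged experiment table
#'
#' Wraps a data frame of measurements as one of the four experiment kinds
#' handled by the package: a stopped-flow `trace` (`time_s`, `signal`), a
#' `kobs_series` of observed rate constants versus ligand concentration
#' (`conc_uM`, `kobs_s`), a urea `denaturation` curve (`urea_M`, `signal`),
#' or integrated `itc` injection heats (`injection`, `heat_kcal_per_mol`).
#'
#' @param data Data frame with the required columns for `kind`.
#' @param kind One of `"trace"`, `"kobs_series"`, `"denaturation"`, `"itc"`.
#' @param metadata Named list of experiment conditions (e.g. `temperature_K`,
#'   `cell_conc_uM`, `syringe_conc_uM`, `inj_volume_uL`, `cell_volume_uL`).
#' @return A tibble of class `evb_expt` carrying `kind` and `metadata`
#'   attributes.
#' @export
#' @examples
#' experiment_table(data.frame(urea_M = 0:8, signal = rnorm(9)),
#'                  "denaturation", list(temperature_K = 283.15))
experiment_table <- function(data, kind, metadata = list()) {
  kind <- match.arg(kind, EXPT_KINDS)
  data <- as_tibble(data)
  req <- expt_required_cols(kind)
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("experiment table of kind '%s' lacks required column(s): %s",
                  kind, paste(missing_cols, collapse = ", ")))
  }
  if (!is.list(metadata) || (length(metadata) > 0 && is.null(names(metadata)))) {
    abort("`metadata` must be a named list")
  }
  for (nm in grep("^temp", names(metadata), value = TRUE)) {
    if (is.numeric(metadata[[nm]]) && any(metadata[[nm]] <= 0)) {
      abort(sprintf("metadata '%s' must be > 0 (kelvin)", nm))
    }
  }
  for (col in req) {
    if (!is.numeric(data[[col]])) {
      abort(sprintf("column '%s' must be numeric", col))
    }
  }
  structure(data,
            kind = kind,
            metadata = metadata,
            class = c("evb_expt", class(data)))
}

#' @export
#' @rdname experiment_table
#' @param x An `evb_expt` object.
expt_kind <- function(x) attr(x, "kind", exact = TRUE)

#' @export
#' @rdname experiment_table
expt_metadata <- function(x) attr(x, "metadata", exact = TRUE) %||% list()

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_expt <- function(x, kind) {
  if (!inherits(x, "evb_expt") || !identical(expt_kind(x), kind)) {
    abort(sprintf("expected an experiment table of kind '%s'", kind))
  }
  invisible(x)
}

#' Read / write experiment tables as annotated CSV
#'
#' The on-disk form is a plain CSV preceded by two comment lines: the
#' experiment kind and a JSON metadata record. Round-trips exactly.
#'
#' @param path File path.
#' @return `read_experiment_csv()` returns an `evb_expt` tibble;
#'   `write_experiment_csv()` returns `path` invisibly.
#' @export
read_experiment_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  kind_line <- grep("^# kind:", hdr, value = TRUE)
  if (length(kind_line) != 1) {
    abort(sprintf("%s: expected exactly one '# kind:' comment line", path))
  }
  kind <- trimws(sub("^# kind:", "", kind_line))
  meta_line <- grep("^# metadata:", hdr, value = TRUE)
  metadata <- if (length(meta_line) == 1) {
    as.list(jsonlite::fromJSON(trimws(sub("^# metadata:", "", meta_line))))
  } else {
    list()
  }
  data <- readr::read_csv(I(lines[!startsWith(lines, "#")]),
                          show_col_types = FALSE, progress = FALSE)
  experiment_table(data, kind, metadata)
}

#' @param x An `evb_expt` object to serialise.
#' @export
#' @rdname read_experiment_csv
write_experiment_csv <- function(x, path) {
  if (!inherits(x, "evb_expt")) abort("`x` must be an experiment table")
  lines <- sprintf("# kind: %s", expt_kind(x))
  meta <- expt_metadata(x)
  if (length(meta) > 0) {
    lines <- c(lines, sprintf(
      "# metadata: %s",
      jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)))
  }
  body <- readr::format_csv(as_tibble(as.data.frame(x)))
  writeLines(c(lines, sub("\n$", "", body)), path)
  invisible(path)
}

#' @export
print.evb_expt <- function(x, ...) {
  cat(sprintf("<experiment table: %s, %d rows>\n", expt_kind(x), nrow(x)))
  meta <- expt_metadata(x)
  if (length(meta) > 0) {
    cat("metadata:", paste(names(meta), unlist(meta), sep = "=", collapse = ", "), "\n")
  }
  NextMethod()
}
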