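# CSV interchange (RFC 4180, header rows, units encoded in column names)
# and validated ingestion of per-cell morphometric records.

cell_record_columns <- c("cell_id", "state", "time_bin_h", "V_cell_um3",
                         "V_spindle_um3", "spindle_length_um",
                         "spindle_width_um", "V_centrosome_um3",
                         "rho_mg_per_ml", "mean_tubulin_signal")

#' Write per-cell records to CSV
#'
#' @param records tibble from [generate_cell_population()] (or compatible).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cell_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Read and validate per-cell records
#'
#' Reads the documented CSV schema (units in column names) and validates
#' every row: positive volumes and density, `0 < V_spindle < V_cell`,
#' `V_centrosome < V_spindle`.  Violations are reported per row with line
#' numbers; a missing mandatory column rejects the file.
#'
#' @param path CSV file written by [write_cell_records()] or following the
#'   same schema.
#' @param strict if TRUE (default) any invalid row aborts; otherwise
#'   invalid rows are dropped with a warning and returned in the
#'   `"problems"` attribute.
#' @return validated tibble of records.
#' @export
ingest_records <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "spindlescale_error_io")
  }
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(cell_record_columns, names(rec))
  if (length(miss)) {
    abort(paste0("Rejected file; missing mandatory column(s): ",
                 paste(miss, collapse = ", ")),
          class = "spindlescale_error_schema")
  }
  if (!nrow(rec)) return(rec)
  bad <- character(0)
  check <- function(cond, msg) {
    idx <- which(!cond)
    if (length(idx)) {
      bad <<- c(bad, sprintf("line %d: %s", idx + 1L, msg))
    }
  }
  check(is.finite(rec$V_cell_um3) & rec$V_cell_um3 > 0,
        "V_cell_um3 must be positive")
  check(is.finite(rec$V_spindle_um3) & rec$V_spindle_um3 > 0 &
          rec$V_spindle_um3 < rec$V_cell_um3,
        "V_spindle_um3 must satisfy 0 < V_spindle < V_cell")
  check(is.finite(rec$V_centrosome_um3) &
          rec$V_centrosome_um3 < rec$V_spindle_um3,
        "V_centrosome_um3 must be smaller than V_spindle_um3")
  check(is.finite(rec$rho_mg_per_ml) & rec$rho_mg_per_ml > 0,
        "rho_mg_per_ml must be positive")
  if (length(bad)) {
    if (strict) {
      abort(paste0("Invalid record rows:\n",
                   paste(utils::head(bad, 20), collapse = "\n")),
            class = "spindlescale_error_record")
    }
    warn(paste0(length(bad), " invalid rows dropped."))
    bad_lines <- as.integer(sub("line (\\d+):.*", "\\1", bad)) - 1L
    keep <- setdiff(seq_len(nrow(rec)), unique(bad_lines))
    out <- rec[keep, ]
    attr(out, "problems") <- bad
    return(out)
  }
  rec
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file; fields mirror [default_run_config()].
#' @return run-config list, merged over the defaults.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config(seed = cfg$seed %||% 1)
  modifyList(base, cfg)
}
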