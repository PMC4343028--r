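#' Per-comet scoring tables
#'
#' A `comet_dataset` is a `data.frame` holding one row per scored comet with
#' the canonical columns `experiment_id`, `sample_id`, `cell_index`, `tfi`
#' (total fluorescence intensity, arbitrary units, strictly positive),
#' `tail_dna_pct` (Tail %DNA in \[0, 100\], optional), `tail_moment`
#' (arbitrary units, optional), `dose_gy` (absorbed X-ray dose in gray,
#' optional) and `class_label` (assigned DNA-content class, `NA` until
#' gated). Extra columns (for example a simulation's `true_population`
#' ground truth) are carried along untouched. Row order is never changed by
#' reading or writing.
#'
#' Invariants enforced at construction and at read time:
#' * `tfi > 0` — a comet with zero integrated intensity is no stained object,
#'   not an undamaged cell;
#' * `tail_dna_pct`, when present, lies in \[0, 100\];
#' * `tail_moment` and `dose_gy`, when present, are non-negative;
#' * `(experiment_id, sample_id, cell_index)` is unique within the dataset.
#'
#' Absent optional measurements are stored as `NA`, never as 0.
#'
#' @param records data.frame with at least a `tfi` column; missing identifier
#'   columns are filled (`experiment_id = "E1"`, `sample_id = "S1"`,
#'   `cell_index` = row number) and missing optional columns are set to `NA`.
#' @param units_note free-text note on the intensity/damage units.
#' @param provenance free-text origin of the data.
#' @return A `comet_dataset` (also a `data.frame`).
#' @examples
#' comet_dataset(data.frame(tfi = c(2.5e5, 4.7e5), tail_dna_pct = c(1, 3)))
#' @export
comet_dataset <- function(records, units_note = "arbitrary units",
                          provenance = "") {
  if (!is.data.frame(records)) {
    abort_cometcal("`records` must be a data.frame", "cometcal_parameter_error")
  }
  if (!"tfi" %in% names(records)) {
    abort_cometcal("`records` must contain a `tfi` column",
                   "cometcal_format_error")
  }
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  n <- nrow(df)
  if (is.null(df$experiment_id)) df$experiment_id <- rep("E1", n)
  if (is.null(df$sample_id)) df$sample_id <- rep("S1", n)
  if (is.null(df$cell_index)) df$cell_index <- seq_len(n)
  for (col in c("tail_dna_pct", "tail_moment", "dose_gy")) {
    if (is.null(df[[col]])) df[[col]] <- rep(NA_real_, n)
  }
  if (is.null(df$class_label)) df$class_label <- rep(NA_character_, n)
  df$experiment_id <- as.character(df$experiment_id)
  df$sample_id <- as.character(df$sample_id)
  df$cell_index <- as.integer(df$cell_index)
  for (col in c("tfi", "tail_dna_pct", "tail_moment", "dose_gy")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$class_label <- as.character(df$class_label)
  df <- df[, c(canonical_comet_columns(),
               setdiff(names(df), canonical_comet_columns())), drop = FALSE]
  bad <- comet_record_problems(df)
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1L]
    abort_cometcal(sprintf("invalid comet record in row %d: %s", i, bad[i]),
                   "cometcal_row_error")
  }
  rownames(df) <- NULL
  structure(df,
            units_note = units_note,
            provenance = provenance,
            class = c("comet_dataset", "data.frame"))
}

canonical_comet_columns <- function() {
  c("experiment_id", "sample_id", "cell_index", "tfi",
    "tail_dna_pct", "tail_moment", "dose_gy", "class_label")
}

# One reason string per offending row, NA for valid rows.
comet_record_problems <- function(df) {
  n <- nrow(df)
  reason <- rep(NA_character_, n)
  flag <- function(idx, msg) {
    idx <- idx & is.na(reason)
    reason[idx] <<- msg
  }
  flag(is.na(df$tfi), "non-numeric or missing tfi")
  flag(!is.na(df$tfi) & df$tfi <= 0, "tfi must be > 0")
  flag(!is.na(df$tail_dna_pct) &
         (df$tail_dna_pct < 0 | df$tail_dna_pct > 100),
       "tail_dna_pct outside [0, 100]")
  flag(!is.na(df$tail_moment) & df$tail_moment < 0, "tail_moment < 0")
  flag(!is.na(df$dose_gy) & df$dose_gy < 0, "dose_gy < 0")
  key <- paste(df$experiment_id, df$sample_id, df$cell_index, sep = "\r")
  flag(duplicated(key), "duplicate (experiment_id, sample_id, cell_index)")
  reason
}

#' Default column mapping for comet scoring exports
#'
#' Maps `comet_dataset` field names to the column headers of the input file.
#' The default profile matches the package's own `write_comet_table()` output
#' and generic image-analysis exports; pass a modified copy for scorers that
#' use different headers. Entries whose column is absent from the file are
#' allowed only for optional fields.
#'
#' @return Named character vector `field -> file column`.
#' @export
default_column_map <- function() {
  cols <- canonical_comet_columns()
  structure(cols, names = cols)
}

#' Read a per-comet scoring table
#'
#' Reads a delimited text export (comma or tab; the delimiter is auto-detected
#' from the header line, decimal point only) into a [comet_dataset()]. No
#' intensity-based filtering happens at read time — comets are never dropped
#' for being very dim or very bright; only records violating the structural
#' invariants are rejected, and always loudly.
#'
#' @param path file to read.
#' @param column_map named character vector mapping `comet_dataset` fields to
#'   file column headers, see [default_column_map()].
#' @param policy `"reject"` (default) fails on the first invalid row;
#'   `"drop"` drops invalid rows and reports them in the `rejected` attribute
#'   (a data.frame of row numbers and reasons) and via a message.
#' @return A `comet_dataset`; under `policy = "drop"` the attribute
#'   `rejected` records every dropped data row (1-based, header excluded).
#' @export
read_comet_table <- function(path, column_map = default_column_map(),
                             policy = c("reject", "drop")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) {
    abort_cometcal(sprintf("file not found: %s", path), "cometcal_io_error")
  }
  header <- readLines(path, n = 1L)
  sep <- if (!grepl(",", header, fixed = TRUE) &&
             grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", na.strings = NULL,
                           stringsAsFactors = FALSE)
  required <- c("experiment_id", "sample_id", "cell_index", "tfi")
  for (field in names(column_map)) {
    col <- column_map[[field]]
    if (!col %in% names(raw) && field %in% required) {
      abort_cometcal(sprintf("required column '%s' (field %s) missing from %s",
                             col, field, path),
                     "cometcal_format_error")
    }
  }
  n <- nrow(raw)
  pick <- function(field, default) {
    col <- column_map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else rep(default, n)
  }
  num <- function(x) {
    x[x == ""] <- NA_character_
    suppressWarnings(as.numeric(x))
  }
  df <- data.frame(
    experiment_id = pick("experiment_id", "E1"),
    sample_id = pick("sample_id", "S1"),
    cell_index = num(pick("cell_index", NA_character_)),
    tfi = num(pick("tfi", NA_character_)),
    tail_dna_pct = num(pick("tail_dna_pct", NA_character_)),
    tail_moment = num(pick("tail_moment", NA_character_)),
    dose_gy = num(pick("dose_gy", NA_character_)),
    class_label = pick("class_label", NA_character_),
    stringsAsFactors = FALSE
  )
  df$class_label[df$class_label == ""] <- NA_character_
  # keep unmapped extra columns (e.g. simulation ground truth)
  extra <- setdiff(names(raw), column_map)
  for (col in extra) {
    df[[col]] <- utils::type.convert(raw[[col]], as.is = TRUE)
  }
  bad <- comet_record_problems(df)
  bad_rows <- which(!is.na(bad))
  if (length(bad_rows) > 0L) {
    if (policy == "reject") {
      abort_cometcal(
        sprintf("invalid rows in %s: %s", path,
                paste(sprintf("row %d (%s)", bad_rows, bad[bad_rows]),
                      collapse = "; ")),
        "cometcal_row_error")
    }
    message(sprintf("read_comet_table: dropped %d invalid row(s): %s",
                    length(bad_rows),
                    paste(sprintf("row %d (%s)", bad_rows, bad[bad_rows]),
                          collapse = "; ")))
    df <- df[-bad_rows, , drop = FALSE]
  }
  ds <- comet_dataset(df, provenance = path)
  attr(ds, "rejected") <- data.frame(
    row = bad_rows,
    reason = if (length(bad_rows)) bad[bad_rows] else character(0),
    stringsAsFactors = FALSE
  )
  ds
}

#' Write a per-comet scoring table
#'
#' Writes a `comet_dataset` as comma-separated text with a fixed header
#' (the canonical columns first, extra columns after). Numbers are written
#' with 17 significant digits so that `read_comet_table(write_comet_table(d))`
#' reproduces every value exactly; missing values (including an unassigned
#' `class_label`) become empty fields.
#'
#' @param dataset a [comet_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_comet_table <- function(dataset, path) {
  if (!inherits(dataset, "comet_dataset")) {
    abort_cometcal("`dataset` must be a comet_dataset", "cometcal_parameter_error")
  }
  df <- as.data.frame(dataset)
  out <- lapply(df, function(col) {
    if (is.numeric(col)) {
      s <- vapply(col, function(v) {
        if (is.na(v)) "" else formatC(v, digits = 17, format = "g")
      }, character(1))
      s
    } else {
      s <- as.character(col)
      s[is.na(s)] <- ""
      s
    }
  })
  out <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort_cometcal(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
                   "cometcal_io_error")
  }
  invisible(path)
}

#' @export
print.comet_dataset <- function(x, ...) {
  cat(sprintf("<comet_dataset> %d comets, %d experiment(s)\n",
              nrow(x), length(unique(x$experiment_id))))
  if (nzchar(attr(x, "provenance") %||% "")) {
    cat("provenance:", attr(x, "provenance"), "\n")
  }
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
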