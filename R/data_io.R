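#' Trial-level IAT dataset
#'
#' The universal long-format container for trial-level IAT data. One
#' row per trial with columns:
#'
#' * `participant_id` (character) — opaque participant identifier.
#' * `iat_type` (character) — `"good_bad"`, `"competent_incompetent"`
#'   or `"generic"`.
#' * `block_index` (integer, 1–7) — position in the standard 7-block
#'   schedule. Dual-stimulus (analysed) trials live in blocks 3, 4, 6
#'   and 7; blocks 1, 2 and 5 are single-stimulus training.
#' * `run_index` (integer, 1–2) — which dual-stimulus pairing run the
#'   trial belongs to (run 1 = blocks 3+4, run 2 = blocks 6+7).
#' * `trial_index` (integer, >= 1) — position within the run, counting
#'   continuously across the 20-trial block into the 40-trial block, so
#'   a full run spans 1..60.
#' * `compatibility` (character) — `"compatible"` or `"incompatible"`;
#'   `NA` allowed only on single-stimulus rows.
#' * `stimulus_class` (character, optional) — `"word"` or `"face"`.
#' * `rt_ms` (numeric, > 0) — response time in milliseconds.
#' * `correct` (logical, optional) — response accuracy.
#' * `condition_order` (character) — `"compatible_first"` or
#'   `"incompatible_first"`, constant within participant and IAT type.
#'
#' @param records a data frame with the columns above.
#' @param metadata named list of provenance (source, filters applied,
#'   seed); stored as an attribute and carried through I/O.
#' @param validate if `TRUE` (default), structural invariants are
#'   checked and any violation raises an error.
#' @return a tibble of class `iat_trials`.
#' @seealso [read_iat_trials()], [write_iat_trials()],
#'   [validate_iat_trials()]
#' @export
iat_trials <- function(records, metadata = list(), validate = TRUE) {
  records <- tibble::as_tibble(records)
  missing_cols <- setdiff(iat_required_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("trial data is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records$participant_id <- as.character(records$participant_id)
  records$iat_type <- as.character(records$iat_type)
  records$compatibility <- as.character(records$compatibility)
  records$condition_order <- as.character(records$condition_order)
  for (col in c("block_index", "run_index", "trial_index")) {
    records[[col]] <- as.integer(records[[col]])
  }
  if (!is.numeric(records$rt_ms)) {
    stop("`rt_ms` must be numeric", call. = FALSE)
  }
  if ("correct" %in% names(records) && !is.logical(records$correct)) {
    records$correct <- as.logical(records$correct)
  }
  optional <- intersect(c("stimulus_class", "correct"), names(records))
  metadata$optional_columns <- optional
  out <- structure(records,
                   metadata = metadata,
                   class = c("iat_trials", class(records)))
  if (validate) {
    v <- validate_iat_trials(out)
    if (nrow(v) > 0) {
      stop("trial data violates structural invariants:\n",
           paste(utils::capture.output(print(as.data.frame(v))),
                 collapse = "\n"),
           call. = FALSE)
    }
  }
  out
}

iat_required_columns <- function() {
  c("participant_id", "iat_type", "block_index", "run_index",
    "trial_index", "compatibility", "rt_ms", "condition_order")
}

iat_column_order <- function() {
  c("participant_id", "iat_type", "block_index", "run_index",
    "trial_index", "compatibility", "stimulus_class", "rt_ms",
    "correct", "condition_order")
}

#' Dataset metadata
#'
#' @param x an `iat_trials` object.
#' @return the provenance list stored with the dataset.
#' @export
iat_metadata <- function(x) {
  attr(x, "metadata") %||% list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate the structural invariants of a trial dataset
#'
#' Pure reporting operation: checks every structural rule and returns a
#' tibble of violations (zero rows when the dataset is compliant). The
#' rules are:
#'
#' * `dual_block` — rows carrying a compatibility label must sit in
#'   blocks 3, 4, 6 or 7 (block 5 has no dual-stimulus data).
#' * `duplicate_key` — no duplicated
#'   (participant, iat_type, block, trial) key.
#' * `trial_consecutive` — within (participant, iat_type, run),
#'   `trial_index` is consecutive from 1.
#' * `compat_constant` — compatibility is constant within a block.
#' * `runs_opposite` — the two runs of a (participant, iat_type) have
#'   opposite compatibility.
#' * `run_per_type` — every participant present has at least one run
#'   of every IAT type present in the dataset.
#' * `rt_positive` — response times are finite and strictly positive.
#'
#' @param x an `iat_trials` object or plain data frame with the same
#'   columns.
#' @return tibble with columns `rule`, `participant_id`, `detail`.
#' @export
validate_iat_trials <- function(x) {
  df <- tibble::as_tibble(x)
  bad <- list()
  note <- function(rule, pid, detail) {
    tibble::tibble(rule = rule, participant_id = as.character(pid),
                   detail = detail)
  }

  dual <- !is.na(df$compatibility)
  off_block <- dual & !(df$block_index %in% c(3L, 4L, 6L, 7L))
  if (any(off_block)) {
    for (i in which(off_block)) {
      bad[[length(bad) + 1L]] <- note(
        "dual_block", df$participant_id[i],
        sprintf("dual-stimulus trial in block %d (allowed: 3,4,6,7)",
                df$block_index[i]))
    }
  }

  key <- paste(df$participant_id, df$iat_type, df$block_index,
               df$trial_index, sep = "\r")
  dupe <- duplicated(key)
  if (any(dupe)) {
    for (i in which(dupe)) {
      bad[[length(bad) + 1L]] <- note(
        "duplicate_key", df$participant_id[i],
        sprintf("duplicate (iat_type=%s, block=%d, trial=%d)",
                df$iat_type[i], df$block_index[i], df$trial_index[i]))
    }
  }

  grp <- split(seq_len(nrow(df)),
               list(df$participant_id, df$iat_type, df$run_index),
               drop = TRUE)
  for (g in grp) {
    ti <- sort(df$trial_index[g])
    if (!identical(ti, seq_len(length(ti)))) {
      bad[[length(bad) + 1L]] <- note(
        "trial_consecutive", df$participant_id[g[1]],
        sprintf("iat_type=%s run=%d: trial_index not consecutive from 1",
                df$iat_type[g[1]], df$run_index[g[1]]))
    }
  }

  blk <- split(seq_len(nrow(df)),
               list(df$participant_id, df$iat_type, df$block_index),
               drop = TRUE)
  for (g in blk) {
    cmp <- unique(df$compatibility[g])
    cmp <- cmp[!is.na(cmp)]
    if (length(cmp) > 1) {
      bad[[length(bad) + 1L]] <- note(
        "compat_constant", df$participant_id[g[1]],
        sprintf("iat_type=%s block=%d mixes compatibility labels",
                df$iat_type[g[1]], df$block_index[g[1]]))
    }
  }

  pr <- split(seq_len(nrow(df)), list(df$participant_id, df$iat_type),
              drop = TRUE)
  for (g in pr) {
    runs <- split(df$compatibility[g], df$run_index[g])
    runs <- lapply(runs, function(v) unique(v[!is.na(v)]))
    if (length(runs) == 2 && all(lengths(runs) == 1) &&
        runs[[1]] == runs[[2]]) {
      bad[[length(bad) + 1L]] <- note(
        "runs_opposite", df$participant_id[g[1]],
        sprintf("iat_type=%s: both runs share compatibility '%s'",
                df$iat_type[g[1]], runs[[1]]))
    }
  }

  types <- unique(df$iat_type)
  for (pid in unique(df$participant_id)) {
    have <- unique(df$iat_type[df$participant_id == pid])
    miss <- setdiff(types, have)
    if (length(miss) > 0) {
      bad[[length(bad) + 1L]] <- note(
        "run_per_type", pid,
        paste("missing iat_type(s):", paste(miss, collapse = ", ")))
    }
  }

  bad_rt <- !is.finite(df$rt_ms) | df$rt_ms <= 0
  if (any(bad_rt)) {
    for (i in which(bad_rt)) {
      bad[[length(bad) + 1L]] <- note(
        "rt_positive", df$participant_id[i],
        sprintf("non-positive or non-finite rt_ms at block=%d trial=%d",
                df$block_index[i], df$trial_index[i]))
    }
  }

  if (length(bad) == 0) {
    tibble::tibble(rule = character(), participant_id = character(),
                   detail = character())
  } else {
    do.call(rbind, bad)
  }
}

#' Read a long-format trial CSV
#'
#' Reads the standard comma-separated, UTF-8, "." decimal trial format
#' (see [iat_trials()] for the schema). Rows with unparseable or
#' non-positive response times are rejected with row-level diagnostics
#' recorded in the metadata; structural invariant violations raise an
#' error.
#'
#' @param path path to an existing CSV file.
#' @param dialect CSV dialect; only `"standard"` is defined.
#' @return an `iat_trials` tibble. A JSON sidecar `<path>.json`, if
#'   present, is read into the metadata.
#' @export
read_iat_trials <- function(path, dialect = "standard") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("trial file does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"),
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(iat_required_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("trial file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rt <- suppressWarnings(as.numeric(df$rt_ms))
  rejected <- which(!is.finite(rt) | rt <= 0)
  if (length(rejected) > 0) {
    warning(sprintf("rejected %d row(s) with invalid rt_ms (rows: %s)",
                    length(rejected),
                    paste(utils::head(rejected, 10), collapse = ", ")),
            call. = FALSE)
    df <- df[-rejected, , drop = FALSE]
    rt <- rt[-rejected]
  }
  df$rt_ms <- rt
  meta <- list(source = path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- utils::modifyList(jsonlite::read_json(sidecar,
                                                  simplifyVector = TRUE),
                              meta)
  }
  if (length(rejected) > 0) meta$rejected_rows <- rejected
  iat_trials(df, metadata = meta, validate = TRUE)
}

#' Write a trial dataset to CSV
#'
#' Deterministic column order and number formatting; the result is
#' byte-identical under a read/write round trip. Metadata is written to
#' a JSON sidecar `<path>.json`.
#'
#' @param x an `iat_trials` object.
#' @param path destination file path.
#' @param sidecar write the metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_iat_trials <- function(x, path, sidecar = TRUE) {
  df <- tibble::as_tibble(x)
  cols <- intersect(iat_column_order(), names(df))
  df <- df[, cols, drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8", na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("could not write trial file '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  if (sidecar) {
    meta <- iat_metadata(x)
    if (length(meta) > 0) {
      jsonlite::write_json(meta, paste0(path, ".json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(path)
}

#' Participant-level external measures
#'
#' One row per participant with the behavioral/self-report measures
#' used in linkage analyses: internal and external motivation to
#' respond without prejudice (`ims`, `ems`; 1–9 scale means),
#' interviewer race and sex, seating distance (cm), the interviewer's
#' "seeming racist" rating (1–5), plus zero-centerable gender and age
#' covariates.
#'
#' @param df data frame with at least `participant_id`; recognised
#'   measure columns are `ims`, `ems`, `interviewer_race`,
#'   `interviewer_sex`, `seating_distance_cm`, `seeming_racist`,
#'   `gender`, `age`.
#' @return a tibble of class `external_measures`.
#' @export
external_measures <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"participant_id" %in% names(df)) {
    stop("external measures need a `participant_id` column",
         call. = FALSE)
  }
  df$participant_id <- as.character(df$participant_id)
  if (anyDuplicated(df$participant_id)) {
    stop("external measures must have one row per participant",
         call. = FALSE)
  }
  for (col in c("ims", "ems")) {
    if (col %in% names(df)) {
      v <- df[[col]]
      if (any(!is.na(v) & (v < 1 | v > 9))) {
        stop("`", col, "` must lie within the 1-9 scale bounds",
             call. = FALSE)
      }
    }
  }
  if ("seeming_racist" %in% names(df)) {
    v <- df$seeming_racist
    if (any(!is.na(v) & (v < 1 | v > 5))) {
      stop("`seeming_racist` must lie within the 1-5 scale bounds",
           call. = FALSE)
    }
  }
  structure(df, class = c("external_measures", class(df)))
}

#' Read / write participant-level external measures
#'
#' @param path CSV file path.
#' @return for `read_external_measures`, an `external_measures` tibble;
#'   for `write_external_measures`, `path` invisibly.
#' @export
read_external_measures <- function(path) {
  if (!file.exists(path)) {
    stop("external-measures file does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"),
                        fileEncoding = "UTF-8")
  external_measures(df)
}

#' @rdname read_external_measures
#' @param x an `external_measures` object.
#' @export
write_external_measures <- function(x, path) {
  utils::write.csv(tibble::as_tibble(x), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}
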