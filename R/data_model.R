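# Domain types and table I/O for free-report response data.
#
# A response table has one row per reported word. The canonical (package)
# dialect uses the column names in `response_columns()`; other dialects
# (e.g. a public deposit with different headers) are ingested through a
# column map.

#' Required response-table columns
#'
#' Field names of the canonical response dialect, one row per reported word.
#' `word` (the normalized form) is optional on input; it is added by
#' [clean_table()].
#'
#' @return Character vector of required column names.
#' @export
response_columns <- function() {
  c("participant_id", "block_id", "image_id", "soa_ms",
    "trial_index", "word_slot", "raw_word", "confidence")
}

#' Default column map for the package dialect
#'
#' A column map is a named character vector: names are canonical field names
#' (see [response_columns()]), values are the column headers found in the
#' file. The default maps every field to itself. An optional `order` entry
#' names a column giving each participant's order position within their
#' (image, SOA) cohort; when present it overrides first-appearance ordering
#' in [build_cohorts()].
#'
#' @return Named character vector.
#' @export
default_column_map <- function() {
  cols <- response_columns()
  stats::setNames(cols, cols)
}

#' Read a response table
#'
#' Reads a delimited text file of free-report responses (one row per reported
#' word), renames columns through `column_map`, and validates every row.
#' Rows failing validation are reported by row number; nothing is silently
#' dropped.
#'
#' @param path Path to a delimited text file with a header row (UTF-8).
#' @param column_map Named character vector mapping canonical field names to
#'   the file's column headers; see [default_column_map()].
#' @param sep Field separator (default comma).
#' @return A `data.frame` with the canonical columns (plus `word` and any
#'   `order` column if present in the file).
#' @export
read_responses <- function(path, column_map = default_column_map(), sep = ",") {
  if (!file.exists(path)) {
    stop("response file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  required <- response_columns()
  if (is.null(names(column_map)) || !all(required %in% names(column_map))) {
    stop("column_map must name all required fields: ",
         paste(setdiff(required, names(column_map)), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(unname(column_map[required]), names(raw))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    participant_id = raw[[column_map[["participant_id"]]]],
                    block_id = suppressWarnings(as.integer(raw[[column_map[["block_id"]]]])),
                    image_id = raw[[column_map[["image_id"]]]],
                    soa_ms = suppressWarnings(as.integer(raw[[column_map[["soa_ms"]]]])),
                    trial_index = suppressWarnings(as.integer(raw[[column_map[["trial_index"]]]])),
                    word_slot = suppressWarnings(as.integer(raw[[column_map[["word_slot"]]]])),
                    raw_word = raw[[column_map[["raw_word"]]]],
                    confidence = suppressWarnings(as.integer(raw[[column_map[["confidence"]]]])))
  for (extra in c("word", "order")) {
    if (!is.na(column_map[extra]) && !is.null(column_map[extra]) &&
        extra %in% names(column_map) && column_map[[extra]] %in% names(raw)) {
      out[[extra]] <- raw[[column_map[[extra]]]]
      if (extra == "order") out[[extra]] <- as.integer(out[[extra]])
    }
  }
  validate_responses(out)
  out
}

#' Validate a response table
#'
#' Checks types and ranges row by row: confidence in 1..5, SOA in the
#' observed design levels (67/133/267 ms by default), word slot in 1..5.
#' Fails with an error listing the offending row numbers.
#'
#' @param records Response `data.frame`.
#' @param soa_levels Allowed SOA values in milliseconds.
#' @return Invisibly, `records` (unchanged) when valid.
#' @export
validate_responses <- function(records, soa_levels = c(67L, 133L, 267L)) {
  problems <- character(0)
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx)) {
      shown <- utils::head(idx, 20L)
      problems <<- c(problems, paste0(
        what, " in row(s) ", paste(shown, collapse = ", "),
        if (length(idx) > 20L) sprintf(" (and %d more)", length(idx) - 20L) else ""))
    }
  }
  bad(is.na(records$confidence) | !(records$confidence %in% 1:5),
      "confidence outside 1..5")
  bad(is.na(records$soa_ms) | !(records$soa_ms %in% soa_levels),
      paste0("SOA not in {", paste(soa_levels, collapse = ","), "}"))
  bad(is.na(records$word_slot) | !(records$word_slot %in% 1:5),
      "word slot outside 1..5")
  bad(is.na(records$raw_word) | !nzchar(records$raw_word), "empty raw word")
  bad(is.na(records$participant_id) | !nzchar(records$participant_id),
      "empty participant id")
  bad(is.na(records$image_id) | !nzchar(records$image_id), "empty image id")
  if (length(problems)) {
    stop("invalid response rows:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(records)
}

#' Write a response table
#'
#' Writes the canonical delimited-text dialect consumed by
#' [read_responses()]; the round trip preserves all fields exactly.
#'
#' @param records Response `data.frame`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_responses <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Build per-(image, SOA) cohorts and the study design
#'
#' Each (image, SOA) cell gathers the participants who saw that image at
#' that SOA. Participants get an order position within the cell: the rank of
#' their first appearance in the table, unless `order_col` names an explicit
#' order column (in which case that column is used, making the ordering
#' reproducible under row shuffling). Cells whose size differs from
#' `n_per_cell` are flagged, not dropped. A participant seeing the same
#' image more than once (across SOAs or trials) is a design violation and an
#' error.
#'
#' @param records Validated response `data.frame`.
#' @param order_col Optional name of an explicit order column in `records`.
#' @param n_per_cell Expected participants per (image, SOA) cell; if `NULL`,
#'   the modal observed cell size is used.
#' @return An object of class `cohort_index`: a `data.frame` with columns
#'   `image_id`, `soa_ms`, `participant_id`, `order_pos`, with attributes
#'   `n_per_cell`, `design` (list: images, blocks, soa_levels) and
#'   `flagged_cells` (data.frame of off-size cells).
#' @export
build_cohorts <- function(records, order_col = NULL, n_per_cell = NULL) {
  trials <- records[!duplicated(records[c("participant_id", "image_id")]),
                    , drop = FALSE]
  # design violation: one participant, one image, more than one SOA or trial
  key <- paste(records$participant_id, records$image_id, sep = "\r")
  ctx <- paste(records$soa_ms, records$trial_index, sep = "\r")
  nctx <- tapply(ctx, key, function(v) length(unique(v)))
  if (any(nctx > 1L)) {
    offender <- names(nctx)[which(nctx > 1L)[1L]]
    parts <- strsplit(offender, "\r", fixed = TRUE)[[1L]]
    stop("design violation: participant '", parts[1L],
         "' saw image '", parts[2L], "' more than once", call. = FALSE)
  }
  if (!is.null(order_col)) {
    if (!order_col %in% names(records)) {
      stop("order column '", order_col, "' not found", call. = FALSE)
    }
    ord <- records[[order_col]][!duplicated(records[c("participant_id", "image_id")])]
    o <- order(trials$image_id, trials$soa_ms, ord)
  } else {
    o <- order(trials$image_id, trials$soa_ms,
               seq_len(nrow(trials)))  # first appearance
  }
  trials <- trials[o, , drop = FALSE]
  cell <- paste(trials$image_id, trials$soa_ms, sep = "\r")
  pos <- stats::ave(seq_along(cell), cell, FUN = seq_along)
  cohorts <- data.frame(image_id = trials$image_id,
                        soa_ms = trials$soa_ms,
                        participant_id = trials$participant_id,
                        order_pos = as.integer(pos),
                        stringsAsFactors = FALSE,
                        row.names = NULL)
  sizes <- table(cell)
  if (is.null(n_per_cell)) {
    tab <- table(as.integer(sizes))
    n_per_cell <- as.integer(names(tab)[which.max(tab)])
  }
  off <- sizes[as.integer(sizes) != n_per_cell]
  flagged <- if (length(off)) {
    parts <- do.call(rbind, strsplit(names(off), "\r", fixed = TRUE))
    data.frame(image_id = parts[, 1L], soa_ms = as.integer(parts[, 2L]),
               n_participants = as.integer(off), stringsAsFactors = FALSE)
  } else {
    data.frame(image_id = character(0), soa_ms = integer(0),
               n_participants = integer(0))
  }
  blocks <- lapply(split(records$image_id, records$block_id),
                   function(v) sort(unique(v)))
  design <- list(images = sort(unique(records$image_id)),
                 blocks = blocks,
                 soa_levels = sort(unique(records$soa_ms)))
  structure(cohorts, class = c("cohort_index", "data.frame"),
            n_per_cell = n_per_cell, design = design,
            flagged_cells = flagged)
}

#' Read a similar-image pair registry
#'
#' The registry is delimited text with columns `pair_id`, `image_a`,
#' `image_b`, `class` (`natural` or `artificial`). Registered partners are
#' excluded from each other's IA baselines and drive the SSE analyses.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator.
#' @return A `data.frame` with the four registry columns.
#' @export
read_similar_pairs <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("pair_id", "image_a", "image_b", "class")
  if (!all(need %in% names(df))) {
    stop("similar-pair registry must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df[need]
}

#' Assemble an analysis-ready dataset
#'
#' Bundles cleaned response records, the cohort index, the study design and
#' the similar-pair registry into the object consumed by [ia()],
#' [word_ia()], [frequency_vector()] and friends. Records must carry the
#' normalized `word` column produced by [clean_table()] (or constructed
#' fixtures). Within the dataset, reports are reduced to one row per
#' (participant, image, word): repeated reports of a word within a trial
#' should already have been removed by [dedup_within_trial()].
#'
#' @param records Cleaned response `data.frame` with a `word` column.
#' @param similar_pairs Optional similar-pair registry (see
#'   [read_similar_pairs()]).
#' @param order_col Optional explicit cohort-order column name.
#' @param n_per_cell Expected cohort size per (image, SOA) cell.
#' @return An object of class `ia_data`.
#' @export
ia_data <- function(records, similar_pairs = NULL, order_col = NULL,
                    n_per_cell = NULL) {
  if (!"word" %in% names(records) || anyNA(records$word)) {
    stop("records must carry a normalized 'word' column; run clean_table() first",
         call. = FALSE)
  }
  validate_responses(records, soa_levels = sort(unique(records$soa_ms)))
  cohorts <- build_cohorts(records, order_col = order_col,
                           n_per_cell = n_per_cell)
  if (nrow(attr(cohorts, "flagged_cells"))) {
    warning(nrow(attr(cohorts, "flagged_cells")),
            " (image, SOA) cell(s) deviate from the expected cohort size; ",
            "IA denominators assume exact cells", call. = FALSE)
  }
  design <- attr(cohorts, "design")
  npc <- attr(cohorts, "n_per_cell")

  key <- paste(records$participant_id, records$image_id, records$word,
               sep = "\r")
  rep_rows <- records[!duplicated(key), , drop = FALSE]
  m <- match(paste(rep_rows$image_id, rep_rows$soa_ms, rep_rows$participant_id,
                   sep = "\r"),
             paste(cohorts$image_id, cohorts$soa_ms, cohorts$participant_id,
                   sep = "\r"))
  reports <- data.frame(participant_id = rep_rows$participant_id,
                        image_id = rep_rows$image_id,
                        soa_ms = rep_rows$soa_ms,
                        word = rep_rows$word,
                        confidence = rep_rows$confidence,
                        order_pos = cohorts$order_pos[m],
                        stringsAsFactors = FALSE, row.names = NULL)
  images <- design$images
  soas <- design$soa_levels
  reports$img <- match(reports$image_id, images)
  reports$soa <- match(reports$soa_ms, soas)

  partner <- rep(NA_integer_, length(images))
  if (!is.null(similar_pairs) && nrow(similar_pairs)) {
    a <- match(similar_pairs$image_a, images)
    b <- match(similar_pairs$image_b, images)
    ok <- !is.na(a) & !is.na(b)
    partner[a[ok]] <- b[ok]
    partner[b[ok]] <- a[ok]
  }

  structure(list(reports = reports,
                 cohorts = cohorts,
                 design = design,
                 n_per_cell = npc,
                 images = images,
                 soa_levels = soas,
                 partner = partner,
                 similar_pairs = similar_pairs),
            class = "ia_data")
}

#' @export
print.ia_data <- function(x, ...) {
  cat("Free-report dataset:\n")
  cat("  ", length(x$images), "images,",
      length(unique(x$reports$participant_id)), "participants,",
      nrow(x$reports), "distinct (participant, image, word) reports\n")
  cat("  SOA levels (ms):", paste(x$soa_levels, collapse = ", "),
      "; cohort size per cell:", x$n_per_cell, "\n")
  if (!is.null(x$similar_pairs)) {
    cat("  similar pairs registered:", nrow(x$similar_pairs), "\n")
  }
  invisible(x)
}

#' Write a result table as delimited text and JSON
#'
#' Writes `<stem>.csv` and `<stem>.json` with identical content.
#'
#' @param x A `data.frame`, or a fitted object with an [as.data.frame()]
#'   method (e.g. an `ia_fit`).
#' @param stem Output path without extension.
#' @return Invisibly, the two paths written.
#' @export
write_results <- function(x, stem) {
  df <- as.data.frame(x)
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, ".json")
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(df, js, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}
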