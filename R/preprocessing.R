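# Deterministic cleaning of typed free reports: case folding, spell
# correction, lemmatization, within-trial deduplication.
#
# The original curation of this kind of data is typically semi-automatic (a
# human picks among spell-checker suggestions). Everything here is
# deterministic instead: a correction is accepted only when the dictionary
# service returns exactly one suggestion, or when a user-supplied manual map
# has an entry; otherwise the word passes through unchanged. Lemmatization
# is a fixed lookup table shipped with the package so results are stable
# across environments.

.wordia_env <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "wordia")
  if (!nzchar(path)) stop("missing package asset: ", file, call. = FALSE)
  path
}

#' Shipped spell-check dictionary
#'
#' The word list behind the default speller: lowercase known-good words.
#' Small by design; supply your own list (or speller) for real corpora.
#'
#' @return Character vector of dictionary words.
#' @export
ia_dictionary <- function() {
  if (is.null(.wordia_env$dictionary)) {
    .wordia_env$dictionary <-
      readLines(.extdata("dictionary.txt"), encoding = "UTF-8")
  }
  .wordia_env$dictionary
}

#' Shipped lemma lookup table
#'
#' Maps inflected forms (plurals, verb tenses) to a base form, e.g.
#' `children -> child`, `walked -> walk`. Fixed and versioned with the
#' package; base forms are never themselves keys, so lemmatization is
#' idempotent.
#'
#' @return Named character vector (names = inflected, values = base form).
#' @export
ia_lemma_table <- function() {
  if (is.null(.wordia_env$lemma)) {
    df <- utils::read.table(.extdata("lemma_table.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
    .wordia_env$lemma <- stats::setNames(df$base, df$inflected)
  }
  .wordia_env$lemma
}

#' Read a two-column word map
#'
#' Reads manual spell-correction maps or lemma overrides: delimited text
#' with two columns, raw form then replacement.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field separator.
#' @return Named character vector (names = raw, values = replacement).
#' @export
read_word_map <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("word map needs two columns", call. = FALSE)
  stats::setNames(df[[2L]], df[[1L]])
}

#' Shipped manual spell-correction map
#'
#' @return Named character vector (names = misspelling, values = correction).
#' @export
ia_manual_map <- function() {
  if (is.null(.wordia_env$manual)) {
    .wordia_env$manual <- read_word_map(.extdata("manual_map.csv"))
  }
  .wordia_env$manual
}

#' Build a deterministic dictionary speller
#'
#' Returns a suggestion service: a function taking a character vector of
#' words and returning a list of suggestion vectors (dictionary words within
#' Damerau-free edit distance 1). Words already in the dictionary, or
#' containing digits or hyphens, get no suggestions. [normalize_word()]
#' accepts a suggestion only when it is unique.
#'
#' @param dictionary Character vector of known-good lowercase words.
#' @return A function `f(words) -> list of character vectors`.
#' @export
dictionary_speller <- function(dictionary = ia_dictionary()) {
  dictionary <- unique(dictionary)
  dlen <- nchar(dictionary)
  force(dictionary)
  function(words) {
    out <- vector("list", length(words))
    checkable <- grepl("^[a-z]+$", words) & !(words %in% dictionary)
    for (i in which(checkable)) {
      w <- words[i]
      cand <- dictionary[abs(dlen - nchar(w)) <= 1L]
      if (length(cand)) {
        d <- utils::adist(w, cand)
        out[[i]] <- cand[d == 1L]
      } else {
        out[[i]] <- character(0)
      }
    }
    out[!checkable] <- list(character(0))
    out
  }
}

.default_speller <- function() {
  if (is.null(.wordia_env$speller)) {
    .wordia_env$speller <- dictionary_speller(ia_dictionary())
  }
  .wordia_env$speller
}

#' Normalize a reported word
#'
#' Applies the cleaning pipeline to raw typed words, in order: lowercase
#' (and reduction to letters, digits and hyphens; internal whitespace
#' becomes a hyphen), manual-map or unique-suggestion spell correction,
#' then table lemmatization. Unknown words pass through unchanged. The
#' result is a fixed point: normalizing twice equals normalizing once.
#'
#' @param raw Character vector of words as typed.
#' @param speller Suggestion service from [dictionary_speller()].
#' @param lemma_table Named character vector, inflected form to base form.
#' @param manual_map Named character vector, misspelling to correction;
#'   consulted before the speller.
#' @return Character vector of normalized words.
#' @export
normalize_word <- function(raw, speller = .default_speller(),
                           lemma_table = ia_lemma_table(),
                           manual_map = ia_manual_map()) {
  u <- unique(raw)
  w <- tolower(u)
  w <- gsub("\\s+", "-", trimws(w))
  w <- gsub("[^a-z0-9-]", "", w)
  w <- gsub("-+", "-", w)
  w <- gsub("^-|-$", "", w)
  # spell correction: manual map wins, else a unique dictionary suggestion
  if (length(manual_map)) {
    hit <- match(w, names(manual_map))
    w[!is.na(hit)] <- unname(manual_map[hit[!is.na(hit)]])
  }
  sugg <- speller(w)
  one <- vapply(sugg, length, integer(1)) == 1L
  w[one] <- vapply(sugg[one], `[[`, character(1), 1L)
  if (length(lemma_table)) {
    hit <- match(w, names(lemma_table))
    w[!is.na(hit)] <- unname(lemma_table[hit[!is.na(hit)]])
  }
  w[match(raw, u)]
}

#' Remove repeated words within a trial
#'
#' When a participant enters the same word more than once for one image,
#' only the earliest entry (lowest word slot) is kept, with its confidence;
#' later repeats are removed. Comparison uses the normalized `word` column,
#' so spelling/inflection variants that collapse to one form are
#' deduplicated too.
#'
#' @param records Response `data.frame` with a `word` column.
#' @return The records with within-trial repeats removed, original order
#'   preserved.
#' @export
dedup_within_trial <- function(records) {
  if (!nrow(records)) return(records)
  o <- order(records$participant_id, records$image_id, records$word_slot)
  key <- paste(records$participant_id, records$image_id, records$word,
               sep = "\r")
  dup_sorted <- duplicated(key[o])
  keep <- rep(TRUE, nrow(records))
  keep[o] <- !dup_sorted
  records[keep, , drop = FALSE]
}

#' Clean a response table
#'
#' Runs the full cleaning pipeline over a validated response table:
#' normalization of every raw word ([normalize_word()]), then within-trial
#' deduplication on the normalized forms ([dedup_within_trial()]). Returns
#' the cleaned records together with a `cleaning_report` accounting for
#' every change.
#'
#' @param records Validated response `data.frame` (with `raw_word`).
#' @param speller,lemma_table,manual_map Passed to [normalize_word()].
#' @return A list with elements `records` (cleaned, with a `word` column)
#'   and `report` (class `cleaning_report`).
#' @export
clean_table <- function(records, speller = .default_speller(),
                        lemma_table = ia_lemma_table(),
                        manual_map = ia_manual_map()) {
  n_in <- nrow(records)
  lc <- gsub("^-|-$", "",
             gsub("-+", "-",
                  gsub("[^a-z0-9-]", "",
                       gsub("\\s+", "-", trimws(tolower(records$raw_word))))))
  spelled <- normalize_word(records$raw_word, speller = speller,
                            lemma_table = character(0),
                            manual_map = manual_map)
  final <- normalize_word(records$raw_word, speller = speller,
                          lemma_table = lemma_table,
                          manual_map = manual_map)
  records$word <- final
  out <- dedup_within_trial(records)
  changed <- records$raw_word != final
  log <- unique(data.frame(raw_word = records$raw_word[changed],
                           word = final[changed],
                           stringsAsFactors = FALSE))
  report <- structure(
    list(n_input_rows = n_in,
         n_output_rows = nrow(out),
         n_dedup_removed = n_in - nrow(out),
         n_spell_corrected = sum(spelled != lc),
         n_lemmatized_changed = sum(final != spelled),
         mapping_log = log),
    class = "cleaning_report")
  list(records = out, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report:\n")
  cat(sprintf("  input rows            %d\n", x$n_input_rows))
  cat(sprintf("  removed as repeats    %d\n", x$n_dedup_removed))
  cat(sprintf("  spell-corrected       %d\n", x$n_spell_corrected))
  cat(sprintf("  changed by lemma      %d\n", x$n_lemmatized_changed))
  cat(sprintf("  distinct raw->final   %d\n", nrow(x$mapping_log)))
  invisible(x)
}
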