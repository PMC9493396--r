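# Headline analyses over IA results: confidence-IA correlations, the
# rarely-reported-word correlation, image rankings, and the model-ready
# response-level export.

.pearson <- function(xv, yv, what) {
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L) {
    stop(errorCondition(paste0("fewer than 3 points for ", what),
                        class = c("wordia_too_few_points", "error",
                                  "condition")))
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop(errorCondition(paste0("correlation undefined for ", what,
                               ": a variable is constant"),
                        class = c("wordia_degenerate_cor", "error",
                                  "condition")))
  }
  ct <- stats::cor.test(xv, yv, method = "pearson")
  structure(list(r = unname(ct$estimate),
                 df = unname(ct$parameter),
                 n = length(xv),
                 p = ct$p.value,
                 conf_int = as.numeric(ct$conf.int),
                 what = what),
            class = "ia_cor")
}

#' @export
print.ia_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation (%s):\n", x$what))
  cat(sprintf("  r = %.3f, df = %d, p %s, 95%% CI [%.3f, %.3f]\n",
              x$r, x$df,
              if (x$p < 0.001) "< .001" else sprintf("= %.3f", x$p),
              x$conf_int[1L], x$conf_int[2L]))
  invisible(x)
}

#' Correlate Word IA with confidence
#'
#' Two analysis levels:
#' * `"word_pooled"`: one point per defined pooled (word, image) group;
#'   x is the mean confidence over the group's reporters, y the pooled IA.
#' * `"response_per_soa"`: one point per individual response whose
#'   (word, image, SOA) group has a defined per-SOA IA; x is that
#'   response's confidence, y the group's per-SOA IA. `soa` restricts the
#'   analysis to one SOA level.
#'
#' Pearson r is reported with `df = n - 2` and a Fisher-z 95% CI.
#'
#' @param fit An `ia_fit` covering the needed scope(s).
#' @param data The [ia_data()] the fit was computed from (needed for
#'   response-level confidences).
#' @param level Analysis level.
#' @param soa Optional single SOA level for the response-level analysis.
#' @param exclude_dont_know Drop confidence-1 responses ("Don't Know")
#'   before correlating (response level only).
#' @return An object of class `ia_cor`.
#' @export
correlate_ia_confidence <- function(fit, data,
                                    level = c("word_pooled",
                                              "response_per_soa"),
                                    soa = NULL,
                                    exclude_dont_know = FALSE) {
  level <- match.arg(level)
  tab <- fit$table
  if (level == "word_pooled") {
    t <- tab[tab$scope == "pooled" & tab$defined, ]
    if (!nrow(t)) stop("fit has no defined pooled groups", call. = FALSE)
    return(.pearson(t$mean_confidence, t$ia,
                    "mean confidence vs pooled Word IA, per word"))
  }
  scopes <- if (is.null(soa)) as.character(data$soa_levels)
            else as.character(soa)
  t <- tab[tab$scope %in% scopes & tab$defined, ]
  if (!nrow(t)) {
    stop("fit has no defined per-SOA groups in scope ",
         paste(scopes, collapse = ","), call. = FALSE)
  }
  rp <- data$reports
  key <- paste(rp$word, rp$image_id, rp$soa_ms, sep = "\r")
  m <- match(key, paste(t$word, t$image_id, t$scope, sep = "\r"))
  sel <- !is.na(m)
  conf <- rp$confidence[sel]
  iav <- t$ia[m[sel]]
  if (exclude_dont_know) {
    keep <- conf > 1L
    conf <- conf[keep]; iav <- iav[keep]
  }
  .pearson(conf, iav,
           sprintf("response confidence vs per-SOA Word IA (SOA %s)",
                   paste(scopes, collapse = ",")))
}

#' Correlate the rarely-reported-word proportion with Image IA
#'
#' One point per image with a defined Image IA: x is the image's
#' proportion of rarely reported words (single-reporter groups), y its
#' Image IA.
#'
#' @param imgfit An `image_ia_fit` from [image_ia()].
#' @return An object of class `ia_cor`.
#' @export
correlate_rare_vs_imageia <- function(imgfit) {
  t <- imgfit[!is.na(imgfit$image_ia), , drop = FALSE]
  .pearson(t$prop_rare, t$image_ia,
           "proportion of rarely reported words vs Image IA, per image")
}

#' Rank images by Image IA with their most informative words
#'
#' Lists the `k` images with the highest (or lowest) Image IA; for each,
#' the defined words sorted by IA (descending), then report frequency
#' (descending), then alphabetically — a deterministic tie-break.
#'
#' @param imgfit An `image_ia_fit`.
#' @param fit The pooled `ia_fit` supplying per-word IA, frequency and
#'   mean confidence.
#' @param direction `"top"` or `"bottom"`.
#' @param k Number of images to list (truncated with a warning if fewer
#'   are available).
#' @param words_per_image Words shown per image.
#' @return An object of class `ia_ranking`: a list of per-image word
#'   tables, with the ranked image summary in `$images`.
#' @export
rank_images <- function(imgfit, fit, direction = c("top", "bottom"),
                        k = 5L, words_per_image = 5L) {
  direction <- match.arg(direction)
  t <- imgfit[!is.na(imgfit$image_ia), , drop = FALSE]
  if (k > nrow(t)) {
    warning("only ", nrow(t), " images with defined Image IA; truncating",
            call. = FALSE)
    k <- nrow(t)
  }
  o <- order(t$image_ia, decreasing = (direction == "top"))
  sel <- t[o[seq_len(k)], , drop = FALSE]
  pooled <- fit$table[fit$table$scope == "pooled" & fit$table$defined, ]
  words <- lapply(sel$image_id, function(im) {
    w <- pooled[pooled$image_id == im, , drop = FALSE]
    w <- w[order(-w$ia, -w$n_reporters, w$word), , drop = FALSE]
    utils::head(w[c("word", "ia", "n_reporters", "mean_confidence")],
                words_per_image)
  })
  names(words) <- sel$image_id
  structure(list(images = sel, words = words, direction = direction),
            class = "ia_ranking")
}

#' @export
print.ia_ranking <- function(x, ...) {
  cat(sprintf("%s %d images by Image IA:\n",
              if (x$direction == "top") "Top" else "Bottom",
              nrow(x$images)))
  for (i in seq_len(nrow(x$images))) {
    im <- x$images$image_id[i]
    cat(sprintf("  %s  Image IA = %.3f  (rarely reported: %.0f%%)\n",
                im, x$images$image_ia[i], 100 * x$images$prop_rare[i]))
    w <- x$words[[im]]
    for (j in seq_len(nrow(w))) {
      cat(sprintf("      %-20s IA %.3f  Fre. %2d  Con. %.1f\n",
                  w$word[j], w$ia[j], w$n_reporters[j],
                  w$mean_confidence[j]))
    }
  }
  invisible(x)
}

#' Model-ready response-level point table
#'
#' Exports one row per individual response whose (word, image, SOA) group
#' has a defined per-SOA Word IA: participant, image, SOA, word,
#' confidence and the group's IA. Intended for external mixed-model
#' software; no multilevel estimation is performed here.
#'
#' @param fit An `ia_fit` covering the per-SOA scopes.
#' @param data The [ia_data()] the fit was computed from.
#' @return A `data.frame`.
#' @export
ia_point_table <- function(fit, data) {
  t <- fit$table[fit$table$scope %in% as.character(data$soa_levels) &
                   fit$table$defined, ]
  rp <- data$reports
  m <- match(paste(rp$word, rp$image_id, rp$soa_ms, sep = "\r"),
             paste(t$word, t$image_id, t$scope, sep = "\r"))
  sel <- !is.na(m)
  data.frame(participant_id = rp$participant_id[sel],
             image_id = rp$image_id[sel],
             soa_ms = rp$soa_ms[sel],
             word = rp$word[sel],
             confidence = rp$confidence[sel],
             word_ia = t$ia[m[sel]],
             stringsAsFactors = FALSE, row.names = NULL)
}
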