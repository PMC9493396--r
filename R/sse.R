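# Report-frequency consistency between image pairs: the SSE statistic and
# its shuffled-pair bootstrap null.
#
# Two images shown to two separate participant cohorts are compared by the
# frequencies with which each word was reported (distinct participants
# across SOAs, 0..30 in the full design). Plotting one image's frequencies
# against the other's, perfect consistency puts every word on y = x; SSE
# sums the squared distances from that line over the union of words.

.sse_from_freq <- function(fa, fb, convention) {
  words <- union(names(fa), names(fb))
  a <- stats::setNames(numeric(length(words)), words)
  b <- a
  a[names(fa)] <- fa
  b[names(fb)] <- fb
  d2 <- (a - b)^2
  if (convention == "perpendicular") d2 <- d2 / 2
  list(sse = sum(d2), per_word = d2)
}

#' Word report frequencies for one image
#'
#' Count, for each word, the number of distinct participants (across SOAs)
#' who reported it on the image.
#'
#' @param x An [ia_data()] object.
#' @param image Image identifier.
#' @return Named integer vector of counts; unreported words are absent
#'   (treated as 0 when two images' vectors are united).
#' @export
frequency_vector <- function(x, image) {
  if (!image %in% x$images) stop("unknown image: ", image, call. = FALSE)
  rp <- x$reports
  sel <- rp$image_id == image
  tab <- table(rp$word[sel])
  stats::setNames(as.integer(tab), names(tab))
}

#' SSE consistency between two images' report frequencies
#'
#' Over the union of words reported on either image, sums the squared
#' distance of each (frequency on A, frequency on B) point from the
#' identity line. The default `"perpendicular"` convention uses the true
#' geometric distance to y = x, giving `sum((fA - fB)^2) / 2`; the
#' `"vertical"` convention drops the factor 2. SSE is symmetric and is 0
#' exactly when the two frequency vectors are identical.
#'
#' @param x An [ia_data()] object.
#' @param image_a,image_b Image identifiers.
#' @param convention `"perpendicular"` (default) or `"vertical"`.
#' @return An object of class `sse_result`: images, `sse`,
#'   `per_word_contributions`, `convention`.
#' @export
sse_pair <- function(x, image_a, image_b,
                     convention = c("perpendicular", "vertical")) {
  convention <- match.arg(convention)
  res <- .sse_from_freq(frequency_vector(x, image_a),
                        frequency_vector(x, image_b), convention)
  structure(list(image_a = image_a, image_b = image_b,
                 sse = res$sse, per_word_contributions = res$per_word,
                 convention = convention),
            class = "sse_result")
}

#' @export
print.sse_result <- function(x, ...) {
  cat(sprintf("SSE(%s, %s) = %g  [%s convention, %d words in union]\n",
              x$image_a, x$image_b, x$sse, x$convention,
              length(x$per_word_contributions)))
  invisible(x)
}

#' Observed SSE for a registry of similar pairs
#'
#' @param x An [ia_data()] object.
#' @param pairs Similar-pair registry (`pair_id`, `image_a`, `image_b`,
#'   `class`); see [read_similar_pairs()].
#' @param convention Passed to [sse_pair()].
#' @return A `data.frame` with one row per pair and its SSE.
#' @export
sse_similar <- function(x, pairs,
                        convention = c("perpendicular", "vertical")) {
  convention <- match.arg(convention)
  sse <- mapply(function(a, b) sse_pair(x, a, b, convention)$sse,
                pairs$image_a, pairs$image_b)
  data.frame(pair_id = pairs$pair_id, image_a = pairs$image_a,
             image_b = pairs$image_b, class = pairs$class,
             sse = as.numeric(sse), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Shuffled-pair bootstrap null for the mean SSE
#'
#' Builds the null distribution of the mean SSE over random image
#' pairings. Each iteration selects one image from each registered pair at
#' random and pairs it with an image drawn at random from the whole pool
#' (the union of the pairs' images, 48 in the full design), excluding the
#' selected image itself (self-pairing would give SSE 0 and bias the null
#' low); the mean SSE of the resulting pairings is recorded.
#'
#' @param x An [ia_data()] object.
#' @param pairs Similar-pair registry to shuffle (typically the natural
#'   pairs).
#' @param n_iter Number of bootstrap iterations (100 by default).
#' @param seed Optional integer seed for reproducibility.
#' @param convention Passed to [sse_pair()].
#' @param ci_level Central percentile interval level for the null means.
#' @return An object of class `sse_null`: `null_means` (length `n_iter`),
#'   `null_ci`, `observed` (per registered pair, via [sse_similar()]),
#'   `mean_observed`, `convention`.
#' @export
sse_null <- function(x, pairs, n_iter = 100L, seed = NULL,
                     convention = c("perpendicular", "vertical"),
                     ci_level = 0.99) {
  convention <- match.arg(convention)
  stopifnot(n_iter >= 1L)
  pool <- unique(c(pairs$image_a, pairs$image_b))
  if (length(pool) < 2L) {
    stop("need at least two distinct images in the pool", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  freqs <- lapply(stats::setNames(pool, pool),
                  function(im) frequency_vector(x, im))
  n_pairs <- nrow(pairs)
  null_means <- vapply(seq_len(n_iter), function(i) {
    first <- ifelse(stats::runif(n_pairs) < 0.5, pairs$image_a,
                    pairs$image_b)
    partner <- vapply(first, function(im) {
      sample(setdiff(pool, im), 1L)
    }, character(1))
    mean(mapply(function(a, b) {
      .sse_from_freq(freqs[[a]], freqs[[b]], convention)$sse
    }, first, partner))
  }, numeric(1))
  alpha <- (1 - ci_level) / 2
  observed <- sse_similar(x, pairs, convention)
  structure(list(null_means = null_means,
                 null_ci = unname(stats::quantile(null_means,
                                                  c(alpha, 1 - alpha))),
                 ci_level = ci_level,
                 observed = observed,
                 mean_observed = mean(observed$sse),
                 n_iter = n_iter,
                 convention = convention),
            class = "sse_null")
}

#' @export
print.sse_null <- function(x, ...) {
  cat(sprintf("Shuffled-pair bootstrap null of mean SSE (%d iterations, %s convention):\n",
              x$n_iter, x$convention))
  cat(sprintf("  null mean %.1f, %g%% interval [%.1f, %.1f]\n",
              mean(x$null_means), 100 * x$ci_level,
              x$null_ci[1L], x$null_ci[2L]))
  cat(sprintf("  observed mean SSE over %d registered pairs: %.1f\n",
              nrow(x$observed), x$mean_observed))
  invisible(x)
}

#' @export
plot.sse_null <- function(x, ...) {
  graphics::hist(x$null_means, breaks = 20, col = "lightblue",
                 main = "Mean SSE: observed vs shuffled-pair null",
                 xlab = "mean SSE",
                 xlim = range(c(x$null_means, x$mean_observed)), ...)
  graphics::abline(v = x$mean_observed, col = "darkgreen", lwd = 2)
  graphics::abline(v = x$null_ci, col = "blue", lty = 3)
  invisible(x)
}
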