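# Intersubjective agreement (IA): how specifically a reported word picks
# out its target image against the rest of the image set.
#
# For one reporter of a word on an image, the within-image report fraction
# (among the reporter's cohort peers) is compared, via an ROC over
# cumulative report-frequency curves, with the word's baseline report
# fractions on every other image. The area under that ROC is the
# reporter's AUC; Word IA is the mean AUC over the word's reporters, and
# is defined only when the word was reported by at least two participants.

.scope_code <- function(x, scope) {
  scope <- as.character(scope)
  if (identical(scope, "pooled")) return(0L)
  code <- match(scope, as.character(x$soa_levels))
  if (is.na(code)) {
    stop("scope must be \"pooled\" or one of: ",
         paste(x$soa_levels, collapse = ", "), call. = FALSE)
  }
  code
}

#' Within-image report fraction for one reporter
#'
#' The fraction of the reporter's comparison participants who also reported
#' the word on the target image. Per-SOA scope: the other `n - 1` members
#' of the reporter's (image, SOA) cohort (9 in the full design). Pooled
#' scope: all participants who saw the image, minus the reporter and minus
#' the participant occupying the reporter's order position in each other
#' SOA cohort (27 in the full design).
#'
#' @param x An [ia_data()] object.
#' @param word Normalized word.
#' @param image Image identifier.
#' @param scope `"pooled"` or one of the SOA levels (e.g. `67`).
#' @param reporter Participant identifier; must have reported `word` on
#'   `image` within the scope.
#' @return A fraction in `[0, 1]`.
#' @export
within_fraction <- function(x, word, image, scope, reporter) {
  code <- .scope_code(x, scope)
  rp <- x$reports
  rows <- rp$word == word & rp$image_id == image
  if (code > 0L) rows <- rows & rp$soa == code
  rrow <- which(rows & rp$participant_id == reporter)
  if (!length(rrow)) {
    stop("reporter '", reporter, "' did not report '", word, "' on image '",
         image, "' in this scope", call. = FALSE)
  }
  if (code > 0L) {
    (sum(rows) - 1L) / (x$n_per_cell - 1L)
  } else {
    o <- rp$order_pos[rrow[1L]]
    s <- rp$soa[rrow[1L]]
    removed_hits <- sum(rows & rp$order_pos == o & rp$soa != s)
    n_soa <- length(x$soa_levels)
    (sum(rows) - 1L - removed_hits) / (n_soa * (x$n_per_cell - 1L))
  }
}

#' Baseline report fractions of a word on all other images
#'
#' For every image other than the target (and other than the target's
#' registered similar partner, which is excluded from the baseline), the
#' fraction of comparison participants who reported the word there. The
#' participant at the reporter's cohort order position is removed from
#' every baseline cohort, so per-SOA denominators are `n - 1` (9) and
#' pooled denominators are `3(n - 1)` (27).
#'
#' @param x An [ia_data()] object.
#' @param word Normalized word.
#' @param scope `"pooled"` or one SOA level.
#' @param image Target image identifier (excluded, with its partner).
#' @param reporter_order Cohort order position (1..n) of the reporter.
#' @return Named numeric vector over the other images, zeros included
#'   (length 419, or 418 with a registered partner, in the full design).
#' @export
baseline_fractions <- function(x, word, scope, image, reporter_order) {
  code <- .scope_code(x, scope)
  rp <- x$reports
  tgt <- match(image, x$images)
  if (is.na(tgt)) stop("unknown image: ", image, call. = FALSE)
  pu <- x$partner[tgt]
  others <- setdiff(seq_along(x$images), c(tgt, pu))
  rows <- rp$word == word & rp$img != tgt & (is.na(pu) | rp$img != pu)
  if (code > 0L) {
    rows <- rows & rp$soa == code
    denom <- x$n_per_cell - 1L
  } else {
    denom <- length(x$soa_levels) * (x$n_per_cell - 1L)
  }
  counts <- stats::setNames(numeric(length(others)), x$images[others])
  if (any(rows)) {
    keep <- rows & rp$order_pos != reporter_order
    tab <- table(factor(rp$img[keep], levels = others))
    counts[] <- as.numeric(tab) / denom
  }
  counts
}

#' Cumulative report-frequency curves for target and baseline
#'
#' Builds the pair of cumulative curves from which the ROC is constructed.
#' Criteria are the descending union of the observed fractions with the
#' endpoints 1 and 0. At each criterion c, the target curve is the step
#' indicating whether the within-image fraction is at least c, and the
#' baseline curve is the proportion of other images whose fraction is at
#' least c (so both curves reach 1 at criterion 0).
#'
#' @param within Within-image report fraction in `[0, 1]`.
#' @param baseline Numeric vector of baseline fractions in `[0, 1]`.
#' @return An object of class `ia_curves` with elements `criteria`,
#'   `target_cum`, `baseline_cum`.
#' @export
make_curves <- function(within, baseline) {
  stopifnot(length(within) == 1L, within >= 0, within <= 1,
            all(baseline >= 0), all(baseline <= 1))
  if (!length(baseline)) {
    stop("no baseline images to compare against", call. = FALSE)
  }
  crit <- sort(unique(c(1, 0, within, baseline)), decreasing = TRUE)
  structure(list(
    criteria = crit,
    target_cum = as.numeric(within >= crit),
    baseline_cum = vapply(crit, function(cr) mean(baseline >= cr),
                          numeric(1)),
    within = within,
    n_other = length(baseline)), class = "ia_curves")
}

#' @export
print.ia_curves <- function(x, ...) {
  cat("Cumulative report curves over", length(x$criteria), "criteria;",
      "within-image fraction", sprintf("%.3f", x$within),
      sprintf("(%d%%),", round(100 * x$within)),
      x$n_other, "baseline images\n")
  invisible(x)
}

#' @export
plot.ia_curves <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(oldpar))
  pct <- 100 * x$criteria
  graphics::plot(pct, 100 * x$baseline_cum, type = "s", col = "red",
                 xlim = c(100, 0), ylim = c(0, 100),
                 xlab = "% participants reporting (criterion, descending)",
                 ylab = "cumulative % of images", ...)
  graphics::lines(pct, 100 * x$target_cum, type = "s", col = "darkgreen")
  graphics::legend("topleft", legend = c("other images", "target image"),
                   col = c("red", "darkgreen"), lty = 1, bty = "n")
  graphics::plot(c(0, x$baseline_cum), c(0, x$target_cum), type = "l",
                 xlab = "baseline cumulative", ylab = "target cumulative",
                 xlim = c(0, 1), ylim = c(0, 1), main = "ROC")
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Area under the report-frequency ROC
#'
#' Constructs the ROC from the two cumulative curves of [make_curves()]
#' (baseline cumulative as x, target cumulative as y, across all criteria,
#' anchored at the origin) and integrates it with the trapezoidal rule.
#' Equals the closed form `P(b < within) + P(b = within) / 2` over the
#' baseline fractions `b`.
#'
#' @inheritParams make_curves
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(within, baseline) {
  cv <- make_curves(within, baseline)
  xs <- c(0, cv$baseline_cum)
  ys <- c(0, cv$target_cum)
  sum(diff(xs) * (ys[-length(ys)] + ys[-1L]) / 2)
}

#' Word IA for one (word, image, scope) triple
#'
#' One AUC per reporter of the word on the image in the scope, using that
#' reporter's leave-one-out within fraction and order-matched baseline;
#' the IA is the mean of the reporter AUCs. Undefined (with an explicit
#' status) when the word has fewer than two reporters ("rarely reported
#' word") or was never reported on the image.
#'
#' @param x An [ia_data()] object.
#' @param word Normalized word.
#' @param image Image identifier.
#' @param scope `"pooled"` (default) or one SOA level.
#' @return An object of class `word_ia`: word, image_id, scope,
#'   n_reporters, reporter_aucs, ia (`NA` when undefined), status
#'   (`"ok"`, `"rare"`, or `"unreported"`).
#' @export
word_ia <- function(x, word, image, scope = "pooled") {
  code <- .scope_code(x, scope)
  rp <- x$reports
  rows <- which(rp$word == word & rp$image_id == image &
                  (code == 0L | rp$soa == code))
  n_rep <- length(rows)
  status <- if (n_rep == 0L) "unreported" else if (n_rep == 1L) "rare" else "ok"
  aucs <- numeric(0)
  if (status == "ok") {
    aucs <- vapply(rows, function(r) {
      w_frac <- within_fraction(x, word, image, scope, rp$participant_id[r])
      b <- baseline_fractions(x, word, scope, image, rp$order_pos[r])
      roc_auc(w_frac, b)
    }, numeric(1))
  }
  structure(list(word = word, image_id = image,
                 scope = as.character(scope), n_reporters = n_rep,
                 reporter_aucs = aucs,
                 ia = if (status == "ok") mean(aucs) else NA_real_,
                 status = status),
            class = "word_ia")
}

#' @export
print.word_ia <- function(x, ...) {
  cat(sprintf("Word IA of '%s' on image '%s' (scope %s): ",
              x$word, x$image_id, x$scope))
  if (x$status == "ok") {
    cat(sprintf("%.4f (mean of %d reporter AUCs)\n", x$ia, x$n_reporters))
  } else if (x$status == "rare") {
    cat("undefined (rarely reported: single reporter)\n")
  } else {
    cat("undefined (word not reported on this image)\n")
  }
  invisible(x)
}

# Fast path over all (word, image) groups of one word. Integer-coded
# inputs; key = img * (npc + 1) + order identifies a (cell, order) slot.
.ia_groups_for_word <- function(img, ord, soa, conf, code, npc, n_images,
                                partner, n_soa) {
  mult <- npc + 1L
  if (code > 0L) {
    sel <- soa == code
    img <- img[sel]; ord <- ord[sel]; conf <- conf[sel]
    if (!length(img)) return(NULL)
    denom <- npc - 1L
  } else {
    denom <- n_soa * (npc - 1L)
  }
  u <- unique(img)
  mi <- match(img, u)
  cnt <- tabulate(mi, length(u))
  keys <- img * mult + ord
  ukeys <- unique(keys)
  kcnt <- tabulate(match(keys, ukeys), length(ukeys))
  ia <- rep(NA_real_, length(u))
  mconf <- vapply(seq_along(u), function(k) mean(conf[mi == k]), numeric(1))
  for (k in seq_along(u)) {
    if (cnt[k] < 2L) next
    tgt <- u[k]
    pu <- partner[tgt]
    selo <- u != tgt & (is.na(pu) | u != pu)
    uo <- u[selo]
    co <- cnt[selo]
    n_other <- n_images - 1L - as.integer(!is.na(pu))
    rep_rows <- which(mi == k)
    aucs <- vapply(rep_rows, function(r) {
      o <- ord[r]
      hit <- match(uo * mult + o, ukeys)
      excl <- ifelse(is.na(hit), 0L, kcnt[hit])
      if (code > 0L) {
        t_frac <- (cnt[k] - 1L) / denom
        adj <- co - as.integer(!is.na(hit))
      } else {
        m_io <- kcnt[match(tgt * mult + o, ukeys)]
        t_frac <- (cnt[k] - m_io) / denom
        adj <- co - excl
      }
      b <- numeric(n_other)
      if (length(adj)) b[seq_along(adj)] <- adj / denom
      roc_auc(t_frac, b)
    }, numeric(1))
    ia[k] <- mean(aucs)
  }
  list(img = u, n_reporters = cnt, ia = ia, mean_confidence = mconf)
}

#' Compute Word IA for every reported (word, image) group
#'
#' The main computation: for each scope requested, every (word, image)
#' group with at least one report gets a row with its reporter count and
#' its IA (`NA`, never 0, when undefined — groups with a single reporter
#' are the "rarely reported words"). Registered similar partners are
#' excluded from baselines.
#'
#' @param x An [ia_data()] object.
#' @param scope `"pooled"` (default), one or more SOA levels, `"per_soa"`
#'   (all SOA levels), or `"all"` (pooled plus all SOA levels).
#' @return An object of class `ia_fit` whose `table` is a `data.frame`
#'   with columns `word`, `image_id`, `scope`, `n_reporters`, `ia`,
#'   `defined`, `mean_confidence`.
#' @export
ia <- function(x, scope = "pooled") {
  stopifnot(inherits(x, "ia_data"))
  scope <- as.character(scope)
  if (identical(scope, "per_soa")) scope <- as.character(x$soa_levels)
  if (identical(scope, "all")) scope <- c("pooled", as.character(x$soa_levels))
  rp <- x$reports
  idx <- split(seq_len(nrow(rp)), rp$word)
  words <- names(idx)
  npc <- x$n_per_cell
  n_images <- length(x$images)
  n_soa <- length(x$soa_levels)
  out <- vector("list", length(scope))
  for (si in seq_along(scope)) {
    code <- .scope_code(x, scope[si])
    acc <- vector("list", length(words))
    for (wi in seq_along(words)) {
      ii <- idx[[wi]]
      g <- .ia_groups_for_word(rp$img[ii], rp$order_pos[ii], rp$soa[ii],
                               rp$confidence[ii], code, npc, n_images,
                               x$partner, n_soa)
      if (!is.null(g)) {
        g$word <- rep(words[wi], length(g$img))
        acc[[wi]] <- g
      }
    }
    acc <- acc[!vapply(acc, is.null, logical(1))]
    out[[si]] <- data.frame(
      word = unlist(lapply(acc, `[[`, "word"), use.names = FALSE),
      image_id = x$images[unlist(lapply(acc, `[[`, "img"),
                                 use.names = FALSE)],
      scope = scope[si],
      n_reporters = unlist(lapply(acc, `[[`, "n_reporters"),
                           use.names = FALSE),
      ia = unlist(lapply(acc, `[[`, "ia"), use.names = FALSE),
      mean_confidence = unlist(lapply(acc, `[[`, "mean_confidence"),
                               use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab$defined <- !is.na(tab$ia)
  tab <- tab[c("word", "image_id", "scope", "n_reporters", "ia", "defined",
               "mean_confidence")]
  structure(list(table = tab, scopes = scope, n_images = n_images,
                 n_per_cell = npc, soa_levels = x$soa_levels),
            class = "ia_fit")
}

#' @export
as.data.frame.ia_fit <- function(x, ...) x$table

#' @export
print.ia_fit <- function(x, ...) {
  cat("Word IA fit:", nrow(x$table), "(word, image) groups over",
      x$n_images, "images; scopes:", paste(x$scopes, collapse = ", "), "\n")
  for (s in x$scopes) {
    t <- x$table[x$table$scope == s, ]
    cat(sprintf("  scope %-7s %6d groups, %6d defined, %6d rarely reported; mean IA %.3f\n",
                s, nrow(t), sum(t$defined), sum(t$n_reporters == 1L),
                mean(t$ia, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
plot.ia_fit <- function(x, scope = x$scopes[1L], ...) {
  t <- x$table[x$table$scope == scope & x$table$defined, ]
  graphics::plot(jitter(t$n_reporters), t$ia, pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.4),
                 xlab = "report frequency (participants)", ylab = "Word IA",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' @export
summary.ia_fit <- function(object, ...) ia_summary(object)

#' Distribution summary of Word IA
#'
#' Mean, SD, median and quartiles of the defined IA values per scope,
#' together with the counts of defined versus rarely-reported (single
#' reporter) groups. Undefined IAs are never averaged in.
#'
#' @param fit An `ia_fit` from [ia()].
#' @return An object of class `ia_summary` (a `data.frame`, one row per
#'   scope).
#' @export
ia_summary <- function(fit) {
  tab <- fit$table
  if (!any(tab$defined)) {
    stop(errorCondition("no defined IA values to summarise",
                        class = c("wordia_empty_summary", "error",
                                  "condition")))
  }
  rows <- lapply(fit$scopes, function(s) {
    t <- tab[tab$scope == s, ]
    v <- t$ia[t$defined]
    data.frame(scope = s,
               n_groups = nrow(t),
               n_defined = sum(t$defined),
               n_rare = sum(t$n_reporters == 1L),
               mean = mean(v), sd = stats::sd(v),
               median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("ia_summary", "data.frame"))
}

#' @export
print.ia_summary <- function(x, ...) {
  cat("Word IA summary (defined groups only):\n")
  df <- as.data.frame(unclass(x), stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "n_groups" &
    names(df) != "n_defined" & names(df) != "n_rare"
  df[num] <- lapply(df[num], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Image IA and rarely-reported-word proportions
#'
#' Image IA is the mean of the defined pooled Word IAs of all words
#' reported on the image; it is `NA` when the image has no defined word.
#' `prop_rare` is the fraction of the image's (word) groups reported by
#' exactly one participant.
#'
#' @param fit An `ia_fit` containing the `"pooled"` scope.
#' @return An object of class `image_ia_fit` (a `data.frame` with columns
#'   `image_id`, `image_ia`, `n_defined_words`, `n_words`, `prop_rare`).
#' @export
image_ia <- function(fit) {
  tab <- fit$table[fit$table$scope == "pooled", ]
  if (!nrow(tab)) {
    stop("image_ia needs an ia() fit computed with the \"pooled\" scope",
         call. = FALSE)
  }
  sp <- split(tab, tab$image_id)
  rows <- lapply(sp, function(t) {
    v <- t$ia[t$defined]
    data.frame(image_id = t$image_id[1L],
               image_ia = if (length(v)) mean(v) else NA_real_,
               n_defined_words = length(v),
               n_words = nrow(t),
               prop_rare = sum(t$n_reporters == 1L) / nrow(t),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  structure(out, class = c("image_ia_fit", "data.frame"))
}

#' @export
print.image_ia_fit <- function(x, ...) {
  cat("Image IA over", nrow(x), "images: mean",
      sprintf("%.3f", mean(x$image_ia, na.rm = TRUE)),
      "; mean proportion of rarely reported words",
      sprintf("%.3f", mean(x$prop_rare)), "\n")
  invisible(x)
}
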