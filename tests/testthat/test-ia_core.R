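test_that("trapezoidal ROC area equals the pairwise-comparison closed form", {
  set.seed(20260922)
  for (i in 1:400) {
    denom <- sample(c(3L, 9L, 27L), 1L)
    n_other <- sample(2:60, 1L)
    b <- rand_fracs(n_other, denom)
    t_frac <- rand_fracs(1L, denom)
    expect_equal(roc_auc(t_frac, b), auc_pairwise_oracle(t_frac, b))
  }
})

test_that("AUC is bounded, permutation-invariant, and 1 iff baseline below", {
  set.seed(1)
  for (i in 1:200) {
    b <- rand_fracs(sample(2:40, 1L))
    t_frac <- rand_fracs(1L)
    a <- roc_auc(t_frac, b)
    expect_gte(a, 0); expect_lte(a, 1)
    expect_equal(roc_auc(t_frac, sample(b)), a)
    expect_equal(a == 1, all(b < t_frac))
  }
})

test_that("dropping a baseline image above within never lowers AUC", {
  # a partner image on which the word is reported more often than the
  # within fraction can only depress the AUC; excluding it cannot hurt.
  # (An image exactly tied with the within fraction can pull either way,
  # so the guarantee is for strictly larger fractions.)
  set.seed(2)
  for (i in 1:200) {
    b <- rand_fracs(sample(3:40, 1L))
    t_frac <- rand_fracs(1L)
    high <- which(b > t_frac)
    if (!length(high)) next
    drop <- high[sample.int(length(high), 1L)]
    expect_gte(roc_auc(t_frac, b[-drop]), roc_auc(t_frac, b))
    # ties never lower an above-chance AUC either
    tie <- which(b == t_frac)
    if (length(tie) && roc_auc(t_frac, b) >= 0.5) {
      expect_gte(roc_auc(t_frac, b[-tie[1L]]), roc_auc(t_frac, b))
    }
  }
})

test_that("hand-computed curve and AUC examples come out exactly", {
  # a word reported by 5 of 9 peers, never reported elsewhere
  cv <- make_curves(5 / 9, rep(0, 419))
  expect_equal(cv$criteria[cv$target_cum == 1][1L], 5 / 9)  # step at 56%
  expect_equal(cv$baseline_cum[cv$criteria > 0], rep(0, sum(cv$criteria > 0)))
  expect_equal(cv$baseline_cum[cv$criteria == 0], 1)  # baseline jumps at 0
  expect_equal(roc_auc(5 / 9, rep(0, 419)), 1)

  # chance level when the baseline everywhere matches the within fraction
  expect_equal(roc_auc(0.4, rep(0.4, 10)), 0.5)

  # two baseline values straddling the criterion grid
  cv2 <- make_curves(0.9, c(0.2, 0.4))
  expect_equal(cv2$baseline_cum[cv2$criteria == 0.4], 0.5)
  expect_equal(cv2$baseline_cum[cv2$criteria == 0.2], 1.0)

  # half the baseline below, half above
  expect_equal(roc_auc(0.5, c(0, 0, 1, 1)), 0.5)

  # an unreported word's target curve rises only at criterion 0
  cv3 <- make_curves(0, c(0.3, 0.6))
  expect_equal(cv3$target_cum, as.numeric(cv3$criteria == 0))
})

test_that("within and baseline fractions implement the leave-out rules", {
  fx <- make_fixture("eiffel")
  x <- ia_data(fx$records)
  # 6 reporters in the 67 ms cell of img001 -> each sees 5 of 9 peers
  expect_equal(within_fraction(x, "eiffel-tower", "img001", 67, "p01"),
               5 / 9)
  b <- baseline_fractions(x, "eiffel-tower", 67, "img001", 1L)
  expect_length(b, 5L)  # 6 images, target excluded
  expect_true(all(b == 0))
  # pooled scope: 27 comparison participants
  expect_equal(within_fraction(x, "eiffel-tower", "img001", "pooled", "p01"),
               5 / 27)
  expect_error(within_fraction(x, "eiffel-tower", "img002", 67, "p01"),
               "did not report")
})

test_that("a registered similar partner is excluded from the baseline", {
  p <- small_pipeline()
  x <- p$x
  pairs <- p$sim$similar_pairs
  a <- pairs$image_a[1L]
  bimg <- pairs$image_b[1L]
  w <- x$reports$word[x$reports$image_id == a][1L]
  ord <- x$reports$order_pos[x$reports$image_id == a][1L]
  b_with <- baseline_fractions(x, w, "pooled", a, ord)
  expect_length(b_with, length(x$images) - 2L)
  expect_false(bimg %in% names(b_with))
  # for an unpaired image the baseline has one more entry
  unpaired <- setdiff(x$images, c(pairs$image_a, pairs$image_b))[1L]
  w2 <- x$reports$word[x$reports$image_id == unpaired][1L]
  expect_length(baseline_fractions(x, w2, "pooled", unpaired, 1L),
                length(x$images) - 1L)
})

test_that("word_ia handles defined, rare and unreported cases distinctly", {
  fx <- make_fixture("eiffel")
  x <- ia_data(fx$records)
  w <- word_ia(x, "eiffel-tower", "img001", 67)
  expect_equal(w$status, "ok")
  expect_equal(w$n_reporters, 6L)
  expect_equal(w$reporter_aucs, rep(1, 6L))
  expect_equal(w$ia, 1)
  # a filler word: reported by exactly one participant
  filler <- fx$records$word[!fx$records$word %in% "eiffel-tower"][1L]
  img <- fx$records$image_id[fx$records$word == filler][1L]
  rare <- word_ia(x, filler, img, "pooled")
  expect_equal(rare$status, "rare")
  expect_true(is.na(rare$ia))
  none <- word_ia(x, "eiffel-tower", "img002", 67)
  expect_equal(none$status, "unreported")
  expect_true(is.na(none$ia))
})

test_that("the vectorized fit agrees with the single-triple computation", {
  p <- small_pipeline()
  x <- p$x
  fit <- ia(x, scope = "all")
  tab <- fit$table[fit$table$defined, ]
  set.seed(4)
  for (r in sample.int(nrow(tab), 25L)) {
    w <- word_ia(x, tab$word[r], tab$image_id[r], tab$scope[r])
    expect_equal(w$ia, tab$ia[r], info = paste(tab$word[r], tab$scope[r]))
    expect_equal(w$n_reporters, tab$n_reporters[r])
  }
})

test_that("Word IA is invariant to relabeling images and participants", {
  p <- small_pipeline()
  rec <- p$records
  set.seed(8)
  imap <- setNames(sprintf("pic-%s", sample(LETTERS, length(unique(rec$image_id)))),
                   sort(unique(rec$image_id)))
  pmap <- setNames(sprintf("subj-%03d", sample(900:999, length(unique(rec$participant_id)))),
                   sort(unique(rec$participant_id)))
  rec2 <- rec
  rec2$image_id <- unname(imap[rec$image_id])
  rec2$participant_id <- unname(pmap[rec$participant_id])
  pairs2 <- p$sim$similar_pairs
  pairs2$image_a <- unname(imap[pairs2$image_a])
  pairs2$image_b <- unname(imap[pairs2$image_b])
  fit1 <- ia(p$x, scope = "pooled")$table
  fit2 <- ia(ia_data(rec2, similar_pairs = pairs2), scope = "pooled")$table
  fit2$image_id <- names(imap)[match(fit2$image_id, imap)]
  o1 <- order(fit1$word, fit1$image_id)
  o2 <- order(fit2$word, fit2$image_id)
  expect_equal(fit1$ia[o1], fit2$ia[o2])
  expect_equal(fit1$n_reporters[o1], fit2$n_reporters[o2])
})

test_that("image IA averages defined pooled words; singletons feed prop_rare", {
  fx <- make_fixture("sperling")
  x <- ia_data(fx$records)
  fit <- ia(x, scope = "pooled")
  imf <- image_ia(fit)
  expect_equal(imf$image_ia, rep(1, 6L))
  expect_equal(imf$prop_rare, rep(0, 6L))

  # hand-built fit: defined IAs {1.0, 0.6} average to 0.8; an image with
  # only singletons has undefined image IA and prop_rare 1
  tab <- data.frame(
    word = c("a", "b", "c", "d"),
    image_id = c("i1", "i1", "i1", "i2"),
    scope = "pooled",
    n_reporters = c(3L, 2L, 1L, 1L),
    ia = c(1.0, 0.6, NA, NA),
    defined = c(TRUE, TRUE, FALSE, FALSE),
    mean_confidence = 3, stringsAsFactors = FALSE)
  fake <- structure(list(table = tab, scopes = "pooled"), class = "ia_fit")
  imf2 <- image_ia(fake)
  expect_equal(imf2$image_ia[imf2$image_id == "i1"], 0.8)
  expect_equal(imf2$prop_rare[imf2$image_id == "i1"], 1 / 3)
  expect_true(is.na(imf2$image_ia[imf2$image_id == "i2"]))
  expect_equal(imf2$prop_rare[imf2$image_id == "i2"], 1)
})

test_that("ia_summary reports moments over defined groups only", {
  tab <- data.frame(word = c("a", "b", "c"), image_id = "i1",
                    scope = "pooled", n_reporters = c(2L, 3L, 1L),
                    ia = c(0.8, 1.0, NA), defined = c(TRUE, TRUE, FALSE),
                    mean_confidence = 3, stringsAsFactors = FALSE)
  fake <- structure(list(table = tab, scopes = "pooled"), class = "ia_fit")
  s <- ia_summary(fake)
  expect_equal(s$mean, 0.9)
  expect_equal(s$median, 0.9)
  expect_equal(s$n_defined, 2L)
  expect_equal(s$n_rare, 1L)

  tab$defined <- FALSE
  tab$ia <- NA_real_
  empty <- structure(list(table = tab, scopes = "pooled"), class = "ia_fit")
  expect_error(ia_summary(empty), class = "wordia_empty_summary")
})
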