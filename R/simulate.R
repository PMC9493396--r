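# Synthetic free-report generator emulating the blocked study design:
# blocks of images, a fixed cohort of participants per block, a rotating
# SOA schedule giving every (image, SOA) cell exactly n participants, and
# five words (with confidences) per trial.
#
# Reports are drawn from a three-class vocabulary mixture: an image-specific
# lexicon (disjoint between images unless a similar-pair overlap is
# requested), a generic lexicon shared by all images, and a noise lexicon
# (arbitrary entries typed with confidence 1). Specific words become more
# likely, and confidence higher, as SOA grows, which plants the
# specificity and metacognition effects the analyses should recover.

#' Generator configuration
#'
#' Defaults emulate the full study design: 20 blocks x 21 images,
#' 30 participants per block, 7 trials at each of 67/133/267 ms per
#' participant (so each image is seen by exactly 10 participants per SOA),
#' 5 words per trial — 63,000 response rows in total.
#'
#' @param n_blocks Number of image blocks.
#' @param images_per_block Images per block; must be divisible by the
#'   number of SOA levels.
#' @param participants_per_block Participants per block; must be divisible
#'   by the number of SOA levels.
#' @param soa_levels SOA levels in ms.
#' @param words_per_trial Words typed per trial.
#' @param specific_vocab Image-specific lexicon size per image.
#' @param generic_vocab Shared generic lexicon size.
#' @param noise_vocab Noise lexicon size.
#' @param p_specific Probability that a non-noise word is drawn from the
#'   image-specific lexicon, one value per SOA level (ascending).
#' @param noise_rate Probability of a noise word per slot (confidence is
#'   forced to 1 for these).
#' @param conf_probs Confidence distributions (over ratings 1..5) per word
#'   class.
#' @param misspelling_rate Probability that a generic word is emitted as a
#'   planted misspelling from the shipped manual map.
#' @param inflection_rate Probability that a generic word is emitted as an
#'   inflected form from the shipped lemma table.
#' @param n_similar_natural,n_similar_artificial Numbers of registered
#'   similar pairs of each class.
#' @param similar_overlap Fraction of the specific lexicon shared within a
#'   registered similar pair.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_blocks = 20L,
                       images_per_block = 21L,
                       participants_per_block = 30L,
                       soa_levels = c(67L, 133L, 267L),
                       words_per_trial = 5L,
                       specific_vocab = 20L,
                       generic_vocab = 60L,
                       noise_vocab = 30L,
                       p_specific = c(0.45, 0.55, 0.65),
                       noise_rate = 0.05,
                       conf_probs = list(
                         specific = c(0.02, 0.05, 0.13, 0.35, 0.45),
                         generic = c(0.05, 0.15, 0.40, 0.30, 0.10),
                         noise = c(1, 0, 0, 0, 0)),
                       misspelling_rate = 0.02,
                       inflection_rate = 0.05,
                       n_similar_natural = 24L,
                       n_similar_artificial = 4L,
                       similar_overlap = 0.8) {
  n_soa <- length(soa_levels)
  if (images_per_block %% n_soa != 0L) {
    stop("images_per_block must be divisible by the number of SOA levels",
         call. = FALSE)
  }
  if (participants_per_block %% n_soa != 0L) {
    stop("participants_per_block must be divisible by the number of SOA levels",
         call. = FALSE)
  }
  if (length(p_specific) != n_soa) {
    stop("p_specific needs one value per SOA level", call. = FALSE)
  }
  probs <- c(p_specific, noise_rate, similar_overlap,
             unlist(conf_probs, use.names = FALSE),
             misspelling_rate, inflection_rate)
  if (any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (words_per_trial > min(specific_vocab, generic_vocab, noise_vocab)) {
    stop("words_per_trial exceeds the smallest lexicon; infeasible config",
         call. = FALSE)
  }
  if (2L * (n_similar_natural + n_similar_artificial) >
        n_blocks * images_per_block) {
    stop("too many similar pairs for the image set", call. = FALSE)
  }
  structure(list(n_blocks = as.integer(n_blocks),
                 images_per_block = as.integer(images_per_block),
                 participants_per_block = as.integer(participants_per_block),
                 soa_levels = as.integer(soa_levels),
                 words_per_trial = as.integer(words_per_trial),
                 specific_vocab = as.integer(specific_vocab),
                 generic_vocab = as.integer(generic_vocab),
                 noise_vocab = as.integer(noise_vocab),
                 p_specific = p_specific,
                 noise_rate = noise_rate,
                 conf_probs = conf_probs,
                 misspelling_rate = misspelling_rate,
                 inflection_rate = inflection_rate,
                 n_similar_natural = as.integer(n_similar_natural),
                 n_similar_artificial = as.integer(n_similar_artificial),
                 similar_overlap = similar_overlap),
            class = "sim_config")
}

.generic_lexicon <- function(n) {
  base <- readLines(.extdata("generic_words.txt"), encoding = "UTF-8")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("generic-%03d", seq_len(n - length(base))))
}

.noise_lexicon <- function(n) {
  base <- c("na", "none", "arbitrary", "nothing", "blank", "dunno")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("xx-%02d", seq_len(n - length(base))))
}

.similar_registry <- function(cfg, image_of) {
  n_pairs <- cfg$n_similar_natural + cfg$n_similar_artificial
  if (n_pairs == 0L || cfg$n_blocks < 2L) {
    return(data.frame(pair_id = character(0), image_a = character(0),
                      image_b = character(0), class = character(0)))
  }
  m <- seq_len(n_pairs)
  block_a <- ((2L * m - 2L) %% cfg$n_blocks) + 1L
  block_b <- ((2L * m - 1L) %% cfg$n_blocks) + 1L
  slot <- ((m - 1L) %% cfg$images_per_block) + 1L
  data.frame(pair_id = sprintf("pair%02d", m),
             image_a = image_of(block_a, slot),
             image_b = image_of(block_b, slot),
             class = rep(c("natural", "artificial"),
                         c(cfg$n_similar_natural, cfg$n_similar_artificial)),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic free-report dataset
#'
#' Produces a full response table following the blocked design in
#' `config`, together with ground-truth word-class labels
#' (specific / generic / noise) for parameter-recovery tests and a
#' similar-pair registry. The same seed gives byte-identical output.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return An object of class `sim_reports`: `records` (a response
#'   `data.frame` in the canonical dialect, `raw_word` possibly carrying
#'   planted misspellings/inflections), `truth` (`word`, `label`,
#'   `image_id`), `similar_pairs`, `config`.
#' @export
simulate_reports <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (!is.null(seed)) set.seed(seed)
  n_soa <- length(cfg$soa_levels)
  ipb <- cfg$images_per_block
  ppb <- cfg$participants_per_block
  wpt <- cfg$words_per_trial
  n_images <- cfg$n_blocks * ipb
  image_of <- function(block, slot) {
    sprintf("img%03d", (block - 1L) * ipb + slot)
  }
  images <- image_of(rep(seq_len(cfg$n_blocks), each = ipb),
                     rep(seq_len(ipb), cfg$n_blocks))
  generic <- .generic_lexicon(cfg$generic_vocab)
  noise <- .noise_lexicon(cfg$noise_vocab)
  specific <- lapply(stats::setNames(images, images), function(im) {
    sprintf("%s-w%02d", im, seq_len(cfg$specific_vocab))
  })
  pairs <- .similar_registry(cfg, image_of)
  if (nrow(pairs) && cfg$similar_overlap > 0) {
    n_share <- round(cfg$similar_overlap * cfg$specific_vocab)
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$image_a[i]; b <- pairs$image_b[i]
      if (n_share > 0L) {
        specific[[b]][seq_len(n_share)] <- specific[[a]][seq_len(n_share)]
      }
    }
  }
  # planted raw-form variants, recoverable by the shipped cleaning assets
  manual <- ia_manual_map()
  lemma <- ia_lemma_table()
  missp_of <- stats::setNames(names(manual), unname(manual))
  infl_of <- stats::setNames(names(lemma)[!duplicated(unname(lemma))],
                             unname(lemma)[!duplicated(unname(lemma))])

  n_trials <- cfg$n_blocks * ppb * ipb
  n_rows <- n_trials * wpt
  col_participant <- character(n_rows)
  col_block <- integer(n_rows)
  col_image <- character(n_rows)
  col_soa <- integer(n_rows)
  col_trial <- integer(n_rows)
  col_word <- character(n_rows)
  col_conf <- integer(n_rows)
  at <- 0L
  for (b in seq_len(cfg$n_blocks)) {
    block_images <- image_of(b, seq_len(ipb))
    offset <- sample.int(n_soa, 1L) - 1L
    for (p0 in seq_len(ppb) - 1L) {
      pid <- sprintf("p%02d-%02d", b, p0 + 1L)
      trial_order <- sample.int(ipb)
      for (tix in seq_len(ipb)) {
        i0 <- trial_order[tix] - 1L
        im <- block_images[i0 + 1L]
        s <- ((p0 + i0 + offset) %% n_soa) + 1L
        u <- stats::runif(wpt)
        cls <- integer(wpt)
        is_noise <- u < cfg$noise_rate
        cls[is_noise] <- 3L
        u2 <- stats::runif(wpt)
        cls[!is_noise] <- ifelse(u2[!is_noise] < cfg$p_specific[s], 1L, 2L)
        words <- character(wpt)
        n1 <- sum(cls == 1L); n2 <- sum(cls == 2L); n3 <- sum(cls == 3L)
        if (n1) words[cls == 1L] <- sample(specific[[im]], n1)
        if (n2) words[cls == 2L] <- sample(generic, n2)
        if (n3) words[cls == 3L] <- sample(noise, n3)
        conf <- integer(wpt)
        if (n1) conf[cls == 1L] <- sample.int(5L, n1, replace = TRUE,
                                              prob = cfg$conf_probs$specific)
        if (n2) conf[cls == 2L] <- sample.int(5L, n2, replace = TRUE,
                                              prob = cfg$conf_probs$generic)
        if (n3) conf[cls == 3L] <- 1L
        raw <- words
        if (n2 && (cfg$misspelling_rate > 0 || cfg$inflection_rate > 0)) {
          gi <- which(cls == 2L)
          um <- stats::runif(length(gi))
          for (j in seq_along(gi)) {
            w <- words[gi[j]]
            if (um[j] < cfg$misspelling_rate && !is.na(missp_of[w])) {
              raw[gi[j]] <- missp_of[[w]]
            } else if (um[j] < cfg$misspelling_rate + cfg$inflection_rate &&
                         !is.na(infl_of[w])) {
              raw[gi[j]] <- infl_of[[w]]
            }
          }
        }
        idx <- at + seq_len(wpt)
        col_participant[idx] <- pid
        col_block[idx] <- b
        col_image[idx] <- im
        col_soa[idx] <- cfg$soa_levels[s]
        col_trial[idx] <- tix
        col_word[idx] <- raw
        col_conf[idx] <- conf
        at <- at + wpt
      }
    }
  }
  records <- data.frame(participant_id = col_participant,
                        block_id = col_block,
                        image_id = col_image,
                        soa_ms = col_soa,
                        trial_index = col_trial,
                        word_slot = rep(seq_len(wpt), n_trials),
                        raw_word = col_word,
                        confidence = col_conf,
                        stringsAsFactors = FALSE)
  truth <- rbind(
    data.frame(word = unlist(specific, use.names = FALSE),
               label = "specific",
               image_id = rep(images, each = cfg$specific_vocab),
               stringsAsFactors = FALSE),
    data.frame(word = generic, label = "generic", image_id = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(word = noise, label = "noise", image_id = NA_character_,
               stringsAsFactors = FALSE))
  truth <- truth[!duplicated(truth$word), ]
  structure(list(records = records, truth = truth, similar_pairs = pairs,
                 config = cfg),
            class = "sim_reports")
}

#' @export
print.sim_reports <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic free-report dataset:", nrow(x$records), "rows;",
      cfg$n_blocks, "blocks x", cfg$images_per_block, "images x",
      cfg$participants_per_block, "participants\n")
  cat("  vocabulary:", sum(x$truth$label == "specific"), "specific,",
      sum(x$truth$label == "generic"), "generic,",
      sum(x$truth$label == "noise"), "noise words;",
      nrow(x$similar_pairs), "similar pairs\n")
  invisible(x)
}

# deterministic design skeleton shared by the canned fixtures
.fixture_skeleton <- function(n_images = 6L, n_participants = 30L,
                              soa_levels = c(67L, 133L, 267L)) {
  n_soa <- length(soa_levels)
  rows <- vector("list", n_participants * n_images)
  at <- 0L
  for (p0 in seq_len(n_participants) - 1L) {
    for (i0 in seq_len(n_images) - 1L) {
      at <- at + 1L
      rows[[at]] <- data.frame(
        participant_id = sprintf("p%02d", p0 + 1L),
        block_id = 1L,
        image_id = sprintf("img%03d", i0 + 1L),
        soa_ms = soa_levels[((p0 + i0) %% n_soa) + 1L],
        trial_index = i0 + 1L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.fixture_fill <- function(skel, words_per_trial = 5L) {
  n <- nrow(skel)
  out <- skel[rep(seq_len(n), each = words_per_trial), , drop = FALSE]
  out$word_slot <- rep(seq_len(words_per_trial), n)
  out$raw_word <- sprintf("f-%s-%s-%d", out$participant_id, out$image_id,
                          out$word_slot)
  out$confidence <- 1L
  row.names(out) <- NULL
  out
}

#' Canned hand-checkable fixtures
#'
#' Tiny deterministic datasets whose IA values are forced by construction:
#'
#' * `"eiffel"`: one landmark word reported by 6 of the 10 participants in
#'   a single (image, SOA = 67 ms) cohort and by nobody anywhere else, so
#'   the within-image curve steps at 5/9 (56%), the baseline curve steps
#'   only at 0, and every reporter AUC — hence the Word IA — is 1. All
#'   other words are singletons.
#' * `"uniform"`: one word reported by the participants at cohort order
#'   1..5 of every (image, SOA) cell, so its baseline fractions all equal
#'   its within fraction and its Word IA is exactly 0.5 in every scope.
#' * `"sperling"`: a letter-array world: each image's reports are five
#'   letter tokens unique to it, reported by all 30 participants, so every
#'   Word IA is 1 and every Image IA is 1 with no rarely reported words.
#'
#' @param name Fixture name.
#' @return A list with `records` (cleaned, `word` column present) and
#'   `target` (the word of interest, where applicable).
#' @export
make_fixture <- function(name) {
  fixtures <- c("eiffel", "uniform", "sperling")
  if (!is.character(name) || length(name) != 1L || !name %in% fixtures) {
    stop("unknown fixture; registered fixtures: ",
         paste(fixtures, collapse = ", "), call. = FALSE)
  }
  skel <- .fixture_skeleton()
  if (name == "sperling") {
    letters30 <- c(letters, "aa", "bb", "cc", "dd")
    n <- nrow(skel)
    out <- skel[rep(seq_len(n), each = 5L), , drop = FALSE]
    out$word_slot <- rep(1:5, n)
    i0 <- as.integer(sub("img", "", out$image_id)) - 1L
    out$raw_word <- letters30[i0 * 5L + out$word_slot]
    out$confidence <- 5L
    row.names(out) <- NULL
    out$word <- out$raw_word
    return(list(records = out, target = NULL))
  }
  out <- .fixture_fill(skel)
  if (name == "eiffel") {
    # cell (img001, 67 ms) holds participants with p0 %% 3 == 0; plant the
    # word for the first six of them (cohort orders 1..6)
    reporters <- sprintf("p%02d", c(0L, 3L, 6L, 9L, 12L, 15L) + 1L)
    hit <- out$image_id == "img001" & out$participant_id %in% reporters &
      out$word_slot == 1L
    stopifnot(sum(hit) == 6L, all(out$soa_ms[hit] == 67L))
    out$raw_word[hit] <- "eiffel-tower"
    out$confidence[hit] <- 5L
    target <- "eiffel-tower"
  } else {
    # first five participants of every (image, SOA) cell report it
    p0 <- as.integer(sub("p", "", out$participant_id)) - 1L
    cell_rank <- p0 %/% 3L  # rank within the cell's appearance order
    hit <- cell_rank < 5L & out$word_slot == 1L
    out$raw_word[hit] <- "thing"
    out$confidence[hit] <- 3L
    target <- "thing"
  }
  out$word <- out$raw_word
  list(records = out, target = target)
}
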