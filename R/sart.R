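#' Generate a SART event sequence
#'
#' Simulates the trial stream of a Sustained Attention to Response Task:
#' frequent Go words (8/9 of trials) and rare No-go words (1/9), organised
#' in blocks, with thought probes inserted at random after trials. Each trial
#' is a fixation cross (duration sampled from 1480/1640/1800/1960/2020 ms),
#' a 320 ms word, an 880 ms mask and a 3020 ms inter-stimulus interval;
#' `onset_s` marks word (stimulus) onset. The five trials preceding each
#' thought probe are tagged with that probe's stickiness rating (1-9);
#' ratings 1-4 map to "less_sticky", 6-9 to "more_sticky", 5 is excluded
#' from the sticky/non-sticky contrast.
#'
#' @param n_blocks number of blocks (default 8).
#' @param trials_per_block trials per block (default 90).
#' @param probe_rate probability that a thought probe follows a given trial.
#' @param seed integer seed; the sequence is deterministic per seed.
#' @param p_nogo probability of a No-go trial (default 1/9).
#' @return A data.frame with one row per trial: `onset_s`, `trial_type`
#'   ("go"/"nogo"), `block`, `cross_duration_ms`, `stickiness_rating`
#'   (integer or NA) and `stickiness_class` ("less_sticky", "more_sticky",
#'   "excluded", "unlabeled").
#' @examples
#' ev <- generate_sart_events(8, 90, probe_rate = 1/18, seed = 1)
#' nrow(ev)  # 720
#' @export
generate_sart_events <- function(n_blocks = 8L, trials_per_block = 90L,
                                 probe_rate = 1 / 18, seed = 1L,
                                 p_nogo = 1 / 9) {
  assert_scalar_num(n_blocks, "n_blocks", 1)
  assert_scalar_num(trials_per_block, "trials_per_block", 1)
  assert_scalar_num(probe_rate, "probe_rate", 0, 1)
  assert_scalar_num(p_nogo, "p_nogo", 0, 1)
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  n <- n_blocks * trials_per_block

  cross_choices <- c(1480, 1640, 1800, 1960, 2020)
  word_ms <- 320; mask_ms <- 880; isi_ms <- 3020

  with_seed(seed, {
    cross <- sample(cross_choices, n, replace = TRUE)
    trial_type <- ifelse(stats::runif(n) < p_nogo, "nogo", "go")
    probed <- stats::runif(n) < probe_rate
    rating <- ifelse(probed, sample.int(9L, n, replace = TRUE), NA_integer_)

    trial_total <- cross + word_ms + mask_ms + isi_ms
    trial_start <- c(0, cumsum(trial_total[-n]))
    onset_s <- (trial_start + cross) / 1000

    stick_rating <- rep(NA_integer_, n)
    for (i in which(probed)) {
      lo <- max(1L, i - 4L)
      stick_rating[lo:i] <- rating[i]
    }
    stick_class <- rep("unlabeled", n)
    stick_class[!is.na(stick_rating) & stick_rating <= 4] <- "less_sticky"
    stick_class[!is.na(stick_rating) & stick_rating >= 6] <- "more_sticky"
    stick_class[!is.na(stick_rating) & stick_rating == 5] <- "excluded"

    data.frame(
      onset_s = onset_s,
      trial_type = trial_type,
      block = rep(seq_len(n_blocks), each = trials_per_block),
      cross_duration_ms = cross,
      stickiness_rating = stick_rating,
      stickiness_class = stick_class,
      stringsAsFactors = FALSE
    )
  })
}

#' Total duration implied by an event table
#'
#' Last trial offset (stimulus onset + word + mask + ISI) plus a safety
#' margin; used to size task recordings.
#' @param events event table from [generate_sart_events()].
#' @param margin_s trailing margin in seconds.
#' @return Duration in seconds.
#' @export
sart_duration_s <- function(events, margin_s = 2) {
  if (nrow(events) == 0) return(margin_s)
  max(events$onset_s) + (320 + 880 + 3020) / 1000 + margin_s
}
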