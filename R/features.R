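# Feature table assembly: one row per subject (or subject x epoch), one
# column per (measure, band, channel-or-pair) descriptor.

upper_pairs <- function(channels) {
  nc <- length(channels)
  i <- rep(seq_len(nc - 1), times = (nc - 1):1)
  j <- unlist(lapply(2:nc, function(k) k:nc))
  data.frame(a = channels[i], b = channels[j], stringsAsFactors = FALSE)
}

connectivity_to_row <- function(cm) {
  pr <- upper_pairs(cm$channels)
  vals <- cm$values[cbind(match(pr$a, cm$channels), match(pr$b, cm$channels))]
  names(vals) <- sprintf("%s|%s|%s-%s", cm$measure, cm$band, pr$a, pr$b)
  vals
}

feature_measures <- function() {
  c("band_power", "relative_power", "alpha_asymmetry", "correlation",
    "coherence_mag", "coherence_imag", "plv", "pli", "hfd", "dfa")
}

# All requested features of one epoch set (one subject, or one epoch).
features_of_epochs <- function(ep, measures, bands, hfd_kmax = 8L) {
  scalp <- which(ep$channel_roles == "scalp")
  ch <- ep$channel_names[scalp]
  row <- numeric(0)
  for (ms in measures) {
    if (ms == "alpha_asymmetry") {
      v <- alpha_asymmetry(ep)
      names(v) <- "alpha_asymmetry|alpha|F4-F3"
      row <- c(row, v)
      next
    }
    for (bd in bands) {
      if (ms %in% c("plv", "pli") && bd == "raw") next
      if (ms == "band_power") {
        v <- band_power(ep, bd)[scalp]
        names(v) <- sprintf("band_power|%s|%s", bd, ch)
      } else if (ms == "relative_power") {
        v <- relative_band_power(ep, bd)[scalp]
        names(v) <- sprintf("relative_power|%s|%s", bd, ch)
      } else if (ms == "correlation") {
        v <- connectivity_to_row(connectivity_correlation(ep, bd))
      } else if (ms %in% c("coherence_mag", "coherence_imag")) {
        co <- connectivity_coherence(ep, bd)
        v <- connectivity_to_row(co[[ms]])
      } else if (ms %in% c("plv", "pli")) {
        phs <- connectivity_phase(ep, bd)
        v <- connectivity_to_row(phs[[ms]])
      } else if (ms %in% c("hfd", "dfa")) {
        epb <- band_filter(ep, bd)
        fn <- if (ms == "hfd") {
          function(x) higuchi_fd(x, hfd_kmax)
        } else dfa_exponent
        d <- dim(epb$data)
        v <- vapply(scalp, function(ci) {
          mean(vapply(seq_len(d[1]),
                      function(tr) fn(epb$data[tr, ci, ]), 0))
        }, 0)
        names(v) <- sprintf("%s|%s|%s", ms, bd, ch)
      } else {
        stop_invalid("unknown measure '%s'", ms)
      }
      row <- c(row, v)
    }
  }
  row
}

#' Extract a biomarker feature table from a cohort of epoch sets
#'
#' Computes the requested measures per band and channel (or channel pair)
#' for every subject. At "subject" granularity measures are pooled over
#' each subject's epochs into one row; at "subject_epoch" each epoch gets
#' its own row (connectivity then comes from single epochs).
#'
#' @param epochs_list list of `eeg_epochs`, one per subject.
#' @param measures subset of `feature_measures()`.
#' @param bands band names (see [band_names()]); "raw" is skipped for
#'   phase measures.
#' @param granularity "subject" or "subject_epoch".
#' @return A `feature_table`: data.frame with `subject_id`, `group`, then
#'   one numeric column per descriptor `measure|band|channel[-channel]`;
#'   descriptor metadata in `attr(, "descriptors")`.
#' @export
extract_feature_table <- function(epochs_list, measures = c("band_power"),
                                  bands = "delta",
                                  granularity = c("subject",
                                                  "subject_epoch")) {
  granularity <- match.arg(granularity)
  bad <- setdiff(measures, feature_measures())
  if (length(bad)) stop_invalid("unknown measure(s): %s",
                                paste(bad, collapse = ", "))
  rows <- list(); ids <- character(0); grp <- character(0)
  for (ep in epochs_list) {
    if (granularity == "subject") {
      rows[[length(rows) + 1]] <- features_of_epochs(ep, measures, bands)
      ids <- c(ids, ep$subject_id); grp <- c(grp, ep$group)
    } else {
      for (tr in seq_len(dim(ep$data)[1])) {
        one <- ep
        one$data <- ep$data[tr, , , drop = FALSE]
        one$events <- ep$events[tr, , drop = FALSE]
        rows[[length(rows) + 1]] <- features_of_epochs(one, measures, bands)
        ids <- c(ids, ep$subject_id); grp <- c(grp, ep$group)
      }
    }
  }
  mat <- do.call(rbind, rows)
  ft <- data.frame(subject_id = ids, group = grp, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ft <- cbind(ft, as.data.frame(mat, check.names = FALSE))
  attr(ft, "descriptors") <- parse_descriptors(colnames(mat))
  class(ft) <- c("feature_table", "data.frame")
  ft
}

parse_descriptors <- function(nm) {
  parts <- strsplit(nm, "|", fixed = TRUE)
  data.frame(
    name = nm,
    measure = vapply(parts, `[`, "", 1),
    band = vapply(parts, `[`, "", 2),
    location = vapply(parts, `[`, "", 3),
    stringsAsFactors = FALSE
  )
}

feature_columns <- function(ft) {
  setdiff(colnames(ft), c("subject_id", "group"))
}

#' Write / read a feature table
#'
#' Tab-separated values with the descriptor header preserved verbatim, so a
#' round trip reproduces the table and its descriptor metadata.
#'
#' @param ft a `feature_table`.
#' @param path file path.
#' @return `read_feature_table` returns the `feature_table`.
#' @export
write_feature_table <- function(ft, path) {
  utils::write.table(ft, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  ft <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  attr(ft, "descriptors") <- parse_descriptors(feature_columns(ft))
  class(ft) <- c("feature_table", "data.frame")
  ft
}
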