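# Plain-text containers: a recording is a directory holding one structured
# metadata file (YAML) and one channels x samples matrix file, either
# tab-delimited text or raw little-endian doubles. Event and questionnaire
# tables are tab-delimited text; empty cells mean missing.

#' Write / read a recording container
#'
#' @param rec an `eeg_recording`.
#' @param dir container directory (created if needed).
#' @param format "tsv" (delimited text) or "bin" (raw doubles,
#'   column-major samples-within-channel).
#' @return `read_recording` returns the `eeg_recording`.
#' @export
write_recording <- function(rec, dir, format = c("tsv", "bin")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(subject_id = rec$subject_id, group = rec$group, fs = rec$fs,
               n_channels = nrow(rec$data), n_samples = ncol(rec$data),
               channel_names = as.list(rec$channel_names),
               channel_roles = as.list(rec$channel_roles),
               format = format)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  if (format == "tsv") {
    utils::write.table(rec$data, file.path(dir, "data.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(file.path(dir, "data.bin"), "wb")
    writeBin(as.vector(t(rec$data)), con, size = 8, endian = "little")
    close(con)
  }
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  nc <- meta$n_channels; ns <- meta$n_samples
  if (identical(meta$format, "bin")) {
    con <- file(file.path(dir, "data.bin"), "rb")
    v <- readBin(con, "double", n = nc * ns, size = 8, endian = "little")
    close(con)
    data <- matrix(v, nrow = nc, byrow = TRUE)
  } else {
    data <- as.matrix(utils::read.table(file.path(dir, "data.tsv"),
                                        sep = "\t", header = FALSE))
    dimnames(data) <- NULL
  }
  new_recording(data, meta$fs, unlist(meta$channel_names),
                unlist(meta$channel_roles), meta$subject_id, meta$group)
}

#' Write / read an event table
#' @param events event data.frame ([generate_sart_events()]).
#' @param path file path (tab-separated).
#' @return `read_events` returns the data.frame.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "")
  ev$stickiness_rating <- as.integer(ev$stickiness_rating)
  ev
}

#' Write / read a questionnaire table
#' @param q questionnaire data.frame; empty cells encode missing values.
#' @param path file path (tab-separated).
#' @return `read_questionnaires` returns the data.frame.
#' @export
write_questionnaires <- function(q, path) {
  utils::write.table(q, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_questionnaires
#' @export
read_questionnaires <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, na.strings = "")
}
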