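#' Read and write the plain-text interchange formats
#'
#' Hypnograms (`epoch_index`, `stage`), event annotations (`start_s`,
#' `duration_s`, `type`), and subject tables are exchanged as plain CSV.
#'
#' @param x Object to write.
#' @param path File path.
#' @name psg_io
NULL

#' @rdname psg_io
#' @export
write_hypnogram_csv <- function(x, path) {
  utils::write.csv(data.frame(epoch_index = x$epoch, stage = x$stage),
                   path, row.names = FALSE)
}

#' @rdname psg_io
#' @export
read_hypnogram_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble(epoch = d$epoch_index,
         stage = factor(d$stage, levels = stage_levels()))
}

#' @rdname psg_io
#' @export
write_events_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x[, c("start_s", "duration_s", "type")]),
                   path, row.names = FALSE)
}

#' @rdname psg_io
#' @export
read_events_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname psg_io
#' @export
write_subjects_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
}

#' @rdname psg_io
#' @export
read_subjects_csv <- function(path) {
  d <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if ("group" %in% names(d)) d$group <- factor(d$group)
  if ("risk_group" %in% names(d)) d$risk_group <- factor(d$risk_group)
  d
}
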