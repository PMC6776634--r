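#' Read and write the package's CSV interchange formats
#'
#' Spike sets travel as two RFC-4180 CSVs: a spike table (`unit_id`,
#' `electrode_row`, `electrode_col`, `spike_time_s`) and an event table
#' (`kind`, `time_s`, `depth_um`, `amplitude_um`, `frequency_hz`).
#' Indentation traces are a CSV (`time_s`, `piezo_um`, `deflection_um`,
#' `load_un`, `segment`) preceded by `#`-prefixed header lines carrying
#' `probe_radius_um`, `spring_constant_n_per_m`, `fs_hz`, `x_um`, `y_um`.
#' Saturation frames are a headerless 0/1 grid, one row per electrode row.
#'
#' @param spikes A `spike_train_set`.
#' @param path,spike_path,event_path File paths.
#' @return Readers return the parsed object; writers return the path,
#'   invisibly.
#' @name retinamech-io
NULL

#' @rdname retinamech-io
#' @export
write_spike_csv <- function(spikes, spike_path, event_path = NULL) {
  stopifnot(inherits(spikes, "spike_train_set"))
  tab <- data.frame(
    unit_id = rep(spikes$units$unit_id, lengths(spikes$spikes)),
    electrode_row = rep(spikes$units$electrode_row, lengths(spikes$spikes)),
    electrode_col = rep(spikes$units$electrode_col, lengths(spikes$spikes)),
    spike_time_s = unlist(spikes$spikes, use.names = FALSE)
  )
  write.csv(tab, spike_path, row.names = FALSE, quote = FALSE)
  if (!is.null(event_path) && !is.null(spikes$events)) {
    write.csv(spikes$events, event_path, row.names = FALSE, quote = FALSE)
  }
  invisible(spike_path)
}

#' @rdname retinamech-io
#' @param duration_s Recording duration; inferred (ceiling of the last
#'   spike) when `NULL`.
#' @export
read_spike_csv <- function(spike_path, event_path = NULL, duration_s = NULL) {
  tab <- read.csv(spike_path)
  req <- c("unit_id", "electrode_row", "electrode_col", "spike_time_s")
  if (!all(req %in% names(tab))) {
    stop_invalid("spike CSV must have columns: ", paste(req, collapse = ", "))
  }
  ids <- unique(tab$unit_id)
  spikes <- vector("list", length(ids))
  units <- data.frame(unit_id = ids, electrode_row = NA_integer_,
                      electrode_col = NA_integer_)
  for (i in seq_along(ids)) {
    rows <- tab[tab$unit_id == ids[i], ]
    st <- rows$spike_time_s
    if (is.unsorted(st, strictly = TRUE)) {
      stop_invalid("non-monotone spike times for unit ", ids[i])
    }
    if (any(st < 0)) stop_invalid("negative spike time for unit ", ids[i])
    spikes[[i]] <- st
    units$electrode_row[i] <- rows$electrode_row[1]
    units$electrode_col[i] <- rows$electrode_col[1]
  }
  if (is.null(duration_s)) duration_s <- ceiling(max(tab$spike_time_s))
  events <- if (!is.null(event_path)) read.csv(event_path) else NULL
  structure(list(units = units, spikes = spikes,
                 duration_s = duration_s, events = events),
            class = "spike_train_set")
}

#' @rdname retinamech-io
#' @param trace An `indentation_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "indentation_trace"))
  hdr <- sprintf("# %s=%.10g",
                 c("probe_radius_um", "spring_constant_n_per_m", "fs_hz",
                   "x_um", "y_um"),
                 c(attr(trace, "probe_radius_um"),
                   attr(trace, "spring_constant_n_m"), attr(trace, "fs_hz"),
                   attr(trace, "x_um"), attr(trace, "y_um")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(trace), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname retinamech-io
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines)
  meta <- list()
  for (l in lines[hdr_lines]) {
    kv <- strsplit(sub("^#\\s*", "", l), "=")[[1]]
    meta[[trimws(kv[1])]] <- as.numeric(kv[2])
  }
  req <- c("probe_radius_um", "spring_constant_n_per_m", "fs_hz")
  if (!all(req %in% names(meta))) {
    stop_invalid("trace CSV header must carry ", paste(req, collapse = ", "))
  }
  body <- read.csv(text = paste(lines[-hdr_lines], collapse = "\n"),
                   stringsAsFactors = FALSE)
  structure(body,
            probe_radius_um = meta$probe_radius_um,
            spring_constant_n_m = meta$spring_constant_n_per_m,
            fs_hz = meta$fs_hz,
            x_um = if (!is.null(meta$x_um)) meta$x_um else 0,
            y_um = if (!is.null(meta$y_um)) meta$y_um else 0,
            class = c("indentation_trace", "data.frame"))
}

#' @rdname retinamech-io
#' @param frame A `saturation_frame`.
#' @export
write_saturation_csv <- function(frame, path) {
  utils::write.table(matrix(as.integer(frame), nrow(frame)), path,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname retinamech-io
#' @export
read_saturation_csv <- function(path) {
  m <- as.matrix(read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  structure(m == 1, class = c("saturation_frame", "matrix", "array"))
}
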