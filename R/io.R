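#' Read and write behavioral traces
#'
#' Traces travel as two TSV files: the baseline table
#' (`larva_id, t_s, dpix, x, y`, one row per second) and the burst
#' table (`larva_id, event_id, frame, dpix`, one row per high-speed
#' frame).
#'
#' @param cohort A `"behavior_cohort"` (write) .
#' @param trace_path,burst_path TSV paths.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_traces <- function(cohort, trace_path, burst_path) {
  base <- do.call(rbind, lapply(cohort$traces, function(tr)
    data.frame(larva_id = tr$larva_id, t_s = tr$t, dpix = tr$dpix,
               x = tr$x, y = tr$y)))
  utils::write.table(base, trace_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bursts <- do.call(rbind, lapply(cohort$traces, function(tr) {
    if (!length(tr$bursts)) return(NULL)
    do.call(rbind, lapply(names(tr$bursts), function(ev)
      data.frame(larva_id = tr$larva_id, event_id = ev,
                 frame = seq_along(tr$bursts[[ev]]),
                 dpix = tr$bursts[[ev]])))
  }))
  if (is.null(bursts))
    bursts <- data.frame(larva_id = character(0), event_id = character(0),
                         frame = integer(0), dpix = numeric(0))
  utils::write.table(bursts, burst_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(trace_path, burst_path))
}

#' @rdname trace_io
#' @param burst_rate_hz,burst_window_s Burst geometry to attach to the
#'   read traces.
#' @return `read_traces()` returns a named list of `"dpix_trace"`
#'   objects.
#' @export
read_traces <- function(trace_path, burst_path = NULL,
                        burst_rate_hz = 285, burst_window_s = 1) {
  base <- utils::read.table(trace_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  bursts <- if (!is.null(burst_path) && file.exists(burst_path))
    utils::read.table(burst_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else NULL
  out <- list()
  for (id in unique(base$larva_id)) {
    b <- base[base$larva_id == id, ]
    bl <- list()
    if (!is.null(bursts) && nrow(bursts)) {
      bb <- bursts[bursts$larva_id == id, ]
      for (ev in unique(bb$event_id))
        bl[[ev]] <- bb$dpix[bb$event_id == ev][order(bb$frame[bb$event_id == ev])]
    }
    out[[id]] <- structure(list(larva_id = id, t = b$t_s, dpix = b$dpix,
                                x = b$x, y = b$y, bursts = bl,
                                burst_rate_hz = burst_rate_hz,
                                burst_window_s = burst_window_s),
                           class = "dpix_trace")
  }
  out
}

#' Genotype map IO
#'
#' TSV with columns `larva_id`, `genotype`, `replicate`.
#'
#' @param genotypes Genotype data.frame.
#' @param path TSV path.
#' @export
write_genotypes <- function(genotypes, path) {
  utils::write.table(genotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  if (anyDuplicated(g$larva_id))
    stop("duplicate larva_id in genotype map", call. = FALSE)
  g
}

#' Stimulus schedule IO (YAML)
#'
#' @param schedule A [stimulus_schedule()].
#' @param path YAML path.
#' @export
write_schedule <- function(schedule, path) {
  yaml::write_yaml(list(burst_window_s = schedule$burst_window_s,
                        burst_rate_hz = schedule$burst_rate_hz,
                        events = lapply(seq_len(nrow(schedule$events)),
                                        function(i)
                                          as.list(schedule$events[i, ]))),
                   path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  ev <- do.call(rbind, lapply(y$events, function(e)
    data.frame(time_s = e$time_s, kind = e$kind, block_id = e$block_id,
               freq_hz = if (is.null(e$freq_hz) || is.na(e$freq_hz))
                 NA_real_ else e$freq_hz,
               stringsAsFactors = FALSE)))
  stimulus_schedule(ev, burst_window_s = y$burst_window_s,
                    burst_rate_hz = y$burst_rate_hz)
}

#' Measure matrix IO
#'
#' The matrix travels as a TSV (first column `larva_id`) plus a
#' sidecar JSON of per-column metadata.
#'
#' @param mm A [build_measure_matrix()] matrix.
#' @param path TSV path; the metadata sidecar is `<path>.meta.json`
#'   unless given.
#' @param meta_path Optional explicit sidecar path.
#' @export
write_measure_matrix <- function(mm, path, meta_path = paste0(path, ".meta.json")) {
  df <- data.frame(larva_id = rownames(mm), as.data.frame(unclass(mm)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(attr(mm, "measure_meta"), meta_path,
                       dataframe = "rows", na = "null", auto_unbox = TRUE)
  invisible(c(path, meta_path))
}

#' @rdname write_measure_matrix
#' @export
read_measure_matrix <- function(path, meta_path = paste0(path, ".meta.json")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$larva_id
  meta <- as.data.frame(jsonlite::read_json(meta_path, simplifyVector = TRUE))
  structure(mat, measure_meta = meta,
            class = c("measure_matrix", class(mat)))
}

#' Read and write 3D stacks as NRRD
#'
#' Minimal NRRD support for registered stacks and atlas masks: an
#' attached-header NRRD with raw little-endian encoding, `double` for
#' scalar stacks and `int32` for label volumes.  Axis order `(z, y, x)`
#' is preserved via the sizes field (fastest axis first on disk = R's
#' column-major first dimension).
#'
#' @param x 3D numeric or integer array (a stack, atlas, or
#'   significance map).
#' @param path File path (`.nrrd`).
#' @export
write_nrrd <- function(x, path) {
  is_int <- is.integer(x) || inherits(x, "region_atlas")
  type <- if (is_int) "int32" else "double"
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           paste0("type: ", type),
           "dimension: 3",
           paste0("sizes: ", paste(dim(x), collapse = " ")),
           "encoding: raw",
           "endian: little",
           "")
  writeLines(hdr, con, sep = "\n")
  if (is_int)
    writeBin(as.integer(x), con, size = 4, endian = "little")
  else
    writeBin(as.double(x), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_nrrd
#' @return `read_nrrd()` returns the 3D array (integer for `int32`
#'   files).
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !nzchar(line)) break
    hdr <- c(hdr, line)
  }
  get_field <- function(key) {
    hit <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (!length(hit)) stop("NRRD header missing field: ", key, call. = FALSE)
    sub(paste0("^", key, ": "), "", hit[1])
  }
  if (!grepl("^NRRD", hdr[1])) stop("not an NRRD file", call. = FALSE)
  type <- get_field("type")
  sizes <- as.integer(strsplit(get_field("sizes"), " ")[[1]])
  if (get_field("encoding") != "raw")
    stop("only raw encoding supported", call. = FALSE)
  n <- prod(sizes)
  data <- if (type %in% c("int32", "int", "signed int"))
    readBin(con, "integer", n = n, size = 4, endian = "little")
  else if (type == "double")
    readBin(con, "double", n = n, size = 8, endian = "little")
  else stop("unsupported NRRD type: ", type, call. = FALSE)
  array(data, sizes)
}

#' @rdname write_nrrd
#' @param atlas_path Path of a label-volume NRRD.
#' @param region_names Optional names for labels `1..max`; defaults to
#'   `region<label>`.
#' @return `read_atlas()` returns a `"region_atlas"`; every named
#'   region must be nonempty.
#' @export
read_atlas <- function(atlas_path, region_names = NULL) {
  lab <- read_nrrd(atlas_path)
  if (any(lab < 0)) stop("atlas labels must be nonnegative", call. = FALSE)
  n <- max(lab)
  if (is.null(region_names)) region_names <- paste0("region", seq_len(n))
  if (length(region_names) != n)
    stop("region_names length must equal the label count", call. = FALSE)
  sizes <- tabulate(as.integer(lab), nbins = n)
  if (any(sizes == 0))
    stop("empty region(s): ", paste(region_names[sizes == 0],
                                    collapse = ", "), call. = FALSE)
  structure(array(as.integer(lab), dim(lab)), class = "region_atlas",
            region_names = region_names)
}

#' Calibration result IO (JSON)
#'
#' @param calibration A [calibrate_threshold()] result.
#' @param path JSON path.
#' @export
write_calibration <- function(calibration, path) {
  jsonlite::write_json(unclass(calibration), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "brain_calibration")
}
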