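#' Read and write waveform CSV files
#'
#' The waveform dialect has columns `time_s`, `p_vent_mmHg`, `p_ao_mmHg`,
#' `q_mls`; the cycle period travels in a `# cycle_period: <s>` comment
#' header line (and may instead be supplied to the reader).
#'
#' @param path File path.
#' @param w A `pf_waveform`.
#' @param cycle_period Cycle period, s; overrides the header when given.
#' @return `read_waveform_csv()` returns a `pf_waveform`;
#'   `write_waveform_csv()` returns `path` invisibly.
#' @export
read_waveform_csv <- function(path, cycle_period = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(cycle_period) && grepl("^#\\s*cycle_period:", first)) {
    cycle_period <- as.numeric(sub("^#\\s*cycle_period:\\s*", "", first))
  }
  if (is.null(cycle_period)) {
    stop_data("no cycle_period header found; pass `cycle_period`")
  }
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  as_pf_waveform(d, cycle_period = cycle_period)
}

#' @rdname read_waveform_csv
#' @export
write_waveform_csv <- function(w, path) {
  writeLines(sprintf("# cycle_period: %.12g", attr(w, "cycle_period")), path)
  readr::write_csv(tibble::as_tibble(w), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Read and write indentation CSV files
#'
#' Columns `time_s`, `displacement_um`, `load_uN`, `segment` (one of
#' `loading`, `unloading`, `retraction`).
#'
#' @param path File path.
#' @param record An `indentation_record` tibble.
#' @return The record (reader) or `path` invisibly (writer).
#' @export
read_indentation_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "displacement_um", "load_uN")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop_data(paste0("indentation CSV is missing: ",
                     paste(missing, collapse = ", ")))
  }
  structure(d, class = c("indentation_record", class(d)))
}

#' @rdname read_indentation_csv
#' @export
write_indentation_csv <- function(record, path) {
  readr::write_csv(tibble::as_tibble(record), path)
  invisible(path)
}

#' Write and read a wall-shear surface field as a CSV bundle
#'
#' The on-disk layout is a directory holding `nodes.csv` (`node, x, y, z`),
#' `faces.csv` (`n1, n2, n3`), `times.csv` (`step, time_s`) and one
#' `wss_<k>.csv` per time step (`node, tx, ty, tz` in dynes/cm^2).
#'
#' @param field A [wss_field()].
#' @param dir Directory path (created if absent).
#' @return The field (reader) or `dir` invisibly (writer).
#' @export
write_wss_field_csv <- function(field, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(field$nodes[, c("node", "x", "y", "z")],
                   file.path(dir, "nodes.csv"))
  if (!is.null(field$triangles)) {
    readr::write_csv(field$triangles, file.path(dir, "faces.csv"))
  }
  readr::write_csv(tibble::tibble(step = seq_along(field$times),
                                  time_s = field$times),
                   file.path(dir, "times.csv"))
  for (k in seq_along(field$times)) {
    readr::write_csv(tibble::tibble(node = field$nodes$node,
                                    tx = field$tau[, k, 1],
                                    ty = field$tau[, k, 2],
                                    tz = field$tau[, k, 3]),
                     file.path(dir, sprintf("wss_%03d.csv", k)))
  }
  invisible(dir)
}

#' @rdname write_wss_field_csv
#' @export
read_wss_field_csv <- function(dir) {
  nodes <- readr::read_csv(file.path(dir, "nodes.csv"),
                           show_col_types = FALSE)
  faces_path <- file.path(dir, "faces.csv")
  triangles <- if (file.exists(faces_path)) {
    readr::read_csv(faces_path, show_col_types = FALSE)
  } else NULL
  times <- readr::read_csv(file.path(dir, "times.csv"),
                           show_col_types = FALSE)$time_s
  tau <- array(0, dim = c(nrow(nodes), length(times), 3L))
  for (k in seq_along(times)) {
    d <- readr::read_csv(file.path(dir, sprintf("wss_%03d.csv", k)),
                         show_col_types = FALSE)
    tau[, k, ] <- as.matrix(d[order(d$node), c("tx", "ty", "tz")])
  }
  wss_field(nodes, triangles, times, tau)
}

#' Write a surface field or scalar result as legacy ASCII VTK polydata
#'
#' Minimal legacy-format VTK writer for viewing surfaces and per-node
#' scalars (e.g. TAWSS, OSI) in ParaView-style tools. Writing only; the
#' CSV bundle of [write_wss_field_csv()] is the canonical exchange format.
#'
#' @param field A [wss_field()] with a triangulation.
#' @param path Output `.vtk` path.
#' @param scalars Named list of per-node numeric vectors to attach.
#' @return `path`, invisibly.
#' @export
write_wss_vtk <- function(field, path, scalars = list()) {
  if (is.null(field$triangles)) stop_data("field has no triangulation")
  con <- file(path, "w")
  on.exit(close(con))
  nn <- nrow(field$nodes)
  nt <- nrow(field$triangles)
  writeLines(c("# vtk DataFile Version 3.0", "valvebench surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nn)), con)
  writeLines(apply(field$nodes[, c("x", "y", "z")], 1, paste,
                   collapse = " "), con)
  writeLines(sprintf("POLYGONS %d %d", nt, 4L * nt), con)
  writeLines(paste(3L, field$triangles$n1 - 1L, field$triangles$n2 - 1L,
                   field$triangles$n3 - 1L), con)
  if (length(scalars)) {
    writeLines(sprintf("POINT_DATA %d", nn), con)
    for (nm in names(scalars)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(scalars[[nm]], digits = 8), con)
    }
  }
  invisible(path)
}

#' Write and read orifice frames as PNG with a JSON sidecar
#'
#' The 8-bit grayscale PNG is accompanied by `<path>.json` holding
#' `mm_per_px` and `timestamp`.
#'
#' @param frame An [orifice_frame()].
#' @param path PNG path.
#' @return The frame (reader) or `path` invisibly (writer).
#' @export
write_orifice_png <- function(frame, path) {
  png::writePNG(frame$pixels / 255, path)
  jsonlite::write_json(list(mm_per_px = frame$mm_per_px,
                            timestamp = frame$timestamp),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_orifice_png
#' @export
read_orifice_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"))
  new_orifice_frame(round(px * 255), meta$mm_per_px,
                    meta$timestamp %||% 0)
}

#' Reference pulse-duplicator and simulation benchmark values
#'
#' Published benchmark measurements for three porcine-small-intestinal-
#' submucosa valve groups (raw scaffold, statically calcified, bioreactor
#' flow-conditioned calcified): the four hydrodynamic metrics measured on
#' a pulse duplicator (in vitro) and from a fluid-structure-interaction
#' simulation (in silico), and the matching geometric orifice areas.
#' Shipped as plain-text CSVs under `inst/extdata/` and used by the
#' package's validation examples.
#'
#' @return A tibble. `reference_hydrodynamics()`: columns `metric`
#'   (`rf_pct`, `delta_p_mmHg`, `q_rms_mls`, `eoa_cm2`), `group` (`raw`,
#'   `static`, `bioreactor`), `in_vitro`, `in_silico`.
#'   `reference_goa()`: columns `group`, `in_vitro`, `in_silico` (cm^2).
#' @export
reference_hydrodynamics <- function() {
  readr::read_csv(system.file("extdata", "hydro_reference.csv",
                              package = "valvebench"),
                  show_col_types = FALSE)
}

#' @rdname reference_hydrodynamics
#' @export
reference_goa <- function() {
  readr::read_csv(system.file("extdata", "goa_reference.csv",
                              package = "valvebench"),
                  show_col_types = FALSE)
}
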