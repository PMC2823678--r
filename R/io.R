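#' Export a trajectory record as CSV
#'
#' @param result A `sim_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(result, path) {
  utils::write.csv(result$trajectory, path, row.names = FALSE)
  invisible(path)
}

#' Export a gridded field as CSV
#'
#' Long-format `x, y, value` table of one species field (cell centres,
#' um).
#'
#' @param state A `sim_state`.
#' @param species Species name.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(state, species, path) {
  dom <- state$domain
  xc <- (seq_len(dom$nx) - 0.5) * dom$dx
  yc <- (seq_len(dom$ny) - 0.5) * dom$dx
  df <- data.frame(x = rep(xc, dom$ny), y = rep(yc, each = dom$nx),
                   value = state$conc[, species])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export fields as a legacy-ASCII VTK image file
#'
#' Writes the selected species fields (plus the gel mask and, when a flow
#' state is given, cell-centred velocities) as STRUCTURED_POINTS scalars
#' for visualization.
#'
#' @param state A `sim_state`.
#' @param path Output `.vtk` file.
#' @param species Species to include (default: fibrin and thrombin if
#'   present).
#' @param flow Optional `flow_state`.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(state, path,
                      species = intersect(c("Fn", "IIa"), state$species),
                      flow = NULL) {
  dom <- state$domain
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "coagflow fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", dom$nx, dom$ny),
               sprintf("ORIGIN %g %g 0", dom$dx / 2, dom$dx / 2),
               sprintf("SPACING %g %g 1", dom$dx, dom$dx),
               sprintf("POINT_DATA %d", dom$nx * dom$ny)), con)
  put <- function(name, vals) {
    writeLines(c(sprintf("SCALARS %s float 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(vals, digits = 7, trim = TRUE, scientific = TRUE),
               con)
  }
  for (s in species) put(s, state$conc[, s])
  put("gel", as.numeric(state$gel))
  if (!is.null(flow)) {
    uc <- (flow$u[seq_len(dom$nx), ] + flow$u[-1L, ]) / 2
    vc <- (flow$v[, seq_len(dom$ny)] + flow$v[, -1L]) / 2
    put("u", as.vector(uc))
    put("v", as.vector(vc))
  }
  invisible(path)
}

#' Write a scheme validation report
#'
#' Plain-text, machine-parsable, one issue per line (`OK` when valid).
#'
#' @param scheme A `kinetic_scheme` (or candidate list).
#' @param path Output file, or `""` for stdout.
#' @return The issue lines, invisibly.
#' @export
write_validation_report <- function(scheme, path = "") {
  issues <- validate_scheme(scheme)
  lines <- if (length(issues)) paste0("ERROR\t", issues) else "OK"
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(issues)
}
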