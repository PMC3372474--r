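#' Write a field state to a legacy-VTK rectilinear grid file
#'
#' ASCII legacy VTK (`DATASET RECTILINEAR_GRID`) with cell data: zone
#' label, temperature, pressure and the velocity vector.  Readable by
#' ParaView/VisIt for inspection of meshes and solutions.
#'
#' @param case An [fvm_case()] (for mesh and zones).
#' @param file Output path.
#' @param state Optional `field_state`; omit to export the mesh/zones
#'   only.
#' @return The file path, invisibly.
#' @export
write_vtk <- function(case, file, state = NULL) {
  mesh <- case$mesh
  con <- file(file, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  num <- function(v) paste(formatC(v, format = "g", digits = 9),
                           collapse = " ")
  wl("# vtk DataFile Version 3.0",
     "coraltherm rectilinear grid",
     "ASCII",
     "DATASET RECTILINEAR_GRID",
     sprintf("DIMENSIONS %d %d %d", mesh$nx + 1, mesh$ny + 1, mesh$nz + 1),
     sprintf("X_COORDINATES %d double", mesh$nx + 1), num(mesh$xf),
     sprintf("Y_COORDINATES %d double", mesh$ny + 1), num(mesh$yf),
     sprintf("Z_COORDINATES %d double", mesh$nz + 1), num(mesh$zf),
     sprintf("CELL_DATA %d", mesh$nx * mesh$ny * mesh$nz))
  wl("SCALARS zone int 1", "LOOKUP_TABLE default")
  wl(paste(as.vector(mesh$zone), collapse = " "))
  if (!is.null(state)) {
    wl("SCALARS temperature double 1", "LOOKUP_TABLE default")
    wl(num(as.vector(state$T)))
    wl("SCALARS pressure double 1", "LOOKUP_TABLE default")
    wl(num(as.vector(state$p)))
    wl("VECTORS velocity double")
    wl(num(as.vector(rbind(as.vector(state$u), as.vector(state$v),
                           as.vector(state$w)))))
  }
  invisible(file)
}
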