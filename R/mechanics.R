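axis_index <- function(axis) {
  if (is.character(axis)) match(tolower(axis), c("x", "y", "z"))
  else as.integer(axis)
}

#' Boundary condition specification
#'
#' A set of prescribed (vertex, direction) displacements plus the macroscopic
#' loading they encode. Usually built by [uniaxial_compression_bcs()].
#'
#' @param entries data frame with integer columns `i, j, k` (vertex, 1-based),
#'   `d` (direction, 1 = x, 2 = y, 3 = z) and numeric `value` (mm).
#' @param strain applied macroscopic strain (dimensionless).
#' @param axis loading axis (`"x"`, `"y"`, `"z"` or 1:3).
#' @param end_condition `"axial-only"` or `"clamped"`.
#' @return object of class `boundary_spec`.
#' @export
boundary_spec <- function(entries, strain = 0, axis = "z",
                          end_condition = "axial-only") {
  stopifnot(is.data.frame(entries),
            all(c("i", "j", "k", "d", "value") %in% names(entries)))
  if (anyDuplicated(entries[c("i", "j", "k", "d")]))
    stop("duplicate (vertex, direction) pairs in boundary spec")
  ax <- axis_index(axis)
  if (is.na(ax) || ax < 1L || ax > 3L) stop("`axis` must be x, y or z")
  structure(list(entries = entries, strain = strain, axis = ax,
                 end_condition = end_condition),
            class = "boundary_spec")
}

#' @export
print.boundary_spec <- function(x, ...) {
  cat(sprintf("<boundary_spec> %d prescribed dofs, strain %.4g along %s (%s)\n",
              nrow(x$entries), x$strain, c("x", "y", "z")[x$axis],
              x$end_condition))
  invisible(x)
}

#' Uniaxial compression boundary conditions
#'
#' Simulated compression test: the active vertices of the minimal face along
#' the load axis are held at zero axial displacement, the maximal face is
#' displaced by `-strain * L` (L = physical specimen length along the axis).
#' With `"axial-only"` ends (frictionless platens, the default) the transverse
#' directions stay free; `"clamped"` additionally fixes them to zero.
#'
#' @inheritParams element_moduli
#' @param strain applied compressive strain, `0 <= strain < 0.1`.
#' @param axis loading axis.
#' @param end_condition `"axial-only"` (default) or `"clamped"`.
#' @return a [boundary_spec()].
#' @export
uniaxial_compression_bcs <- function(model, law, strain = 0.01, axis = "z",
                                     end_condition = c("axial-only", "clamped")) {
  end_condition <- match.arg(end_condition)
  if (!is.finite(strain) || strain < 0 || strain >= 0.1)
    stop("`strain` must lie in [0, 0.1)")
  ax <- axis_index(axis)
  if (is.na(ax)) stop("`axis` must be x, y or z")
  act <- element_moduli(model, law) > 0
  if (!any(act)) stop("no material: every element modulus is zero")
  va <- vertex_activity(act)
  vdims <- dim(va)

  face_vertices <- function(layer) {
    idx <- switch(ax,
                  which(va[layer, , ], arr.ind = TRUE),
                  which(va[, layer, ], arr.ind = TRUE),
                  which(va[, , layer], arr.ind = TRUE))
    if (length(idx) == 0L) return(NULL)
    out <- matrix(layer, nrow(idx), 3L)
    out[, -ax] <- idx
    out
  }
  bottom <- face_vertices(1L)
  top <- face_vertices(vdims[ax])
  if (is.null(bottom) || is.null(top))
    stop("structure does not span load axis")

  L <- model$dims[ax] * model$voxel_size
  mk <- function(verts, d, value)
    data.frame(i = verts[, 1], j = verts[, 2], k = verts[, 3], d = d,
               value = value)
  ent <- rbind(mk(bottom, ax, 0), mk(top, ax, -strain * L))
  if (end_condition == "clamped") {
    for (d in setdiff(1:3, ax))
      ent <- rbind(ent, mk(bottom, d, 0), mk(top, d, 0))
  }
  boundary_spec(ent, strain = strain, axis = ax, end_condition = end_condition)
}

# linear positions (into the 3 x Vx x Vy x Vz dof array) of the axial
# prescribed dofs on the displaced (maximal) face
top_face_positions <- function(bcs, vdims) {
  ent <- bcs$entries
  ax <- bcs$axis
  top_layer <- vdims[ax]
  sel <- ent$d == ax & ent[[c("i", "j", "k")[ax]]] == top_layer
  ent <- ent[sel, , drop = FALSE]
  (vertex_linear(ent$i, ent$j, ent$k, vdims) - 1L) * 3L + ent$d
}

cross_section_area <- function(dims, voxel_size, axis) {
  prod(dims[-axis]) * voxel_size^2
}

#' Total stress on the displaced face
#'
#' Sum of axial reaction forces over the constrained vertices of the displaced
#' face, divided by the full cross-sectional area perpendicular to the load
#' axis (apparent stress). Compression is reported positive.
#'
#' @inheritParams total_vertex_forces
#' @param bcs the [boundary_spec()] of the solve.
#' @param model the [voxel_model()] (for dimensions and voxel size).
#' @return total stress in MPa.
#' @export
total_stress <- function(op, full_u, bcs, model) {
  forces <- total_vertex_forces(op, full_u)
  pos <- top_face_positions(bcs, op$vdims)
  -sum(forces[pos]) / cross_section_area(model$dims, model$voxel_size, bcs$axis)
}

# per-iteration monitor evaluating the total stress from the loaded-face
# element subset only (cheap relative to a full operator application)
make_stress_monitor <- function(op, bcs, model) {
  pos <- top_face_positions(bcs, op$vdims)
  hit <- matrix(op$gdofs %in% pos, 24L)
  sel <- which(colSums(hit) > 0L)
  dofs <- op$dofs[, sel, drop = FALSE]
  vals <- op$vals[, sel, drop = FALSE]
  mask <- matrix(as.integer(hit[, sel]), 24L)
  mod <- op$moduli[sel]
  area <- cross_section_area(model$dims, model$voxel_size, bcs$axis)
  kernel <- op$kernel
  function(u, n) {
    -ebe_face_force_cpp(kernel, dofs, vals, mod, u, mask) / area
  }
}

#' Apparent stiffness
#'
#' Macroscopic stress/strain ratio of the compression test, in MPa.
#'
#' @param stress total stress (MPa).
#' @param strain applied strain (> 0).
#' @return apparent stiffness (MPa).
#' @export
apparent_stiffness <- function(stress, strain) {
  if (!is.finite(strain) || strain <= 0) stop("`strain` must be positive")
  stress / strain
}

#' Strain-energy map
#'
#' Per-voxel strain energy `0.5 E_e u' K u` of the displacement field;
#' inactive voxels are zero.
#'
#' @inheritParams total_stress
#' @return 3D numeric array (N mm per element) with the model's dimensions.
#' @export
strain_energy_map <- function(op, full_u, model) {
  en <- ebe_energy_cpp(op$kernel, op$gdofs, op$moduli, as.numeric(full_u))
  out <- array(0, model$dims)
  out[op$dofmap$elem_lin] <- en
  out
}
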