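#' Triangulated surface mesh
#'
#' The basic surface container: vertex coordinates in cm, 1-based triangular
#' faces, optional per-face integer labels (with a code-to-name map in
#' \code{labelNames}) and named boundary ports. Each port tag is the ordered
#' vertex-index loop of one open boundary (e.g. \code{OSTIUM}, \code{PV1},
#' \code{MV}).
#'
#' @slot vertices N x 3 numeric matrix of coordinates (cm).
#' @slot faces M x 3 integer matrix of vertex indices.
#' @slot faceLabels integer vector of length M (0 = unlabeled wall), or
#'   length 0 when the mesh carries no labels.
#' @slot labelNames named character vector mapping label codes (names) to
#'   patch names.
#' @slot portTags named list of ordered integer vertex loops.
#' @export
setClass("TriSurfaceMesh",
  representation(vertices = "matrix", faces = "matrix",
                 faceLabels = "integer", labelNames = "character",
                 portTags = "list"),
  prototype(faceLabels = integer(0), labelNames = character(0),
            portTags = list()))

setValidity("TriSurfaceMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3) return("vertices must have 3 columns")
  if (ncol(f) != 3) return("faces must have 3 columns")
  if (nrow(f) > 0 && (min(f) < 1 || max(f) > nrow(v)))
    return("face indices out of range")
  if (length(object@faceLabels) > 0 && length(object@faceLabels) != nrow(f))
    return("faceLabels must match the number of faces")
  key <- apply(f, 1, function(r) paste(sort(r), collapse = "-"))
  if (anyDuplicated(key)) return("duplicate faces")
  TRUE
})

#' Tetrahedral volume mesh
#'
#' The CFD computational domain: vertices, tetrahedra with positive volume,
#' and boundary triangles partitioned into named patches
#' (\code{WALL}, \code{PV1}..\code{PV4}, \code{MV}, ...).
#'
#' @slot vertices N x 3 numeric matrix (cm).
#' @slot tets K x 4 integer matrix.
#' @slot boundaryFaces B x 3 integer matrix (outward oriented).
#' @slot boundaryPatch character vector of length B.
#' @export
setClass("TetMesh",
  representation(vertices = "matrix", tets = "matrix",
                 boundaryFaces = "matrix", boundaryPatch = "character"))

setValidity("TetMesh", function(object) {
  if (ncol(object@tets) != 4) return("tets must have 4 columns")
  if (nrow(object@boundaryFaces) != length(object@boundaryPatch))
    return("boundaryPatch must match boundaryFaces")
  v <- object@vertices; tt <- object@tets
  a <- v[tt[, 1], , drop = FALSE]
  vol <- rowSums(rowCross(v[tt[, 2], , drop = FALSE] - a,
                          v[tt[, 3], , drop = FALSE] - a) *
                 (v[tt[, 4], , drop = FALSE] - a)) / 6
  if (any(vol <= 0)) return("non-positive tetrahedron volumes")
  TRUE
})

#' LAA centerline
#'
#' Ordered polyline through the appendage lumen from the ostium barycenter
#' to the apex, carrying its arclength L and endpoint distance D (cm).
#' Tortuosity is \code{L/D - 1}.
#'
#' @slot points n x 3 numeric matrix (cm).
#' @slot L arclength (cm).
#' @slot D Euclidean endpoint distance (cm).
#' @export
setClass("Centerline",
  representation(points = "matrix", L = "numeric", D = "numeric"))

setValidity("Centerline", function(object) {
  if (nrow(object@points) < 2) return("centerline needs at least 2 points")
  if (object@D <= 0) return("endpoint distance must be positive")
  if (object@L < object@D - 1e-9) return("arclength cannot be below endpoint distance")
  TRUE
})

#' LAA geometric descriptor report
#'
#' Volume V (cm^3), lateral surface area As (cm^2), orifice area Ao (cm^2)
#' and perimeter Po (cm), centerline length L (cm) and tortuosity chi.
#'
#' @export
setClass("LAAGeometryReport",
  representation(V = "numeric", As = "numeric", Ao = "numeric",
                 Po = "numeric", L = "numeric", chi = "numeric"))

setValidity("LAAGeometryReport", function(object) {
  vals <- c(object@V, object@As, object@Ao, object@Po, object@L)
  if (any(vals <= 0)) return("all geometric quantities must be positive")
  if (object@chi < 0) return("tortuosity cannot be negative")
  if (object@Po^2 < 4 * pi * object@Ao * (1 - 1e-9))
    return("isoperimetric inequality violated by orifice metrics")
  TRUE
})

#' Shape diameter function field
#'
#' Per-face local diameter estimates (cm) with the cone-sampling parameters
#' used to compute them.
#' @export
setClass("SDFField",
  representation(values = "numeric", coneHalfAngle = "numeric",
                 nRays = "integer", seed = "integer"))

setValidity("SDFField", function(object) {
  if (any(!is.finite(object@values)) || any(object@values <= 0))
    return("SDF values must be positive and finite")
  TRUE
})

#' Semantic region labels on a surface mesh
#'
#' Per-face region ids after clustering and connected-component splitting;
#' \code{chamberId} is the modal region (the atrial chamber).
#' @export
setClass("RegionLabels",
  representation(labels = "integer", chamberId = "integer"))

setValidity("RegionLabels", function(object) {
  if (length(object@labels) == 0) return("empty labels")
  if (modeInt(object@labels) != object@chamberId)
    return("chamberId must equal the modal label")
  TRUE
})

#' Rigid (optionally scaled) transform
#'
#' @slot rotation 3 x 3 orthonormal matrix with determinant +1.
#' @slot translation length-3 vector (cm).
#' @slot scale positive uniform scale factor (1 = rigid).
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 scale = "numeric"),
  prototype(scale = 1))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6) return("rotation not orthonormal")
  if (det(R) < 0) return("rotation must have determinant +1")
  if (object@scale <= 0) return("scale must be positive")
  TRUE
})

#' Time series of flow fields on a tetrahedral mesh
#'
#' Nodal velocities (cm/s) and reduced pressures at equidistant time steps,
#' plus the wall-motion displacement mode and per-patch flowrate history.
#'
#' @slot mesh the \linkS4class{TetMesh} computational domain.
#' @slot times snapshot times (s), equidistant.
#' @slot velocity nV x 3 x nT numeric array (cm/s).
#' @slot pressure nV x nT matrix of kinematic pressure p/rho, or NULL.
#' @slot displacementMode nV x 3 static displacement field; the instantaneous
#'   mesh displacement is \code{sin(2 pi f t) * displacementMode}.
#' @slot motionFrequency wall motion frequency (Hz).
#' @slot flowrates data.frame with one row per step: time, per-patch
#'   flowrates (ml/s, positive outward), dVdt and the global mass defect.
#' @export
setClass("FlowFieldSeries",
  representation(mesh = "TetMesh", times = "numeric", velocity = "array",
                 pressure = "ANY", displacementMode = "matrix",
                 motionFrequency = "numeric", flowrates = "data.frame"))

setValidity("FlowFieldSeries", function(object) {
  d <- dim(object@velocity)
  if (length(d) != 3 || d[2] != 3) return("velocity must be nV x 3 x nT")
  if (d[1] != nrow(object@mesh@vertices)) return("velocity/mesh size mismatch")
  if (d[3] != length(object@times)) return("velocity/time size mismatch")
  if (length(object@times) > 2) {
    dt <- diff(object@times)
    if (max(abs(dt - dt[1])) > 1e-9) return("snapshots must be equidistant")
  }
  if (!all(is.finite(object@velocity))) return("non-finite velocities")
  TRUE
})

#' Q-criterion field
#'
#' Per-cell Q values (1/s^2) at one time step, under either the printed
#' convention (velocity-gradient sums without the 1/2 factor inside S and W)
#' or the standard convention; printed values are exactly 4x standard ones.
#' @export
setClass("QCriterionField",
  representation(values = "numeric", convention = "character",
                 time = "numeric"))

#' Ostium velocity trace
#'
#' Area-averaged normal velocity at the grafted ostium section (cm/s);
#' positive values mean LAA emptying, negative filling. \code{lowWashout}
#' flags a peak emptying velocity below 20 cm/s.
#' @export
setClass("OstiumTrace",
  representation(times = "numeric", velocity = "numeric",
                 peakEmptying = "numeric", lowWashout = "logical"))

#' Passive tracer ensemble
#'
#' Initial positions, per-snapshot trajectories and departure status of
#' passive particles seeded inside the LAA.
#'
#' @slot positions0 nP x 3 initial positions (cm).
#' @slot traj nP x 3 x nT trajectory array, or a 0-length array before
#'   advection.
#' @slot times snapshot times covered by \code{traj}.
#' @slot status integer per particle: 0 alive, 1 departed through the MV.
#' @export
setClass("ParticleEnsemble",
  representation(positions0 = "matrix", traj = "array", times = "numeric",
                 status = "integer"))
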