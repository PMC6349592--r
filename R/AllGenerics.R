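#' @rdname TriSurfaceMesh-class
#' @param object,x a mesh object.
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname TriSurfaceMesh-class
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' @rdname TriSurfaceMesh-class
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname TriSurfaceMesh-class
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' @rdname TriSurfaceMesh-class
#' @export
setGeneric("portTags", function(x) standardGeneric("portTags"))

#' Total surface area of a mesh
#'
#' Sum of triangle areas, in cm^2.
#' @param x a \linkS4class{TriSurfaceMesh}.
#' @return numeric scalar (cm^2).
#' @export
setGeneric("surfaceArea", function(x) standardGeneric("surfaceArea"))

#' Enclosed volume of a closed mesh
#'
#' Volume by the divergence theorem (sum of signed tetrahedra to the
#' origin), in cm^3. The mesh must be closed: cap any open ports first.
#' @param x a \linkS4class{TriSurfaceMesh}.
#' @return numeric scalar (cm^3).
#' @export
setGeneric("enclosedVolume", function(x) standardGeneric("enclosedVolume"))

#' Ordered boundary loops of a surface mesh
#'
#' Walks the directed boundary edges into closed vertex loops, returned in
#' decreasing order of loop length.
#' @param x a \linkS4class{TriSurfaceMesh}.
#' @return list of integer vertex-index vectors.
#' @export
setGeneric("boundaryLoops", function(x) standardGeneric("boundaryLoops"))

#' Tortuosity of a centerline
#'
#' \code{L/D - 1}: arclength over endpoint distance minus one; 0 for a
#' straight duct.
#' @param x a \linkS4class{Centerline}.
#' @return dimensionless numeric scalar.
#' @export
setGeneric("tortuosity", function(x) standardGeneric("tortuosity"))
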