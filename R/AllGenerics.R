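# Accessor generics and show methods for the S4 containers.

#' @rdname StructureSet-class
#' @param x,object An object.
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))

#' @rdname StructureSet-class
#' @param name Structure name.
#' @export
setGeneric("getMask", function(x, name) standardGeneric("getMask"))

#' @rdname StructureSet-class
#' @export
setGeneric("structureRoles", function(x) standardGeneric("structureRoles"))

#' @rdname StructureSet-class
#' @export
setGeneric("priorityMode", function(x) standardGeneric("priorityMode"))

#' Voxel spacing accessor (mm)
#' @param x An object with a voxel grid.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Grid shape accessor (voxels per axis)
#' @param x An object with a voxel grid.
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname Plan-class
#' @param x An object.
#' @export
setGeneric("planWeights", function(x) standardGeneric("planWeights"))

#' @rdname Plan-class
#' @export
setGeneric("strategyTag", function(x) standardGeneric("strategyTag"))

#' @rdname SpotGrid-class
#' @param x An object.
#' @export
setGeneric("nSpots", function(x) standardGeneric("nSpots"))

#' @rdname SpotGrid-class
#' @export
setGeneric("spotTable", function(x) standardGeneric("spotTable"))

#' @rdname StructureSet-class
#' @export
setMethod("structureNames", "StructureSet", function(x) names(x@masks))

#' @rdname StructureSet-class
#' @export
setMethod("getMask", "StructureSet", function(x, name) {
  if (!name %in% names(x@masks)) {
    stop("structure '", name, "' not present; available: ",
         paste(names(x@masks), collapse = ", "))
  }
  x@masks[[name]]
})

#' @rdname StructureSet-class
#' @export
setMethod("structureRoles", "StructureSet", function(x) x@roles[names(x@masks)])

#' @rdname StructureSet-class
#' @export
setMethod("priorityMode", "StructureSet", function(x) x@priorityMode)

#' @rdname StructureSet-class
#' @export
setMethod("voxelSpacing", "StructureSet", function(x) x@spacing)

#' @rdname StructureSet-class
#' @export
setMethod("gridShape", "StructureSet", function(x) dim(x@masks[[1]]))

#' @rdname Phantom-class
#' @export
setMethod("voxelSpacing", "Phantom", function(x) x@spacing)

#' @rdname Phantom-class
#' @export
setMethod("gridShape", "Phantom", function(x) dim(x@density))

#' Clinical structures of a phantom
#' @param x A [Phantom-class].
#' @return The ground-truth [StructureSet-class].
#' @export
clinicalStructures <- function(x) {
  stopifnot(is(x, "Phantom"))
  x@structures
}

#' Density grid of a phantom
#' @param x A [Phantom-class].
#' @return Numeric 3D array of relative stopping power.
#' @export
densityGrid <- function(x) {
  stopifnot(is(x, "Phantom"))
  x@density
}

#' @rdname Plan-class
#' @export
setMethod("planWeights", "Plan", function(x) x@weights)

#' @rdname Plan-class
#' @export
setMethod("strategyTag", "Plan", function(x) x@strategy)

#' @rdname SpotGrid-class
#' @export
setMethod("nSpots", "SpotGrid", function(x) nrow(x@spots))

#' @rdname SpotGrid-class
#' @export
setMethod("spotTable", "SpotGrid", function(x) x@spots)

#' @rdname Plan-class
#' @export
setMethod("spotTable", "Plan", function(x) x@spots@spots)

#' @rdname Plan-class
#' @export
setMethod("nSpots", "Plan", function(x) nrow(x@spots@spots))

#' @rdname InfluenceMatrix-class
#' @export
setMethod("gridShape", "InfluenceMatrix", function(x) x@gridDim)

#' @rdname InfluenceMatrix-class
#' @export
setMethod("voxelSpacing", "InfluenceMatrix", function(x) x@spacing)

setMethod("show", "StructureSet", function(object) {
  r <- object@roles[names(object@masks)]
  cat("StructureSet on", paste(dim(object@masks[[1]]), collapse = "x"),
      "grid,", paste(signif(object@spacing, 3), collapse = "x"), "mm voxels\n")
  cat("  priority mode:", object@priorityMode, "\n")
  for (nm in names(object@masks)) {
    cat(sprintf("  %-14s %-8s %7.1f cc\n", nm, r[[nm]],
                sum(object@masks[[nm]]) * voxelVolumeCC(object@spacing)))
  }
})

setMethod("show", "Phantom", function(object) {
  cat("Phantom [", object@template, "], fraction ", object@fractionIndex, ", grid ",
      paste(dim(object@density), collapse = "x"), ", ",
      paste(signif(object@spacing, 3), collapse = "x"), " mm\n", sep = "")
  cat("  density range:", paste(signif(range(object@density), 3), collapse = " - "), "\n")
  cat("  structures:", paste(names(object@structures@masks), collapse = ", "), "\n")
})

setMethod("show", "SpotGrid", function(object) {
  cat("SpotGrid:", nrow(object@spots), "spots in", length(object@beams), "beams\n")
  print(table(beam = object@spots$beam))
})

setMethod("show", "InfluenceMatrix", function(object) {
  cat("InfluenceMatrix:", nrow(object@dose), "spots x", ncol(object@dose),
      "voxels,", length(object@dose@x), "nonzeros\n")
  cat("  scenario:", object@scenario$label, "\n")
})

setMethod("show", "Plan", function(object) {
  cat("Plan [", object@strategy, "]: ", length(object@weights), " spots, ",
      sum(object@weights > 0), " active\n", sep = "")
  if (!is.null(object@diagnostics$iterations)) {
    cat("  solver: ", object@diagnostics$iterations, " iterations, objective ",
        signif(object@diagnostics$objective, 5), ", converged: ",
        isTRUE(object@diagnostics$converged), "\n", sep = "")
  }
})

setMethod("show", "AgreementMap", function(object) {
  cat("AgreementMap over K =", object@K, "sets;", length(object@values), "structures\n")
})

setMethod("show", "SubstructureSet", function(object) {
  cat("SubstructureSet (K =", object@K, "): levels",
      paste(names(object@levels[[1]]), collapse = "/"), "for",
      length(object@levels), "structures\n")
})
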