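# En-face slab projection: maximum intensity projection of a structural or
# flow volume between two retinal boundary surfaces.  Depth increases away
# from the vitreous; "below" a surface adds to depth.  Slabs are half-open
# [inner, outer) so adjacent slabs never double-count a voxel boundary.

#' BoundarySurfaces: retinal layer boundary depths
#'
#' @slot ilm inner limiting membrane depth, um, matrix over (y, x).
#' @slot inl inner nuclear layer depth, um, matrix over (y, x).
#' @slot axialPixel axial voxel size, um.
#' @export
setClass("BoundarySurfaces", representation(ilm = "matrix", inl = "matrix",
                                            axialPixel = "numeric"))

setValidity("BoundarySurfaces", function(object) {
  if (!all(dim(object@ilm) == dim(object@inl)))
    return("ILM and INL surfaces must share one shape")
  if (!all(is.finite(object@ilm)) || !all(is.finite(object@inl)))
    return("boundary depths must be finite")
  if (any(object@inl < object@ilm))
    return("INL depth must be >= ILM depth everywhere")
  if (object@axialPixel <= 0) return("axialPixel must be > 0")
  TRUE
})

#' @param ilm ILM depth matrix, um.
#' @param inl INL depth matrix, um.
#' @param axialPixel axial voxel size, um.
#' @rdname BoundarySurfaces-class
#' @export
boundarySurfaces <- function(ilm, inl, axialPixel) {
  new("BoundarySurfaces", ilm = ilm, inl = inl, axialPixel = axialPixel)
}

#' SlabDefinition: a depth slab between offset boundary surfaces
#'
#' @slot name slab label.
#' @slot innerRef,outerRef reference surface names (`"ILM"` or `"INL"`).
#' @slot innerOffset,outerOffset offsets below the reference surfaces, um.
#' @export
setClass("SlabDefinition", representation(name = "character",
                                          innerRef = "character",
                                          innerOffset = "numeric",
                                          outerRef = "character",
                                          outerOffset = "numeric"))

setValidity("SlabDefinition", function(object) {
  if (!object@innerRef %in% c("ILM", "INL") ||
      !object@outerRef %in% c("ILM", "INL"))
    return("reference surfaces must be ILM or INL")
  TRUE
})

#' @param name label.
#' @param innerRef,innerOffset inner bound: surface and offset below it, um.
#' @param outerRef,outerOffset outer bound: surface and offset below it, um.
#' @rdname SlabDefinition-class
#' @export
slabDefinition <- function(name, innerRef, innerOffset, outerRef,
                           outerOffset) {
  new("SlabDefinition", name = name, innerRef = innerRef,
      innerOffset = innerOffset, outerRef = outerRef,
      outerOffset = outerOffset)
}

#' Built-in retinal slabs
#'
#' The superficial slab runs from the ILM to 15.6 um below the INL; the deep
#' slab from 15.6 um to 70.2 um below the INL.  An outer-retina slab for
#' neovascular lesions is deliberately not fixed here: its bounds are
#' lesion-dependent and are configured per analysis.
#'
#' @return named list of [SlabDefinition-class] objects.
#' @export
builtinSlabs <- function() {
  list(
    superficial = slabDefinition("superficial", "ILM", 0, "INL", 15.6),
    deep = slabDefinition("deep", "INL", 15.6, "INL", 70.2)
  )
}

slabDepths <- function(boundaries, slab) {
  ref <- function(which) switch(which, ILM = boundaries@ilm,
                                INL = boundaries@inl)
  list(inner = ref(slab@innerRef) + slab@innerOffset,
       outer = ref(slab@outerRef) + slab@outerOffset)
}

#' En-face maximum intensity projection of a slab
#'
#' Per (y, x) column, takes the maximum voxel value over depths in the
#' half-open interval \[inner, outer).  Voxel `i` covers depths
#' `[(i-1), i) * axialPixel`; voxels partially covered by the slab are
#' included.  Columns where the slab is empty (outer <= inner) become `NA`
#' and are flagged in the `"emptySlab"` attribute.
#'
#' @param volume numeric array `(ny, nx, nz)`, depth along the third axis.
#' @param boundaries a [BoundarySurfaces-class].
#' @param slab a [SlabDefinition-class].
#' @return `(ny, nx)` matrix with attribute `emptySlab`.
#' @export
extractSlabEnface <- function(volume, boundaries, slab) {
  stopifnot(is(boundaries, "BoundarySurfaces"), is(slab, "SlabDefinition"))
  validObject(boundaries)
  d <- dim(volume)
  stopifnot(length(d) == 3, all(d[1:2] == dim(boundaries@ilm)))
  dz <- boundaries@axialPixel
  dep <- slabDepths(boundaries, slab)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  out <- matrix(NA_real_, ny, nx)
  empty <- dep$outer <= dep$inner
  i1 <- floor(dep$inner / dz) + 1
  i2 <- ceiling(dep$outer / dz)
  i1[i1 < 1] <- 1; i1[i1 > nz] <- nz
  i2[i2 < 1] <- 1; i2[i2 > nz] <- nz
  for (col in seq_len(nx)) for (row in seq_len(ny)) {
    if (empty[row, col]) next
    a <- i1[row, col]; b <- i2[row, col]
    if (b < a) next
    out[row, col] <- max(volume[row, col, a:b])
  }
  attr(out, "emptySlab") <- empty
  out
}
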