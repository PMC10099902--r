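#' Compartment labels of a voxelised leaf volume
#'
#' Integer codes used in the `label` array of a [labelled_volume].  Cell
#' walls thinner than one voxel are not represented as voxels of their own;
#' wall resistance is applied at voxel interfaces by the transport module
#' (see [assemble_system]).  The `mc_wall`/`bs_wall` codes exist for volumes
#' generated at resolutions finer than the wall thickness.
#'
#' @return Named integer vector mapping compartment names to label codes.
#' @export
#' @examples
#' leaf_labels()
leaf_labels <- function() {
  c(airspace       = 0L,
    mc_wall        = 1L,
    mc_cytosol     = 2L,
    mc_chloroplast = 3L,
    mc_vacuole     = 4L,
    bs_wall        = 5L,
    bs_cytosol     = 6L,
    bs_chloroplast = 7L,
    epidermis      = 8L,
    bulliform      = 9L,
    vein           = 10L)
}

.LBL <- leaf_labels()

## label groups used throughout the solvers
.MC_LABELS     <- .LBL[c("mc_wall", "mc_cytosol", "mc_chloroplast", "mc_vacuole")]
.BS_LABELS     <- .LBL[c("bs_wall", "bs_cytosol", "bs_chloroplast")]
.LIQUID_LABELS <- c(.MC_LABELS, .BS_LABELS)
.CHLORO_LABELS <- .LBL[c("mc_chloroplast", "bs_chloroplast")]
.SOLID_LABELS  <- .LBL[c("epidermis", "bulliform", "vein")]
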