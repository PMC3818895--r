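#' Connected-component labeling
#'
#' Labels connected foreground components of a 2D or 3D logical array.
#' Foreground objects conventionally use 8-connectivity in-plane and
#' 26-connectivity in 3D; the complementary background (hole) labeling uses
#' 4- and 6-connectivity respectively, the standard pairing that avoids
#' topological paradoxes.
#'
#' @param mask logical matrix or 3D array.
#' @param connectivity 4 or 8 for 2D; 6, 18 or 26 for 3D.
#' @return integer array of the same shape, 0 = background, components
#'   numbered from 1; attribute `n_components`.
#' @export
label_components <- function(mask, connectivity = if (length(dim(mask)) == 3) 26 else 8) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% c(2, 3)))
    stop("mask must be a 2D or 3D array")
  .label_cc(as.logical(mask), as.integer(d), as.integer(connectivity))
}

# per-label voxel counts from a label array (0 ignored)
label_sizes <- function(labels) {
  n <- attr(labels, "n_components")
  if (is.null(n)) n <- max(labels, 0L)
  if (n == 0) return(integer(0))
  tabulate(labels[labels > 0L], nbins = n)
}
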