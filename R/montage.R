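# 32-channel Biosemi 10-20 scalp layout, projected onto the unit disc with
# the vertex (Cz) at the origin and the nose toward +y. Radii follow an
# azimuthal-equidistant projection of the conventional spherical positions
# (outermost 10% ring at radius 1).
.biosemi32 <- local({
  tab <- rbind(
    Fp1 = c(-0.309, 0.951), AF3 = c(-0.320, 0.713), F7 = c(-0.8090, 0.5878),
    F3  = c(-0.434, 0.536), FC1 = c(-0.200, 0.200), FC5 = c(-0.663, 0.254),
    T7  = c(-1.000, 0.000), C3  = c(-0.400, 0.000), CP1 = c(-0.200, -0.200),
    CP5 = c(-0.663, -0.254), P7 = c(-0.8090, -0.5878), P3 = c(-0.434, -0.536),
    Pz  = c(0.000, -0.400), PO3 = c(-0.320, -0.713), O1 = c(-0.309, -0.951),
    Oz  = c(0.000, -1.000), O2  = c(0.309, -0.951), PO4 = c(0.320, -0.713),
    P4  = c(0.434, -0.536), P8  = c(0.8090, -0.5878), CP6 = c(0.663, -0.254),
    CP2 = c(0.200, -0.200), C4  = c(0.400, 0.000), T8 = c(1.000, 0.000),
    FC6 = c(0.663, 0.254), FC2 = c(0.200, 0.200), F4 = c(0.434, 0.536),
    F8  = c(0.8090, 0.5878), AF4 = c(0.320, 0.713), Fp2 = c(0.309, 0.951),
    Fz  = c(0.000, 0.400), Cz  = c(0.000, 0.000)
  )
  colnames(tab) <- c("x", "y")
  tab
})

#' Build the 32-channel scalp montage
#'
#' Returns the Biosemi 10-20 32-channel layout with 2-D unit-disc
#' coordinates and a k-nearest-neighbor set per channel (Euclidean distance
#' in the projected plane, self excluded). The neighbor sets drive bad-channel
#' interpolation.
#'
#' @param neighbor_k number of nearest neighbors per channel (1..31).
#' @return An object of class `eeg_montage`: list with `channel_names`,
#'   `positions` (32 x 2 matrix), `neighbor_k` and `neighbors` (named list of
#'   character vectors).
#' @examples
#' m <- build_montage(4)
#' m$neighbors$Oz
#' @export
build_montage <- function(neighbor_k = 4L) {
  assert_scalar_num(neighbor_k, "neighbor_k", 1, 31)
  neighbor_k <- as.integer(neighbor_k)
  pos <- .biosemi32
  d <- as.matrix(stats::dist(pos))
  neighbors <- lapply(rownames(pos), function(ch) {
    ord <- order(d[ch, ])
    nb <- rownames(pos)[ord]
    nb <- nb[nb != ch]
    nb[seq_len(neighbor_k)]
  })
  names(neighbors) <- rownames(pos)
  structure(
    list(
      channel_names = rownames(pos),
      positions = pos,
      neighbor_k = neighbor_k,
      neighbors = neighbors
    ),
    class = "eeg_montage"
  )
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels, k = %d neighbors\n",
              length(x$channel_names), x$neighbor_k))
  invisible(x)
}

montage_check_channels <- function(montage, channels) {
  miss <- setdiff(channels, montage$channel_names)
  if (length(miss)) {
    stop_invalid("unknown channel(s): %s", paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
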