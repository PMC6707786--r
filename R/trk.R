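#' Write streamlines in TrackVis .trk format
#'
#' Minimal TrackVis version-2 writer (1000-byte header, float32 points).
#' Points are stored in TrackVis "voxmm" convention - voxel index times voxel
#' size, with the voxel center at `(i + 0.5) * size` - converted from the
#' world mm coordinates of the streamline set via `affine`.
#'
#' @param s a `streamline_set` (world mm polylines).
#' @param path output `.trk` path.
#' @param affine voxel-to-world affine of the tracking grid.
#' @param dims grid voxel counts (length 3).
#' @return `path`, invisibly.
#' @export
write_trk <- function(s, path, affine, dims) {
  vsz <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), raw(1)), con)
  writeBin(as.integer(dims), con, size = 2)
  writeBin(as.numeric(vsz), con, size = 4)
  writeBin(numeric(3), con, size = 4)                 # origin (unused)
  writeBin(0L, con, size = 2)                          # n_scalars
  writeBin(raw(200), con)                              # scalar names
  writeBin(0L, con, size = 2)                          # n_properties
  writeBin(raw(200), con)                              # property names
  writeBin(as.numeric(t(affine)), con, size = 4)       # vox_to_ras, row major
  writeBin(raw(444), con)                              # reserved
  writeBin(c(charToRaw("RAS"), raw(1)), con)           # voxel_order
  writeBin(raw(4), con)                                # pad2
  writeBin(numeric(6), con, size = 4)                  # image orientation
  writeBin(raw(2), con)                                # pad1
  writeBin(raw(6), con)                                # invert/swap flags
  writeBin(length(s), con, size = 4)                   # n_count
  writeBin(2L, con, size = 4)                          # version
  writeBin(1000L, con, size = 4)                       # hdr_size
  inv_aff <- solve(affine)
  for (line in s) {
    ci <- t(inv_aff %*% rbind(t(line), 1))[, 1:3, drop = FALSE]
    voxmm <- sweep(ci + 0.5, 2, vsz, "*")
    writeBin(nrow(line), con, size = 4)
    writeBin(as.numeric(t(voxmm)), con, size = 4)
  }
  invisible(path)
}

#' Read a TrackVis .trk file written by [write_trk()]
#'
#' @param path `.trk` path.
#' @return a `streamline_set` in world mm coordinates.
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- rawToChar(readBin(con, raw(), 6)[1:5])
  if (!identical(id, "TRACK"))
    stop(vol_error("not a TrackVis .trk file", "bad_trk"))
  dims <- readBin(con, integer(), 3, size = 2)
  vsz <- readBin(con, numeric(), 3, size = 4)
  invisible(readBin(con, numeric(), 3, size = 4))
  invisible(readBin(con, integer(), 1, size = 2))
  invisible(readBin(con, raw(), 200))
  invisible(readBin(con, integer(), 1, size = 2))
  invisible(readBin(con, raw(), 200))
  aff <- matrix(readBin(con, numeric(), 16, size = 4), 4, 4, byrow = TRUE)
  invisible(readBin(con, raw(), 444 + 4 + 4 + 24 + 2 + 6))
  n_count <- readBin(con, integer(), 1, size = 4)
  invisible(readBin(con, integer(), 2, size = 4))
  lines <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, integer(), 1, size = 4)
    pts <- matrix(readBin(con, numeric(), 3 * np, size = 4), ncol = 3,
                  byrow = TRUE)
    ci <- sweep(pts, 2, vsz, "/") - 0.5
    lines[[i]] <- t(aff %*% rbind(t(ci), 1))[, 1:3, drop = FALSE]
  }
  structure(lines, class = "streamline_set")
}

#' Write streamlines as a TSV point list
#'
#' Long-format table: `streamline`, `point`, `x`, `y`, `z` (world mm).
#' @param s a `streamline_set`.
#' @param path output TSV path.
#' @export
write_streamlines_tsv <- function(s, path) {
  tab <- do.call(rbind, lapply(seq_along(s), function(i)
    data.frame(streamline = i, point = seq_len(nrow(s[[i]])),
               x = s[[i]][, 1], y = s[[i]][, 2], z = s[[i]][, 3])))
  if (is.null(tab)) tab <- data.frame(streamline = integer(), point = integer(),
                                      x = numeric(), y = numeric(), z = numeric())
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
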