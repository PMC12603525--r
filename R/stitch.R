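#' Assemble a montage from a dense tile grid
#'
#' Abuts the tiles of a [tile_montage()] grid in row-major order with zero
#' overlap and no blending, reproducing the acquisition geometry in which
#' adjacent tiles are scanned without overlap. Pixel values are copied
#' unmodified, so `stitch_tiles(tile_montage(m, ...))` is the identity on
#' pixel values.
#'
#' @param grid a `tile_grid`.
#' @return a [micrograph()] holding the montage, with tile provenance in the
#'   `provenance` attribute.
#' @export
stitch_tiles <- function(grid) {
  if (!inherits(grid, "tile_grid")) stop("expected a tile_grid")
  gr <- grid$grid_dim[1]; gc <- grid$grid_dim[2]
  th <- grid$tile_shape_px[1]; tw <- grid$tile_shape_px[2]
  for (r in seq_len(gr)) {
    for (cc in seq_len(gc)) {
      t <- grid$tiles[[r, cc]]
      if (is.null(t)) stop(sprintf("missing tile at grid position (%d, %d)",
                                   r, cc))
      if (!all(dim(t) == c(th, tw))) {
        stop(sprintf("tile (%d, %d) has shape %d x %d, expected %d x %d",
                     r, cc, nrow(t), ncol(t), th, tw))
      }
    }
  }
  px <- matrix(0L, gr * th, gc * tw) # promoted to double if tiles are double
  for (r in seq_len(gr)) {
    for (cc in seq_len(gc)) {
      px[((r - 1) * th + 1):(r * th), ((cc - 1) * tw + 1):(cc * tw)] <-
        grid$tiles[[r, cc]]
    }
  }
  out <- micrograph(px, pixel_size_nm = grid$pixel_size_nm,
                    bit_depth = grid$bit_depth, channel = grid$channel)
  attr(out, "provenance") <- list(grid_dim = grid$grid_dim,
                                  tile_shape_px = grid$tile_shape_px)
  out
}

#' Write tiles to / read tiles from a directory of TIFF files
#'
#' Tiles are named `tile_r<row>_c<col>.tif` (1-based grid positions), the
#' documented pattern for round-tripping a grid through the filesystem.
#'
#' @param grid a `tile_grid`.
#' @param dir directory (created if needed).
#' @inheritParams micrograph
#' @return `dir` (write) or a `tile_grid` (read).
#' @export
write_tiles <- function(grid, dir) {
  stopifnot(inherits(grid, "tile_grid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_len(grid$grid_dim[1])) {
    for (cc in seq_len(grid$grid_dim[2])) {
      m <- micrograph(grid$tiles[[r, cc]], grid$pixel_size_nm,
                      grid$bit_depth, grid$channel)
      write_micrograph_tiff(m, file.path(dir,
                                         sprintf("tile_r%d_c%d.tif", r, cc)))
    }
  }
  invisible(dir)
}

#' @rdname write_tiles
#' @export
read_tiles <- function(dir, pixel_size_nm = 68, bit_depth = 12,
                       channel = "") {
  files <- list.files(dir, pattern = "^tile_r[0-9]+_c[0-9]+\\.tif$")
  if (length(files) == 0) stop("no tile_r<row>_c<col>.tif files in ", dir)
  rr <- as.integer(sub("^tile_r([0-9]+)_c[0-9]+\\.tif$", "\\1", files))
  cc <- as.integer(sub("^tile_r[0-9]+_c([0-9]+)\\.tif$", "\\1", files))
  gr <- max(rr); gc <- max(cc)
  tiles <- vector("list", gr * gc)
  dim(tiles) <- c(gr, gc)
  for (k in seq_along(files)) {
    m <- read_micrograph_tiff(file.path(dir, files[k]), pixel_size_nm,
                              bit_depth, channel)
    tiles[[rr[k], cc[k]]] <- m$pixels
  }
  shapes <- unique(t(vapply(tiles, dim, integer(2))))
  if (nrow(shapes) != 1) stop("tiles do not share a common shape")
  structure(list(tiles = tiles, tile_shape_px = as.integer(shapes[1, ]),
                 grid_dim = c(gr, gc), pixel_size_nm = pixel_size_nm,
                 bit_depth = as.integer(bit_depth), channel = channel),
            class = "tile_grid")
}
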