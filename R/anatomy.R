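#' Region mask objects
#'
#' A binary 2-D mask with a pixel calibration, e.g. a thresholded Nissl image
#' of a cerebellar nucleus.
#'
#' @param mask logical or 0/1 matrix (nonzero = foreground).
#' @param pixel_um pixel side length, micrometres per pixel.
#' @param label region label (e.g. `"fastigial"`, `"interposed"`).
#' @return a `region_mask` object.
#' @export
region_mask <- function(mask, pixel_um, label = "other") {
  mask <- as.matrix(mask)
  if (!length(mask)) stop_invalid("mask must be nonempty")
  if (pixel_um <= 0) stop_invalid("pixel_um must be positive")
  structure(list(mask = mask != 0, pixel_um = pixel_um, label = label),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %s: %dx%d px @ %g um/px, %d foreground px\n",
              x$label, nrow(x$mask), ncol(x$mask), x$pixel_um, sum(x$mask)))
  invisible(x)
}

# 8-connected component labelling by iterative breadth-first flood fill
# (ImageJ particle-analysis convention)
label_components8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  todo <- which(m & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- ((i - 1L) %% nr) + 1L; cc <- ((i - 1L) %/% nr) + 1L
      nb_r <- r + off_r; nb_c <- cc + off_c
      okn <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      nb <- (nb_c[okn] - 1L) * nr + nb_r[okn]
      nb <- nb[m[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

#' Count particles in a binary mask
#'
#' Number of 8-connected foreground components of at least `min_size_px`
#' pixels, as counted by ImageJ-style particle analysis of a thresholded
#' image.
#'
#' @param mask a [region_mask()] or binary matrix.
#' @param min_size_px minimum component size in pixels.
#' @return integer particle count.
#' @export
count_particles <- function(mask, min_size_px = 1) {
  m <- if (inherits(mask, "region_mask")) mask$mask else as.matrix(mask) != 0
  if (!any(m)) return(0L)
  lab <- label_components8(m)
  sizes <- tabulate(lab[lab > 0L])
  sum(sizes >= min_size_px)
}

#' Nuclear density per 50 micrometre unit
#'
#' Divides a particle count by the number of 50-um units in a caller-supplied
#' reference extent: `count / (reference_extent_um / 50)`. The reference
#' extent is left to the caller because the normalisation of a count "per
#' 50 um" is meaningful for either a length or an area unit.
#'
#' @param count particle count.
#' @param reference_extent_um reference extent in micrometres (> 0).
#' @return density per 50-um unit.
#' @examples
#' nuclear_density(10, 100)  # 5 per 50 um
#' @export
nuclear_density <- function(count, reference_extent_um) {
  if (reference_extent_um <= 0) stop_invalid("reference extent must be positive")
  count / (reference_extent_um / 50)
}

#' Area of a region mask
#'
#' Foreground pixel count times the squared pixel size.
#'
#' @param mask a [region_mask()].
#' @return area in square micrometres.
#' @export
region_area <- function(mask) {
  stopifnot(inherits(mask, "region_mask"))
  sum(mask$mask) * mask$pixel_um^2
}

#' Summarise a region mask
#'
#' @param mask a [region_mask()].
#' @param min_size_px minimum particle size, px.
#' @param reference_extent_um reference extent for the per-50-um density.
#' @return one-row data frame: label, area_um2, particle_count,
#'   density_per_50um.
#' @export
measure_region <- function(mask, min_size_px = 1, reference_extent_um = 50) {
  cnt <- count_particles(mask, min_size_px)
  data.frame(label = mask$label,
             area_um2 = region_area(mask),
             particle_count = cnt,
             density_per_50um = nuclear_density(cnt, reference_extent_um))
}

#' Generate a synthetic mask of non-overlapping disks
#'
#' Testing utility: places `n_disks` disks of the given radius uniformly at
#' random without overlap (rejection sampling), providing a mask whose true
#' particle count is known.
#'
#' @param n_disks number of disks.
#' @param radius_px disk radius, pixels.
#' @param dim_px length-2 mask dimensions, pixels.
#' @param pixel_um pixel size, um/px.
#' @param seed optional seed.
#' @return a [region_mask()] with attribute `centers` (n x 2 matrix).
#' @export
gen_disk_mask <- function(n_disks, radius_px = 4, dim_px = c(128, 128),
                          pixel_um = 1, seed = NULL) {
  with_seed(seed, {
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(centers) < n_disks && tries < 20000) {
      tries <- tries + 1
      cand <- c(runif(1, radius_px + 1, dim_px[1] - radius_px),
                runif(1, radius_px + 1, dim_px[2] - radius_px))
      if (!nrow(centers) ||
          all(sqrt(rowSums(sweep(centers, 2, cand)^2)) > 2 * radius_px + 2))
        centers <- rbind(centers, cand)
    }
    if (nrow(centers) < n_disks)
      stop_invalid("could not place ", n_disks, " non-overlapping disks")
    m <- matrix(FALSE, dim_px[1], dim_px[2])
    rr <- row(m); cc <- col(m)
    for (i in seq_len(n_disks))
      m <- m | ((rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radius_px^2)
    out <- region_mask(m, pixel_um, "synthetic")
    attr(out, "centers") <- centers
    out
  })
}

#' Read a binary mask image with its JSON sidecar
#'
#' Reads a PNG or TIFF image (any nonzero/over-half-intensity pixel is
#' foreground) plus a JSON sidecar holding `pixel_um` and `label`.
#'
#' @param path image path (`.png` or `.tif`/`.tiff`).
#' @param sidecar path to the JSON sidecar; defaults to `<path>.json`.
#' @return a [region_mask()].
#' @export
read_mask <- function(path, sidecar = paste0(path, ".json")) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop_invalid("png package required")
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop_invalid("tiff package required")
    tiff::readTIFF(path)
  } else stop_invalid("unsupported mask format: ", ext)
  if (length(dim(img)) == 3) img <- img[, , 1]
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar)
          else list(pixel_um = 1, label = "other")
  region_mask(img > 0.5, meta$pixel_um %||% 1, meta$label %||% "other")
}
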