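# Labelled-cell spatial statistics and the rotation-null colocalization test.

#' Sector asymmetry index from a rotating window
#'
#' Sweeps a `sector`-degree window (default a quadrant) around a centre in
#' `step`-degree increments, within a given radius, and compares the densest
#' placement against the placement 180 degrees opposite:
#' `index = (I_max - I_opposite) / (I_max + I_opposite)`, in `[0, 1]`. Input
#' is either a set of points (counts) or a 2-D intensity image (intensity
#' sums). Used for dendritic-field asymmetry of labelled neurons.
#'
#' @param x either a 2-column matrix/data.frame of point coordinates, or a
#'   numeric matrix of intensities (pixel `[i, j]` at coordinates `(j, i)`).
#' @param centre length-2 centre (x, y), same units as `x`.
#' @param radius analysis radius (distance to the most distal structure).
#' @param sector window width, deg.
#' @param step sweep step, deg.
#' @return list with `index`, `i_max`, `i_opposite`, `max_sector_angle`
#'   (deg, start angle of the densest placement, counter-clockwise from +x)
#'   and `flag` (`"empty"` when the disc holds no intensity).
#' @export
sector_asymmetry <- function(x, centre, radius, sector = 90, step = 1) {
  stopifnot(radius > 0, length(centre) == 2)
  if (is.matrix(x) && ncol(x) != 2) {
    # intensity image: pixel centres at integer coordinates
    coords <- expand.grid(px = seq_len(ncol(x)), py = seq_len(nrow(x)))
    wx <- coords$px; wy <- coords$py
    wt <- as.vector(t(x))
  } else {
    x <- as.matrix(x)
    wx <- x[, 1]; wy <- x[, 2]
    wt <- rep(1, length(wx))
  }
  dx <- wx - centre[1]; dy <- wy - centre[2]
  keep <- dx^2 + dy^2 <= radius^2 & wt > 0
  if (!any(keep)) {
    return(list(index = NA_real_, i_max = 0, i_opposite = 0,
                max_sector_angle = NA_real_, flag = "empty"))
  }
  ang <- (atan2(dy[keep], dx[keep]) * 180 / pi) %% 360
  wt <- wt[keep]
  starts <- seq(0, 360 - step, by = step)
  intens <- vapply(starts, function(a) {
    rel <- (ang - a) %% 360
    sum(wt[rel < sector])
  }, 0)
  imax <- which.max(intens)
  opp <- ((starts[imax] + 180) %% 360)
  iopp <- intens[match(opp, starts)]
  list(index = (intens[imax] - iopp) / (intens[imax] + iopp),
       i_max = intens[imax], i_opposite = iopp,
       max_sector_angle = starts[imax], flag = NA_character_)
}

#' Quadrant distribution of labelled retinal cells
#'
#' Counts labelled cells per anatomical quadrant around the optic disc and
#' finds the densest rotating window covering 25% of the retinal area (a
#' 90-degree sector of the retinal disk, clipped to the retina footprint).
#' Quadrant boundaries sit `boundary_offset` degrees from the dorsal axis;
#' the default (0) puts them on the anatomical axes so quadrants are the
#' corner sectors (dorsonasal, ventronasal, ventrotemporal, dorsotemporal),
#' counter-clockwise from dorsal with nasal at +90 degrees. Boundary points
#' are assigned half-open (inclusive lower angle).
#'
#' @param points 2-column matrix/data.frame of cell coordinates, mm.
#' @param disc_centre optic disc (x, y), mm.
#' @param dorsal_angle angle of the dorsal axis, deg counter-clockwise from
#'   +x.
#' @param retina_area retina area, mm^2 (the retina is treated as the disk of
#'   this area centred on the optic disc; `NULL` uses the smallest disk
#'   containing all points).
#' @param window_fraction area fraction of the rotating window.
#' @param step sweep step, deg.
#' @param quadrant_names names counter-clockwise starting at the quadrant
#'   whose lower boundary is the dorsal axis.
#' @return list with `counts`, `percentages` (named, summing to 100),
#'   `densest_window_angle` (deg from the dorsal axis, lower edge) and
#'   `densest_window_count`.
#' @export
quadrant_distribution <- function(points, disc_centre, dorsal_angle = 90,
                                  retina_area = NULL, window_fraction = 0.25,
                                  step = 1, boundary_offset = 0,
                                  quadrant_names = c("dorsonasal",
                                                     "ventronasal",
                                                     "ventrotemporal",
                                                     "dorsotemporal")) {
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("no labelled points")
  dx <- points[, 1] - disc_centre[1]
  dy <- points[, 2] - disc_centre[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- ((atan2(dy, dx) * 180 / pi) - dorsal_angle - boundary_offset) %% 360
  quad <- floor(ang / 90) + 1L                  # half-open lower boundary
  counts <- tabulate(quad, nbins = 4)
  names(counts) <- quadrant_names
  pct <- 100 * counts / sum(counts)
  radius <- if (is.null(retina_area)) max(r) else sqrt(retina_area / pi)
  sector <- 360 * window_fraction
  inside <- r <= radius
  starts <- seq(0, 360 - step, by = step)
  win <- vapply(starts, function(a)
    sum(inside & ((ang - a) %% 360) < sector), 0L)
  imax <- which.max(win)
  list(counts = counts, percentages = pct,
       densest_window_angle = starts[imax] + boundary_offset,
       densest_window_count = win[imax])
}

#' Two-channel image stack container
#'
#' @param label,marker aligned 3-D intensity arrays (x, y, z index order is
#'   row, column, slice).
#' @param voxel_size (x, y, z) voxel size, um.
#' @param channel_names labels for the two channels.
#' @return object of class `two_channel_stack`.
#' @export
two_channel_stack <- function(label, marker, voxel_size,
                              channel_names = c("label", "marker")) {
  stopifnot(length(dim(label)) == 3, all(dim(label) == dim(marker)),
            length(voxel_size) == 3, all(voxel_size > 0))
  structure(list(label = label, marker = marker, voxel_size = voxel_size,
                 channel_names = channel_names),
            class = "two_channel_stack")
}

#' Read a two-channel stack from multi-page TIFFs
#'
#' @param label_path,marker_path multi-page TIFF files, one per channel.
#' @param voxel_size (x, y, z) voxel size, um.
#' @return a [two_channel_stack()].
#' @export
read_two_channel_tiff <- function(label_path, marker_path, voxel_size) {
  as_arr <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3)
      p[, , 1] else p)
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  }
  two_channel_stack(as_arr(label_path), as_arr(marker_path), voxel_size)
}

# Per-channel voxel positivity threshold: Otsu on the intensity histogram
# (EBImage), after scaling intensities into [0, 1]; or a fixed value on the
# original intensity scale.
positivity_mask <- function(arr, threshold = NULL) {
  if (!is.null(threshold)) return(arr > threshold)
  mx <- max(arr)
  if (mx <= 0) return(array(FALSE, dim(arr)))
  thr <- EBImage::otsu(arr / mx, range = c(0, 1))
  arr / mx > thr
}

#' Colocalization test with a 90-degree rotation null
#'
#' Divides an aligned two-channel stack into subfields (default 70 x 70 um in
#' xy by 40 um depth), selects the `n_subfields` subfields with the highest
#' proportion of label-positive voxels, and computes, for each, the fraction
#' of label-positive voxels that are marker-positive before and after
#' rotating that subfield's marker channel by 90 degrees in-plane (per
#' z-slice; subfields are square in xy so the rotation is lossless).
#' Colocalization beyond chance is assessed by a paired two-tailed t-test of
#' the original vs rotated fractions across subfields.
#'
#' @param stack a [two_channel_stack()].
#' @param subfield_um (x, y, z) subfield size, um. x and y must map to the
#'   same number of voxels.
#' @param n_subfields number of subfields analysed.
#' @param threshold fixed positivity threshold (original intensity scale), or
#'   `NULL` for per-channel Otsu.
#' @return object of class `coloc_result`: list with `subfields` (data.frame:
#'   original and rotated fraction per subfield), `mean_original`,
#'   `mean_rotated`, `ratio_vs_chance`, `p` (NA with fewer than 3 usable
#'   subfields) and `flag`.
#' @export
colocalization_test <- function(stack, subfield_um = c(70, 70, 40),
                                n_subfields = 10, threshold = NULL) {
  stopifnot(inherits(stack, "two_channel_stack"))
  vs <- stack$voxel_size
  nx <- round(subfield_um[1] / vs[1])
  ny <- round(subfield_um[2] / vs[2])
  nz <- max(1L, round(subfield_um[3] / vs[3]))
  if (nx != ny) stop("subfield must be square in xy at this voxel size")
  dims <- dim(stack$label)
  tiles <- expand.grid(ix = seq_len(dims[1] %/% nx),
                       iy = seq_len(dims[2] %/% ny),
                       iz = seq_len(max(1L, dims[3] %/% nz)))
  if (nrow(tiles) < n_subfields) {
    warning("stack only accommodates ", nrow(tiles), " subfields")
    flag_small <- TRUE
  } else flag_small <- FALSE
  lab_pos <- positivity_mask(stack$label, threshold)
  mrk_pos <- positivity_mask(stack$marker, threshold)
  tile_idx <- function(t) {
    list(x = ((t$ix - 1) * nx + 1):(t$ix * nx),
         y = ((t$iy - 1) * ny + 1):(t$iy * ny),
         z = ((t$iz - 1) * nz + 1):min(dims[3], t$iz * nz))
  }
  lab_frac <- vapply(seq_len(nrow(tiles)), function(i) {
    ii <- tile_idx(tiles[i, ])
    mean(lab_pos[ii$x, ii$y, ii$z])
  }, 0)
  sel <- order(-lab_frac)[seq_len(min(n_subfields, nrow(tiles)))]
  rows <- lapply(sel, function(i) {
    ii <- tile_idx(tiles[i, ])
    L <- lab_pos[ii$x, ii$y, ii$z, drop = FALSE]
    M <- mrk_pos[ii$x, ii$y, ii$z, drop = FALSE]
    nL <- sum(L)
    if (nL == 0) return(NULL)                 # excluded with warning below
    Mrot <- M
    for (z in seq_len(dim(M)[3])) Mrot[, , z] <- rot90_mat(M[, , z])
    data.frame(label_fraction = mean(L),
               original = sum(L & M) / nL,
               rotated = sum(L & Mrot) / nL)
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0) {
    warning(dropped, " subfield(s) with no label-positive voxels excluded")
  }
  sub <- do.call(rbind, rows)
  flag <- if (flag_small) "stack_too_small" else NA_character_
  if (is.null(sub) || nrow(sub) < 3) {
    return(structure(list(subfields = sub, mean_original = NA_real_,
                          mean_rotated = NA_real_,
                          ratio_vs_chance = NA_real_, p = NA_real_,
                          flag = flag %||% "too_few_subfields"),
                     class = "coloc_result"))
  }
  p <- safe_t_p(sub$original - sub$rotated)
  structure(list(subfields = sub, mean_original = mean(sub$original),
                 mean_rotated = mean(sub$rotated),
                 ratio_vs_chance = if (mean(sub$rotated) > 0)
                   mean(sub$original) / mean(sub$rotated) else NA_real_,
                 p = p, flag = flag),
            class = "coloc_result")
}

#' Labelled-cell density per named region
#'
#' Count-in-polygon divided by polygon area, per section, then averaged
#' across sections. Points on a boundary are assigned by the half-open
#' even-odd rule (left/lower boundaries inside), so a point on a boundary
#' shared by two adjacent regions is counted exactly once.
#'
#' @param points data.frame with `x_mm`, `y_mm` and optionally `section`.
#' @param regions named list of polygons (data.frames with `x_mm`, `y_mm`).
#' @return data.frame with `region`, `density` (cells/mm^2, mean across
#'   sections), `n_sections`, `total_count`, `area_mm2`.
#' @export
label_density <- function(points, regions) {
  stopifnot(all(c("x_mm", "y_mm") %in% names(points)))
  if (is.null(points$section)) points$section <- 1L
  out <- lapply(names(regions), function(nm) {
    poly <- regions[[nm]]
    a <- polygon_area(poly[, c("x_mm", "y_mm")])
    if (a <= 0) stop("zero-area polygon: ", nm)
    dens <- vapply(split(points, points$section), function(sec) {
      sum(point_in_polygon(sec$x_mm, sec$y_mm,
                           poly[, c("x_mm", "y_mm")])) / a
    }, 0)
    cnt <- sum(point_in_polygon(points$x_mm, points$y_mm,
                                poly[, c("x_mm", "y_mm")]))
    data.frame(region = nm, density = mean(dens), n_sections = length(dens),
               total_count = cnt, area_mm2 = a)
  })
  do.call(rbind, out)
}
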