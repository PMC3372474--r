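#' Idealised coral shape
#'
#' Massive and branching corals are idealised as the two ends of the coral
#' shape spectrum: a hemisphere sitting on the chamber floor and a vertical
#' cylinder (a single branch).  The living tissue forms a thin shell of
#' thickness `tissue_thickness` over the skeleton.
#'
#' @param kind `"hemisphere"` or `"cylinder"`.
#' @param radius Radius in metres (half the colony/branch diameter).
#' @param height Branch height in metres (cylinders only; ignored for
#'   hemispheres).
#' @param tissue_thickness Thickness of the living-tissue shell in metres.
#'   Defaults to 1 mm, within the few-millimetre layer coral tissue occupies
#'   over the skeleton.
#' @return An object of class `coral_shape`.
#' @examples
#' coral_shape("hemisphere", radius = 0.0175)
#' coral_shape("cylinder", radius = 0.003, height = 0.006)
#' @export
coral_shape <- function(kind = c("hemisphere", "cylinder"),
                        radius,
                        height = NULL,
                        tissue_thickness = 0.001) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius))
  if (radius <= 0) stop("coral radius must be > 0")
  if (kind == "cylinder") {
    if (is.null(height) || !is.finite(height) || height <= 0)
      stop("cylinder corals need height > 0")
  } else {
    height <- radius  # a hemisphere is as tall as its radius
  }
  if (tissue_thickness <= 0 || tissue_thickness >= radius)
    stop("tissue_thickness must lie in (0, radius)")
  structure(
    list(kind = kind, radius = radius, height = height,
         tissue_thickness = tissue_thickness),
    class = "coral_shape"
  )
}

#' @exportS3Method
print.coral_shape <- function(x, ...) {
  cat(sprintf("<coral_shape> %s, d = %.1f mm", x$kind, 2000 * x$radius))
  if (x$kind == "cylinder") cat(sprintf(", z = %.1f mm", 1000 * x$height))
  cat(sprintf(", tissue %.2f mm\n", 1000 * x$tissue_thickness))
  invisible(x)
}

#' Flow-chamber domain
#'
#' The validation flow chamber: 25 cm long, 5 cm wide, 10 cm high, with the
#' inlet at `x = 0`, the outlet at `x = length`, the (sand) floor at `z = 0`.
#'
#' @param length,width,height Interior dimensions in metres.
#' @return An object of class `chamber_domain`.
#' @export
chamber_domain <- function(length = 0.25, width = 0.05, height = 0.10) {
  stopifnot(length > 0, width > 0, height > 0)
  structure(list(length = length, width = width, height = height),
            class = "chamber_domain")
}

#' @exportS3Method
print.chamber_domain <- function(x, ...) {
  cat(sprintf("<chamber_domain> %.0f x %.0f x %.0f mm (L x W x H)\n",
              1000 * x$length, 1000 * x$width, 1000 * x$height))
  invisible(x)
}

#' Analytic coral surface area, volume and area-to-volume ratio
#'
#' For a hemisphere of radius r the surface area counts the curved cap plus
#' the basal disc, A = 2*pi*r^2 + pi*r^2, and V = (2/3)*pi*r^3, so the
#' area-to-volume ratio reduces to S = 4.5/r.  For a cylindrical branch of
#' radius r and height z, A = 2*pi*r*z + 2*pi*r^2 and V = pi*r^2*z, so
#' S = 2/r + 2/z.
#'
#' The ratio S = A/V controls how fast a coral acquires and sheds heat:
#' absorbed power scales with area while heat capacity scales with volume,
#' which is why branching corals equilibrate faster than massive ones.
#'
#' @param coral A [coral_shape()].
#' @return Area in m^2, volume in m^3, or their ratio in 1/m.
#' @examples
#' av_ratio(coral_shape("hemisphere", radius = 0.0175))  # 257 1/m
#' @export
surface_area <- function(coral) {
  stopifnot(inherits(coral, "coral_shape"))
  r <- coral$radius
  switch(coral$kind,
    hemisphere = 3 * pi * r^2,
    cylinder   = 2 * pi * r * coral$height + 2 * pi * r^2
  )
}

#' @rdname surface_area
#' @export
volume <- function(coral) {
  stopifnot(inherits(coral, "coral_shape"))
  r <- coral$radius
  switch(coral$kind,
    hemisphere = (2 / 3) * pi * r^3,
    cylinder   = pi * r^2 * coral$height
  )
}

#' @rdname surface_area
#' @export
av_ratio <- function(coral) {
  V <- volume(coral)
  if (V <= 0) stop("zero-volume coral has no A/V ratio")
  surface_area(coral) / V
}

#' Horizontally projected (irradiated) coral area
#'
#' Area presented to an overhead (90 degree) beam: pi*r^2 for both shapes.
#' @param coral A [coral_shape()].
#' @return Projected area in m^2.
#' @export
projected_area <- function(coral) {
  stopifnot(inherits(coral, "coral_shape"))
  pi * coral$radius^2
}

# Graded 1-D spacing: n cells on [0, L] with a uniformly fine window
# [win[1], win[2]] and geometric expansion (ratio <= `ratio`) towards the
# ends.  Returns the n+1 face positions.  The fine spacing is found by
# bisection so the total cell count matches n exactly.
grade_axis <- function(L, n, win, ratio = 1.2) {
  stopifnot(L > 0, n >= 2)
  win[1] <- max(0, win[1])
  win[2] <- min(L, win[2])
  wlen <- win[2] - win[1]
  if (wlen <= 0 || wlen >= L * 0.999) {
    return(seq(0, L, length.out = n + 1))
  }

  count_side <- function(dist, h) {
    # cells needed to cover `dist` growing geometrically from h
    if (dist <= 1e-12) return(0L)
    k <- 0L; s <- 0; size <- h
    while (s < dist) {
      size <- size * ratio
      s <- s + size
      k <- k + 1L
      if (k > 100000L) break
    }
    k
  }
  total_cells <- function(h) {
    ceiling(wlen / h) + count_side(win[1], h) + count_side(L - win[2], h)
  }

  lo <- wlen / n          # finest conceivable
  hi <- L                 # coarsest
  for (it in 1:200) {
    mid <- sqrt(lo * hi)
    if (total_cells(mid) > n) lo <- mid else hi <- mid
  }
  h <- hi
  n_win <- max(1L, ceiling(wlen / h))
  side_sizes <- function(dist, h) {
    k <- count_side(dist, h)
    if (k == 0L) return(numeric(0))
    s <- h * ratio^(seq_len(k))
    s * dist / sum(s)  # rescale to fit exactly
  }
  left  <- rev(side_sizes(win[1], h))
  right <- side_sizes(L - win[2], h)
  mid   <- rep(wlen / n_win, n_win)
  sizes <- c(left, mid, right)
  # pad or trim to exactly n cells by splitting/merging the largest end cells
  while (length(sizes) < n) {
    i <- which.max(sizes)
    sizes <- append(sizes[-i], rep(sizes[i] / 2, 2), after = i - 1L)
  }
  while (length(sizes) > n) {
    i <- if (length(left) > 0) 1L else length(sizes)
    sizes[i + 1L] <- sizes[i + 1L] + sizes[i]
    sizes <- sizes[-i]
  }
  faces <- c(0, cumsum(sizes))
  faces[length(faces)] <- L
  faces
}

#' Build a zone-tagged graded Cartesian mesh of the flow chamber
#'
#' Constructs a structured Cartesian grid of the chamber with geometric
#' grading that concentrates cells around the coral (expansion ratio
#' `grading_ratio` per cell away from it), and tags every cell as `fluid`,
#' `tissue` or `skeleton` by a stair-step rule: a cell belongs to the coral
#' if its centre lies inside the analytic shape; coral cells within
#' `tissue_thickness` of the surface, or adjacent to a fluid cell, form the
#' tissue shell.
#'
#' The coral stands on the floor, centred laterally, with its upstream edge
#' at `placement` of the chamber length.
#'
#' @param domain A [chamber_domain()].
#' @param coral A [coral_shape()], or `NULL` for an empty chamber.
#' @param resolution Integer triple `c(nx, ny, nz)` of cell counts.
#' @param grading_ratio Geometric expansion ratio away from the coral
#'   (default 1.2; 1 gives a uniform grid).
#' @param placement Fraction of the chamber length at which the upstream
#'   edge of the coral sits (default 0.4).
#' @param bl_pad Extra height of the uniformly fine vertical window above
#'   the coral, m (default 6 mm).  The thermal boundary layer over the
#'   lit surface is a few millimetres thick at chamber velocities and
#'   controls the simulated heat-transfer coefficient, so the fine
#'   region must extend through it.
#' @return An object of class `coral_mesh` with cell centres `x`, `y`, `z`,
#'   spacings `dx`, `dy`, `dz`, face positions `xf`, `yf`, `zf`, a 3-D
#'   integer `zone` array (0 fluid, 1 tissue, 2 skeleton) and the cell
#'   volume array `vol`.
#' @export
build_mesh <- function(domain, coral, resolution,
                       grading_ratio = 1.2, placement = 0.4,
                       bl_pad = 0.006) {
  stopifnot(inherits(domain, "chamber_domain"))
  resolution <- as.integer(resolution)
  stopifnot(length(resolution) == 3L, all(resolution >= 2L))
  nx <- resolution[1]; ny <- resolution[2]; nz <- resolution[3]

  if (is.null(coral)) {
    xf <- seq(0, domain$length, length.out = nx + 1)
    yf <- seq(0, domain$width,  length.out = ny + 1)
    zf <- seq(0, domain$height, length.out = nz + 1)
    centre <- c(NA_real_, NA_real_)
  } else {
    stopifnot(inherits(coral, "coral_shape"))
    r <- coral$radius
    xc <- placement * domain$length + r
    yc <- domain$width / 2
    if (xc + r > domain$length || 2 * r > domain$width + 1e-12 ||
        coral$height > domain$height)
      stop("coral does not fit inside the chamber domain")
    pad <- min(max(0.3 * r, 0.001), 0.003)
    xf <- grade_axis(domain$length, nx, c(xc - r - pad, xc + r + pad),
                     grading_ratio)
    yf <- grade_axis(domain$width, ny, c(yc - r - pad, yc + r + pad),
                     grading_ratio)
    zf <- grade_axis(domain$height, nz,
                     c(0, min(coral$height + max(pad, bl_pad),
                              0.9 * domain$height)),
                     grading_ratio)
    centre <- c(xc, yc)
  }

  x <- (xf[-1] + xf[-(nx + 1)]) / 2; dx <- diff(xf)
  y <- (yf[-1] + yf[-(ny + 1)]) / 2; dy <- diff(yf)
  z <- (zf[-1] + zf[-(nz + 1)]) / 2; dz <- diff(zf)

  zone <- array(0L, dim = c(nx, ny, nz))
  if (!is.null(coral)) {
    r <- coral$radius; tt <- coral$tissue_thickness
    xc <- centre[1]; yc <- centre[2]
    X <- array(x, c(nx, ny, nz))
    Y <- aperm(array(y, c(ny, nx, nz)), c(2, 1, 3))
    Z <- aperm(array(z, c(nz, nx, ny)), c(2, 3, 1))
    if (coral$kind == "hemisphere") {
      dist <- sqrt((X - xc)^2 + (Y - yc)^2 + Z^2)
      inside <- dist <= r
      sdist <- r - dist                     # depth below the curved surface
    } else {
      rad <- sqrt((X - xc)^2 + (Y - yc)^2)
      inside <- rad <= r & Z <= coral$height
      sdist <- pmin(r - rad, coral$height - Z)  # depth below side or top
    }
    # minimum cells across the diameter (checked on the fine window)
    ncross_x <- sum(abs(x - xc) <= r)
    ncross_y <- sum(abs(y - yc) <= r)
    if (min(ncross_x, ncross_y) < 8L)
      stop(sprintf(
        "resolution too coarse: only %d cells across the coral diameter (need >= 8)",
        min(ncross_x, ncross_y)))
    if (!any(inside))
      stop("resolution too coarse: no cell centre falls inside the coral")
    zone[inside] <- 2L
    zone[inside & sdist <= tt] <- 1L
    # ensure the tissue shell exists wherever coral borders fluid
    zone <- tag_interface_tissue(zone)
    if (!any(zone == 1L))
      stop("resolution too coarse to resolve the tissue shell")
  }

  vol <- outer(dx, dy %o% dz)
  structure(
    list(nx = nx, ny = ny, nz = nz,
         x = x, y = y, z = z, dx = dx, dy = dy, dz = dz,
         xf = xf, yf = yf, zf = zf,
         zone = zone, vol = vol,
         coral = coral, domain = domain, centre = centre),
    class = "coral_mesh"
  )
}

# Promote skeleton cells that touch fluid (6-neighbourhood) to tissue, so
# the tissue shell is at least one cell thick over the whole coral surface.
tag_interface_tissue <- function(zone) {
  d <- dim(zone)
  fluid <- zone == 0L
  touches <- array(FALSE, d)
  sh <- function(a, along, by) {
    # shift logical array, padding with FALSE
    out <- array(FALSE, dim(a))
    n <- dim(a)[along]
    if (by >= n) return(out)
    idx_src <- seq_len(n - by); idx_dst <- idx_src + by
    if (along == 1) { out[idx_dst, , ] <- a[idx_src, , ]; }
    if (along == 2) { out[, idx_dst, ] <- a[, idx_src, ]; }
    if (along == 3) { out[, , idx_dst] <- a[, , idx_src]; }
    out
  }
  shm <- function(a, along, by) {
    out <- array(FALSE, dim(a))
    n <- dim(a)[along]
    idx_src <- seq(1 + by, n); idx_dst <- idx_src - by
    if (along == 1) { out[idx_dst, , ] <- a[idx_src, , ]; }
    if (along == 2) { out[, idx_dst, ] <- a[, idx_src, ]; }
    if (along == 3) { out[, , idx_dst] <- a[, , idx_src]; }
    out
  }
  for (al in 1:3) {
    touches <- touches | sh(fluid, al, 1L) | shm(fluid, al, 1L)
  }
  zone[zone == 2L & touches] <- 1L
  zone
}

#' Zone cell counts and volumes of a mesh
#'
#' @param mesh A [build_mesh()] result.
#' @return Data frame with one row per zone: cell count and total volume.
#' @export
zone_summary <- function(mesh) {
  stopifnot(inherits(mesh, "coral_mesh"))
  zones <- c(fluid = 0L, tissue = 1L, skeleton = 2L)
  data.frame(
    zone = names(zones),
    cells = vapply(zones, function(zz) sum(mesh$zone == zz), integer(1)),
    volume = vapply(zones, function(zz) sum(mesh$vol[mesh$zone == zz]),
                    numeric(1)),
    row.names = NULL
  )
}

#' @exportS3Method
print.coral_mesh <- function(x, ...) {
  cat(sprintf("<coral_mesh> %d x %d x %d = %d cells\n",
              x$nx, x$ny, x$nz, x$nx * x$ny * x$nz))
  zs <- zone_summary(x)
  cat(sprintf("  %s: %d cells (%.3g m^3)\n", zs$zone, zs$cells, zs$volume),
      sep = "")
  invisible(x)
}
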