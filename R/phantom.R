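#' Phantom configuration
#'
#' Describes a 2D numerical model of the axillary region: a skin layer
#' (uniform or sinusoidal), optional subcutaneous adipose and muscle layers,
#' bean-shaped axillary lymph nodes (ALNs), tiled dielectric heterogeneity of
#' the healthy background, and an on-skin antenna array.
#'
#' Coordinates: lateral position `x` runs from 0 to `width`; depth `d`
#' increases downward with 0 at the nominal skin surface. An air margin of
#' `air_margin` mm sits above the skin so the antennas radiate from the
#' surface. Cell centers are at `(i - 1/2) * dx`.
#'
#' @param width domain width in mm (the 80-mm array plus 20-mm margins).
#' @param depth axillary region depth in mm (skin plus tissue).
#' @param dx grid step in mm.
#' @param air_margin air layer above the skin in mm.
#' @param skin_thickness skin layer thickness in mm.
#' @param skin_profile `"uniform"` or `"sinusoidal"`.
#' @param skin_amplitude,skin_period sinusoidal surface amplitude and period
#'   in mm (used only for the sinusoidal profile).
#' @param adipose_thickness subcutaneous adipose layer thickness in mm
#'   (0 disables the layer; 12 mm models a normal-weight adult).
#' @param muscle logical; include a muscle layer.
#' @param muscle_top,muscle_thickness muscle band top depth and thickness in
#'   mm, measured from the local skin surface.
#' @param alns list of ALNs, each a list with elements `depth` (center depth
#'   mm), `offset` (lateral offset from the domain center, mm), `long_axis`
#'   (mm), `orientation` (radians) and `status` (`"healthy"` or
#'   `"metastasized"`). Use [aln()] to build entries.
#' @param aln_ring thickness in mm of the outer ring of each ALN that gets
#'   the surface dielectric parameters (the interior gets the cross-section
#'   parameters).
#' @param het_amplitude heterogeneity amplitude as a fraction (0.05 = 5 %).
#' @param het_tile heterogeneity tile side in mm.
#' @param seed integer seed for the heterogeneity draw.
#' @param n_antennas number of antennas.
#' @param array_span lateral extent of the antenna array in mm.
#' @param antenna_placement `"surface"` (each antenna follows the local skin
#'   surface height) or `"planar"` (a rigid planar array touching the highest
#'   point of the skin, leaving air gaps over the troughs of a sinusoidal
#'   skin).
#' @return An object of class `phantom_config`.
#' @seealso [build_phantom()], [built_in_scenarios()]
#' @export
phantom_config <- function(width = 120, depth = 100, dx = 0.5,
                           air_margin = 5,
                           skin_thickness = 2,
                           skin_profile = c("uniform", "sinusoidal"),
                           skin_amplitude = 1, skin_period = 20,
                           adipose_thickness = 0,
                           muscle = FALSE, muscle_top = 37, muscle_thickness = 25,
                           alns = list(aln()),
                           aln_ring = 1,
                           het_amplitude = 0.05, het_tile = 4, seed = 1L,
                           n_antennas = 16, array_span = 80,
                           antenna_placement = c("surface", "planar")) {
  skin_profile <- match.arg(skin_profile)
  antenna_placement <- match.arg(antenna_placement)
  cfg <- list(width = width, depth = depth, dx = dx, air_margin = air_margin,
              skin_thickness = skin_thickness, skin_profile = skin_profile,
              skin_amplitude = skin_amplitude, skin_period = skin_period,
              adipose_thickness = adipose_thickness,
              muscle = muscle, muscle_top = muscle_top,
              muscle_thickness = muscle_thickness,
              alns = alns, aln_ring = aln_ring,
              het_amplitude = het_amplitude, het_tile = het_tile,
              seed = as.integer(seed),
              n_antennas = as.integer(n_antennas), array_span = array_span,
              antenna_placement = antenna_placement)
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

#' @rdname phantom_config
#' @param status,depth,offset,long_axis,orientation see `alns` above.
#' @export
aln <- function(depth = 20, offset = 0, long_axis = 12, orientation = 0,
                status = c("metastasized", "healthy")) {
  status <- match.arg(status)
  list(depth = depth, offset = offset, long_axis = long_axis,
       orientation = orientation, status = status)
}

validate_phantom_config <- function(cfg) {
  stopifnot(cfg$width > 0, cfg$depth > 0, cfg$dx > 0, cfg$air_margin > 0,
            cfg$skin_thickness > 0)
  if (cfg$adipose_thickness < 0) stop("adipose_thickness must be >= 0")
  if (cfg$muscle && (cfg$muscle_top <= 0 || cfg$muscle_thickness <= 0))
    stop("muscle layer thicknesses must be > 0")
  if (cfg$skin_profile == "sinusoidal") {
    stopifnot(cfg$skin_amplitude > 0, cfg$skin_period > 0)
    if (cfg$skin_amplitude > cfg$air_margin)
      stop("air_margin must cover the sinusoidal surface amplitude")
  }
  if (cfg$n_antennas < 2) stop("need at least 2 antennas")
  if (cfg$array_span > cfg$width) stop("array_span exceeds the domain width")
  if (cfg$het_amplitude < 0 || cfg$het_amplitude >= 1)
    stop("het_amplitude must be in [0, 1)")
  if (cfg$het_tile < cfg$dx) stop("het_tile must be >= dx")
  for (a in cfg$alns) {
    half <- a$long_axis / 2
    top <- a$depth - half
    if (top < cfg$skin_thickness + cfg$skin_amplitude *
          (cfg$skin_profile == "sinusoidal"))
      stop("ALN at depth ", a$depth, " mm reaches into the skin band")
    if (a$depth + half > cfg$depth)
      stop("ALN at depth ", a$depth, " mm extends below the domain")
    if (abs(a$offset) + half > cfg$width / 2)
      stop("ALN at lateral offset ", a$offset, " mm leaves the domain")
  }
  invisible(cfg)
}

# skin surface height eta(x) in mm (0 on average; negative = raised crest is
# still 'up', i.e. the surface sits at depth eta)
surface_height <- function(cfg, x) {
  if (cfg$skin_profile == "uniform") rep(0, length(x))
  else cfg$skin_amplitude * sin(2 * pi * (x - cfg$width / 2) / cfg$skin_period)
}

## ---- bean geometry -------------------------------------------------------

# Closed bean curve r(theta) = sin^3(theta) + cos^3(theta), theta in
# [-pi/4, 3*pi/4] (where r >= 0), sampled densely, scaled so the longest
# chord equals long_axis, rotated so that orientation = 0 puts the long axis
# along the lateral direction, and centered on its own centroid.
bean_polygon <- function(long_axis, orientation = 0, n = 720) {
  th <- seq(-pi / 4, 3 * pi / 4, length.out = n)
  r <- sin(th)^3 + cos(th)^3
  u <- r * cos(th)
  v <- r * sin(th)
  hull <- grDevices::chull(u, v)
  hu <- u[hull]; hv <- v[hull]
  dmat <- outer(hu, hu, "-")^2 + outer(hv, hv, "-")^2
  ij <- arrayInd(which.max(dmat), dim(dmat))
  chord <- sqrt(dmat[ij])
  ang <- atan2(hv[ij[1]] - hv[ij[2]], hu[ij[1]] - hu[ij[2]])
  s <- long_axis / chord
  rot <- orientation - ang
  cs <- cos(rot); sn <- sin(rot)
  px <- s * (u * cs - v * sn)
  py <- s * (u * sn + v * cs)
  # polygon centroid (shoelace)
  x2 <- c(px[-1], px[1]); y2 <- c(py[-1], py[1])
  cr <- px * y2 - x2 * py
  A <- sum(cr) / 2
  cx <- sum((px + x2) * cr) / (6 * A)
  cy <- sum((py + y2) * cr) / (6 * A)
  cbind(x = px - cx, d = py - cy)
}

# even-odd point-in-polygon, vectorized over query points
point_in_polygon <- function(qx, qy, px, py) {
  n <- length(px)
  inside <- logical(length(qx))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    cross <- ((yi > qy) != (yj > qy)) &
      (qx < (xj - xi) * (qy - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Rasterize a bean-shaped lymph node
#'
#' Produces a cell mask of the bean curve used to model ALNs, distinguishing
#' a 1-mm-wide outer ring (assigned the node's surface dielectric
#' parameters) from the interior (cross-section parameters).
#'
#' @param center numeric `c(x, d)`: lateral position and depth of the node
#'   center in mm. The mask centroid coincides with `center` to within `dx`.
#' @param long_axis longest chord of the bean in mm (> 2 dx).
#' @param orientation rotation in radians; 0 puts the long axis along the
#'   lateral direction.
#' @param dx cell size in mm.
#' @param dim optional `c(n_depth, n_lateral)` of an existing grid; if
#'   omitted a minimal grid covering the bean is used.
#' @param origin `c(x0, d0)`: mm coordinates of the grid corner (cell centers
#'   at `origin + (i - 1/2) dx`).
#' @param ring ring thickness in mm.
#' @return Integer matrix (rows = depth, cols = lateral): 0 outside, 1
#'   interior, 2 surface ring; attributes `origin` and `dx`.
#' @export
bean_mask <- function(center, long_axis, orientation = 0, dx = 0.5,
                      dim = NULL, origin = NULL, ring = 1) {
  if (long_axis <= 2 * dx)
    stop("long_axis must exceed 2*dx; the bean would be degenerate")
  poly <- bean_polygon(long_axis, orientation)
  px <- poly[, 1] + center[1]
  pd <- poly[, 2] + center[2]
  if (is.null(dim)) {
    pad <- 2 * dx
    origin <- c(floor((min(px) - pad) / dx) * dx,
                floor((min(pd) - pad) / dx) * dx)
    dim <- c(ceiling((max(pd) + pad - origin[2]) / dx),
             ceiling((max(px) + pad - origin[1]) / dx))
  }
  nd <- dim[1]; nl <- dim[2]
  m <- matrix(0L, nd, nl)
  # restrict the point-in-polygon test to the bounding box
  jr <- max(1, floor((min(px) - origin[1]) / dx)):min(nl, ceiling((max(px) - origin[1]) / dx) + 1)
  ir <- max(1, floor((min(pd) - origin[2]) / dx)):min(nd, ceiling((max(pd) - origin[2]) / dx) + 1)
  g <- expand.grid(i = ir, j = jr)
  qx <- origin[1] + (g$j - 0.5) * dx
  qd <- origin[2] + (g$i - 0.5) * dx
  inside <- point_in_polygon(qx, qd, px, pd)
  if (!any(inside)) stop("bean mask is empty; check center and grid")
  gi <- g$i[inside]; gj <- g$j[inside]
  qxi <- qx[inside]; qdi <- qd[inside]
  # distance to the (densely sampled) boundary decides ring membership
  dist2 <- rep(Inf, length(qxi))
  for (k in seq_along(px))
    dist2 <- pmin(dist2, (qxi - px[k])^2 + (qdi - pd[k])^2)
  code <- ifelse(sqrt(dist2) <= ring, 2L, 1L)
  # a 1-cell bean should still be distinguishable: keep at least one interior
  if (!any(code == 1L)) code[which.max(dist2)] <- 1L
  m[cbind(gi, gj)] <- code
  attr(m, "origin") <- origin
  attr(m, "dx") <- dx
  m
}

## ---- phantom construction ------------------------------------------------

TISSUE_CODES <- c(air = 0L, skin = 1L, adipose = 2L, muscle = 3L,
                  background_healthy = 4L,
                  healthy_aln_surface = 5L, healthy_aln_cross = 6L,
                  metastasized_aln_surface = 7L, metastasized_aln_cross = 8L)

#' Build a 2D axillary phantom
#'
#' Assembles the tissue-index grid and per-cell Debye parameter grids from a
#' [phantom_config()]: air above the skin, the skin band (uniform or
#' sinusoidal), optional subcutaneous adipose and muscle layers, the healthy
#' background, and bean-shaped ALNs whose outer ring and interior carry the
#' surface and cross-section dielectric values. Tiled heterogeneity is then
#' applied to the healthy background and the antenna array is placed on the
#' skin.
#'
#' @param config a [phantom_config()].
#' @param tissues a [tissue_library()].
#' @return An object of class `phantom`: tissue index matrix (rows = depth,
#'   cols = lateral), parameter matrices `eps_inf`, `delta_eps`, `sigma_s`,
#'   `tau`, grid metadata, antenna positions and ground-truth ALN masks.
#' @export
build_phantom <- function(config = phantom_config(), tissues = tissue_library()) {
  validate_phantom_config(config)
  dx <- config$dx
  nd <- round((config$air_margin + config$depth) / dx)
  nl <- round(config$width / dx)
  d0 <- -config$air_margin
  dep <- d0 + (seq_len(nd) - 0.5) * dx   # cell-center depths
  lat <- (seq_len(nl) - 0.5) * dx        # cell-center lateral positions
  eta <- surface_height(config, lat)

  tis <- matrix(TISSUE_CODES["air"], nd, nl)
  depm <- matrix(dep, nd, nl)
  etam <- matrix(eta, nd, nl, byrow = TRUE)
  rel <- depm - etam                      # depth below the local surface
  tis[rel >= 0] <- TISSUE_CODES["background_healthy"]
  tis[rel >= 0 & rel < config$skin_thickness] <- TISSUE_CODES["skin"]
  if (config$adipose_thickness > 0)
    tis[rel >= config$skin_thickness &
        rel < config$skin_thickness + config$adipose_thickness] <-
      TISSUE_CODES["adipose"]
  if (config$muscle)
    tis[rel >= config$muscle_top &
        rel < config$muscle_top + config$muscle_thickness &
        tis == TISSUE_CODES["background_healthy"]] <- TISSUE_CODES["muscle"]

  truth <- list()
  for (a in config$alns) {
    cx <- config$width / 2 + a$offset
    m <- bean_mask(c(cx, a$depth), a$long_axis, a$orientation, dx,
                   dim = c(nd, nl), origin = c(0, d0), ring = config$aln_ring)
    if (any(m > 0 & (tis == TISSUE_CODES["air"] | tis == TISSUE_CODES["skin"])))
      stop("ALN overlaps the skin band or the air region")
    for (t2 in truth)
      if (any(m > 0 & t2$mask)) stop("ALNs overlap each other")
    surf <- if (a$status == "healthy") "healthy_aln_surface" else "metastasized_aln_surface"
    crs  <- if (a$status == "healthy") "healthy_aln_cross"   else "metastasized_aln_cross"
    tis[m == 2L] <- TISSUE_CODES[surf]
    tis[m == 1L] <- TISSUE_CODES[crs]
    truth[[length(truth) + 1L]] <-
      list(center = c(x = cx, d = a$depth), mask = m > 0L,
           status = a$status, long_axis = a$long_axis)
  }

  par_of <- function(field) {
    v <- vapply(names(TISSUE_CODES), function(nm) {
      if (nm == "air") {
        if (field == "eps_inf") 1 else if (field == "tau") 13e-12 else 0
      } else tissues[[nm]][[field]]
    }, numeric(1))
    matrix(v[tis + 1L], nd, nl)
  }
  ph <- structure(list(
    tissue = tis, eps_inf = par_of("eps_inf"), delta_eps = par_of("delta_eps"),
    sigma_s = par_of("sigma_s"), tau = par_of("tau"),
    dx = dx, origin = c(x = 0, d = d0), depth = dep, lateral = lat,
    eta = eta, truth = truth, config = config, tissues = tissues,
    antennas = NULL), class = "phantom")

  if (config$het_amplitude > 0)
    ph <- apply_heterogeneity(ph, config$het_amplitude, config$het_tile,
                              config$seed)
  ph$antennas <- antenna_positions(config$n_antennas, config$array_span, ph,
                                   placement = config$antenna_placement)
  ph
}

#' Apply tiled dielectric heterogeneity
#'
#' Tiles the region below the skin into `tile`-by-`tile` mm squares and
#' multiplies `eps_inf`, `delta_eps` and `sigma_s` of the healthy background
#' cells in each tile by a single factor drawn uniformly from
#' `[1 - amplitude, 1 + amplitude]`. Skin, ALN, adipose-layer and muscle
#' cells are untouched, as is the relaxation time. Deterministic for a given
#' seed; the caller's RNG state is preserved.
#'
#' @param phantom a [build_phantom()] result.
#' @param amplitude heterogeneity fraction in `[0, 1)`.
#' @param tile tile side in mm (>= dx).
#' @param seed integer seed.
#' @return The phantom with scaled background parameters.
#' @export
apply_heterogeneity <- function(phantom, amplitude = 0.05, tile = 4, seed = 1L) {
  stopifnot(inherits(phantom, "phantom"))
  if (amplitude < 0 || amplitude >= 1) stop("amplitude must be in [0, 1)")
  if (tile < phantom$dx) stop("tile must be >= dx")
  if (amplitude == 0) return(phantom)
  nd <- nrow(phantom$tissue); nl <- ncol(phantom$tissue)
  ti <- pmax(0, floor(phantom$depth / tile))          # tiles start at depth 0
  tj <- floor(phantom$lateral / tile)
  tile_id <- outer(ti, tj, function(a, b) a * (max(tj) + 2) + b + 1)
  ids <- sort(unique(as.vector(tile_id)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  fac <- stats::runif(length(ids), 1 - amplitude, 1 + amplitude)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  fmap <- fac[match(as.vector(tile_id), ids)]
  fmat <- matrix(fmap, nd, nl)
  bg <- phantom$tissue == TISSUE_CODES["background_healthy"]
  for (f in c("eps_inf", "delta_eps", "sigma_s"))
    phantom[[f]][bg] <- phantom[[f]][bg] * fmat[bg]
  phantom
}

#' Antenna array positions on the skin
#'
#' Places `n` antennas laterally centered with adjacent spacing
#' `span / (n - 1)`. With `"surface"` placement each antenna sits on the
#' local skin surface; with `"planar"` a rigid array touches the highest
#' surface point and air gaps open over the troughs.
#'
#' @param n number of antennas (>= 2).
#' @param span array extent in mm (must fit the domain).
#' @param phantom a `phantom`.
#' @param placement `"surface"` or `"planar"`.
#' @return data.frame with mm coordinates `x`, `depth` and grid indices
#'   `i` (row of the air cell immediately above the surface) and `j`.
#' @export
antenna_positions <- function(n, span, phantom,
                              placement = c("surface", "planar")) {
  placement <- match.arg(placement)
  stopifnot(inherits(phantom, "phantom"))
  if (n < 2) stop("need n >= 2 antennas")
  cfg <- phantom$config
  if (span > cfg$width) stop("span exceeds the domain width")
  x <- cfg$width / 2 + seq(-span / 2, span / 2, length.out = n)
  eta_x <- if (cfg$skin_profile == "uniform") rep(0, n)
    else cfg$skin_amplitude * sin(2 * pi * (x - cfg$width / 2) / cfg$skin_period)
  depth <- if (placement == "surface") eta_x else rep(min(phantom$eta), n)
  dx <- phantom$dx
  j <- pmin(pmax(round(x / dx + 0.5), 1L), length(phantom$lateral))
  if (placement == "surface") {
    # deepest air cell in each antenna's column: immediately above the skin
    i <- vapply(j, function(jj) max(which(phantom$tissue[, jj] == 0L)), integer(1))
  } else {
    i <- rep(floor((min(phantom$eta) - phantom$origin[["d"]]) / dx), n)
  }
  i <- as.integer(pmin(pmax(i, 1L), length(phantom$depth)))
  data.frame(x = x, depth = depth, i = i, j = as.integer(j))
}

#' @export
print.phantom <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("axillary phantom: %g x %g mm at dx = %g mm (%d x %d cells)\n",
              cfg$width, cfg$depth, x$dx, nrow(x$tissue), ncol(x$tissue)))
  cat(sprintf("  skin: %s, %g mm; adipose: %g mm; muscle: %s\n",
              cfg$skin_profile, cfg$skin_thickness, cfg$adipose_thickness,
              if (cfg$muscle) sprintf("[%g, %g) mm", cfg$muscle_top,
                                      cfg$muscle_top + cfg$muscle_thickness)
              else "absent"))
  for (t in x$truth)
    cat(sprintf("  ALN (%s) at x = %.1f mm, depth = %.1f mm, long axis %g mm\n",
                t$status, t$center["x"], t$center["d"], t$long_axis))
  cat(sprintf("  %d antennas over %g mm (%s placement)\n",
              cfg$n_antennas, cfg$array_span, cfg$antenna_placement))
  invisible(x)
}
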