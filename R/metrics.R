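#' Ground truth for one target
#'
#' @param center `c(x, d)` mm center of the ALN.
#' @param mask logical matrix of the ALN cells on the phantom grid.
#' @param status `"healthy"` or `"metastasized"`.
#' @param long_axis longest axis in mm.
#' @param origin `c(x0, d0)` mm corner of the mask grid.
#' @param dx mask cell size in mm.
#' @return An object of class `target_truth`.
#' @export
target_truth <- function(center, mask, status = "metastasized",
                         long_axis = 12, origin = c(0, 0), dx = 0.5) {
  if (!any(mask)) stop("target mask is empty")
  structure(list(center = center, mask = mask, status = status,
                 long_axis = long_axis, origin = origin, dx = dx),
            class = "target_truth")
}

#' Ground-truth targets of a phantom
#'
#' Converts the phantom's ALN ground truth into [target_truth()] objects for
#' the metric functions.
#'
#' @param phantom a [build_phantom()] result.
#' @return List of `target_truth` objects, one per ALN.
#' @export
phantom_truths <- function(phantom) {
  lapply(phantom$truth, function(t)
    target_truth(t$center, t$mask, t$status, t$long_axis,
                 origin = c(phantom$origin[["x"]], phantom$origin[["d"]]),
                 dx = phantom$dx))
}

# logical matrix over the map pixels: within `margin` mm of any mask cell
target_region <- function(map, truth, margin = 2) {
  idx <- which(truth$mask, arr.ind = TRUE)
  mx <- truth$origin[1] + (idx[, 2] - 0.5) * truth$dx
  md <- truth$origin[2] + (idx[, 1] - 0.5) * truth$dx
  nd <- length(map$depth); nl <- length(map$lateral)
  reg <- matrix(FALSE, nd, nl)
  jr <- which(map$lateral >= min(mx) - margin & map$lateral <= max(mx) + margin)
  ir <- which(map$depth >= min(md) - margin & map$depth <= max(md) + margin)
  if (!length(jr) || !length(ir)) return(reg)
  for (j in jr) {
    dx2 <- (map$lateral[j] - mx)^2
    for (i in ir) {
      if (any(dx2 + (map$depth[i] - md)^2 <= margin^2)) reg[i, j] <- TRUE
    }
  }
  reg
}

ratio_db <- function(num, den) 10 * log10(num / den)

#' Signal-to-clutter ratio
#'
#' Ratio (dB) between the maximum energy inside the target region (the
#' ground-truth mask dilated by `margin`) and the maximum energy anywhere
#' else in the map. Regions of other targets can be excluded from the
#' clutter via `exclude`.
#'
#' @param map an `energy_map`.
#' @param truth a [target_truth()].
#' @param margin dilation margin in mm.
#' @param exclude optional list of other `target_truth` objects whose
#'   regions are excluded from the clutter.
#' @return SCR in dB.
#' @export
scr <- function(map, truth, margin = 2, exclude = list()) {
  reg <- target_region(map, truth, margin)
  if (!any(reg)) stop("target region is empty on this map")
  out <- !reg
  for (t2 in exclude) out <- out & !target_region(map, t2, margin)
  if (!any(out)) stop("no clutter region left outside the target(s)")
  ratio_db(max(map$energy[reg]), max(map$energy[out]))
}

#' Signal-to-mean ratio
#'
#' Ratio (dB) between the maximum energy inside the target region and the
#' mean energy of all other pixels.
#'
#' @inheritParams scr
#' @return SMR in dB; always >= the SCR of the same map.
#' @export
smr <- function(map, truth, margin = 2, exclude = list()) {
  reg <- target_region(map, truth, margin)
  if (!any(reg)) stop("target region is empty on this map")
  out <- !reg
  for (t2 in exclude) out <- out & !target_region(map, t2, margin)
  if (!any(out)) stop("no clutter region left outside the target(s)")
  ratio_db(max(map$energy[reg]), mean(map$energy[out]))
}

#' Max-to-max ratio between two targets
#'
#' Ratio (dB) of the peak response in the first target's region to the peak
#' response in the second target's region; used to contrast a metastasized
#' against a healthy node. Swapping the targets negates the value.
#'
#' @param map an `energy_map`.
#' @param truth_a,truth_b two disjoint [target_truth()] objects (numerator,
#'   denominator).
#' @param margin dilation margin in mm.
#' @return MMR in dB.
#' @export
mmr <- function(map, truth_a, truth_b, margin = 2) {
  ra <- target_region(map, truth_a, margin)
  rb <- target_region(map, truth_b, margin)
  if (!any(ra) || !any(rb)) stop("a target region is empty on this map")
  if (any(ra & rb)) stop("target regions overlap; MMR is undefined")
  ratio_db(max(map$energy[ra]), max(map$energy[rb]))
}

# half-maximum crossings along one profile, linear interpolation
half_width_1d <- function(vals, coords, ipk) {
  half <- vals[ipk] / 2
  right <- NA_real_
  if (ipk < length(vals)) for (i in (ipk + 1):length(vals)) {
    if (vals[i] <= half) {
      f <- (vals[i - 1] - half) / (vals[i - 1] - vals[i])
      right <- coords[i - 1] + f * (coords[i] - coords[i - 1])
      break
    }
  }
  left <- NA_real_
  if (ipk > 1) for (i in (ipk - 1):1) {
    if (vals[i] <= half) {
      f <- (vals[i + 1] - half) / (vals[i + 1] - vals[i])
      left <- coords[i + 1] + f * (coords[i] - coords[i + 1])
      break
    }
  }
  c(left = left, right = right)
}

#' Full width at half maximum of a detected response
#'
#' Full width of the half-maximum contour through the peak, computed as the
#' mean of the widths along the two grid axes through the peak; each width
#' is the distance between the two half-energy crossings found by linear
#' interpolation. If the energy never drops to half within the map along an
#' axis, the map-truncated width is used and a warning is raised.
#'
#' @param map an `energy_map`.
#' @param peak `c(x, d)` mm location of a local maximum (e.g. from
#'   [find_map_peaks()]).
#' @return FWHM in mm.
#' @export
fwhm <- function(map, peak) {
  j <- which.min(abs(map$lateral - peak[1]))
  i <- which.min(abs(map$depth - peak[2]))
  truncated <- FALSE
  width_of <- function(vals, coords, ipk) {
    w <- half_width_1d(vals, coords, ipk)
    if (any(is.na(w))) {
      truncated <<- TRUE
      if (is.na(w["left"])) w["left"] <- coords[1]
      if (is.na(w["right"])) w["right"] <- coords[length(coords)]
    }
    unname(w["right"] - w["left"])
  }
  wlat <- width_of(map$energy[i, ], map$lateral, j)
  wdep <- width_of(map$energy[, j], map$depth, i)
  if (truncated)
    warning("half level not crossed within the map; width truncated")
  (wlat + wdep) / 2
}

#' Localization error
#'
#' Euclidean distance (mm) between the highest-energy pixel of the search
#' region and the true target center. Invariant to scaling of the map.
#'
#' @param map an `energy_map`.
#' @param truth a [target_truth()].
#' @param search logical matrix over the map pixels restricting the peak
#'   search (`NULL`: whole map).
#' @return LE in mm (>= 0).
#' @export
localization_error <- function(map, truth, search = NULL) {
  e <- map$energy
  if (!is.null(search)) {
    if (!any(search)) stop("empty search region")
    e <- ifelse(search, e, -Inf)
  }
  ij <- arrayInd(which.max(e), dim(e))
  px <- map$lateral[ij[2]]; pd <- map$depth[ij[1]]
  sqrt((px - truth$center[1])^2 + (pd - truth$center[2])^2)
}

#' Find the strongest well-separated peaks
#'
#' Greedy selection of the `n` highest local maxima (8-neighborhood) subject
#' to a minimum mutual separation. If fewer maxima satisfy the separation,
#' the result is flagged.
#'
#' @param map an `energy_map`.
#' @param n number of peaks requested.
#' @param min_separation minimum mutual distance in mm.
#' @return data.frame with columns `x`, `d` (mm) and `energy`; attribute
#'   `incomplete` is TRUE when fewer than `n` peaks were found.
#' @export
find_map_peaks <- function(map, n = 1, min_separation = 5) {
  e <- map$energy
  nd <- nrow(e); nl <- ncol(e)
  pad <- matrix(-Inf, nd + 2, nl + 2)
  pad[2:(nd + 1), 2:(nl + 1)] <- e
  is_max <- matrix(TRUE, nd, nl)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (e >= pad[(2 + di):(nd + 1 + di), (2 + dj):(nl + 1 + dj)])
  }
  cand <- which(is_max, arr.ind = TRUE)
  ord <- order(e[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- matrix(0, 0, 2)
  vals <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    if (nrow(keep) >= n) break
    cx <- map$lateral[cand[k, 2]]; cd <- map$depth[cand[k, 1]]
    if (nrow(keep) == 0 ||
        all(sqrt((keep[, 1] - cx)^2 + (keep[, 2] - cd)^2) >= min_separation)) {
      keep <- rbind(keep, c(cx, cd))
      vals <- c(vals, e[cand[k, 1], cand[k, 2]])
    }
  }
  out <- data.frame(x = keep[, 1], d = keep[, 2], energy = vals)
  attr(out, "incomplete") <- nrow(out) < n
  out
}

#' Per-target detection report
#'
#' Computes the performance metrics of an energy map against the phantom's
#' ground truth: per target SCR, SMR, FWHM and LE (other targets' regions
#' are excluded from the clutter), and for two-target maps the max-to-max
#' ratio MMR (metastasized over healthy when the statuses differ, stronger
#' over weaker otherwise). Peaks are attributed to targets by nearest true
#' center.
#'
#' @param map an `energy_map`.
#' @param truths list of [target_truth()] (e.g. from a phantom).
#' @param margin region dilation margin in mm.
#' @return data.frame with one row per target: `target`, `status`,
#'   `peak_x`, `peak_d`, `scr_db`, `smr_db`, `mmr_db`, `fwhm_mm`, `le_mm`.
#' @export
detection_report <- function(map, truths, margin = 2) {
  n <- length(truths)
  if (n == 0) stop("no targets in truth")
  if (n == 1) {
    pk <- find_map_peaks(map, 1)
    assign_pk <- list(c(pk$x[1], pk$d[1]))
  } else {
    sepmin <- min(dist(t(vapply(truths, function(t) t$center, numeric(2))))) / 2
    pk <- find_map_peaks(map, n, min_separation = sepmin)
    assign_pk <- vector("list", n)
    if (nrow(pk) > 0) {
      centers <- vapply(truths, function(t) t$center, numeric(2))
      for (k in seq_len(nrow(pk))) {
        dists <- sqrt((centers[1, ] - pk$x[k])^2 + (centers[2, ] - pk$d[k])^2)
        tgt <- which.min(dists)
        if (is.null(assign_pk[[tgt]])) assign_pk[[tgt]] <- c(pk$x[k], pk$d[k])
      }
    }
  }
  rows <- lapply(seq_len(n), function(k) {
    t <- truths[[k]]
    others <- truths[-k]
    p <- assign_pk[[k]]
    le <- if (is.null(p)) NA_real_
      else sqrt((p[1] - t$center[1])^2 + (p[2] - t$center[2])^2)
    data.frame(target = k, status = t$status,
               peak_x = if (is.null(p)) NA_real_ else p[1],
               peak_d = if (is.null(p)) NA_real_ else p[2],
               scr_db = scr(map, t, margin, exclude = others),
               smr_db = smr(map, t, margin, exclude = others),
               mmr_db = NA_real_,
               fwhm_mm = if (is.null(p)) NA_real_ else fwhm(map, p),
               le_mm = le)
  })
  rep <- do.call(rbind, rows)
  if (n == 2) {
    st <- vapply(truths, function(t) t$status, character(1))
    ord <- if (any(st == "metastasized") && any(st == "healthy")) {
      c(which(st == "metastasized")[1], which(st == "healthy")[1])
    } else {
      ra <- max(map$energy[target_region(map, truths[[1]], margin)])
      rb <- max(map$energy[target_region(map, truths[[2]], margin)])
      if (ra >= rb) c(1, 2) else c(2, 1)
    }
    rep$mmr_db <- mmr(map, truths[[ord[1]]], truths[[ord[2]]], margin)
  }
  rep
}
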