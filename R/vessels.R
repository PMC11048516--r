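# Large-vessel / capillary separation, skeletonization, local diameters.

# Zhang-Suen topology-preserving thinning, fully vectorized over the image.
#' @noRd
.zhang_suen <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  shift <- function(p, dr, dc) p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- pad
      P2 <- shift(p, -1L, 0L); P3 <- shift(p, -1L, 1L); P4 <- shift(p, 0L, 1L)
      P5 <- shift(p, 1L, 1L);  P6 <- shift(p, 1L, 0L);  P7 <- shift(p, 1L, -1L)
      P8 <- shift(p, 0L, -1L); P9 <- shift(p, -1L, -1L)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      core <- pad[2:(nr + 1L), 2:(nc + 1L)] & B >= 2 & B <= 6 & A == 1
      if (sub == 1) {
        del <- core & !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        del <- core & !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(del)) {
        changed <- TRUE
        inner <- pad[2:(nr + 1L), 2:(nc + 1L)]
        inner[del] <- FALSE
        pad[2:(nr + 1L), 2:(nc + 1L)] <- inner
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1L), 2:(nc + 1L)]
}

# Pruned 8-adjacency of skeleton pixels: a diagonal link is dropped when an
# orthogonal common neighbor provides the same connection (otherwise every
# junction and staircase corner becomes a clique of spurious branch points).
#' @noRd
.skeleton_adjacency <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  idx <- which(skel)
  ord <- integer(nr * nc); ord[idx] <- seq_along(idx)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  offs <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  at <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- logical(length(r))
    v[ok] <- skel[(c[ok] - 1L) * nr + r[ok]]
    v
  }
  nbr <- vector("list", length(idx))
  for (k in seq_len(8)) {
    dr <- offs[k, 1]; dc <- offs[k, 2]
    rr <- rows + dr; cc <- cols + dc
    hit <- at(rr, cc)
    if (dr != 0 && dc != 0) {
      hit <- hit & !(at(rows + dr, cols) | at(rows, cols + dc))
    }
    w <- which(hit)
    for (i in w) nbr[[i]] <- c(nbr[[i]], ord[(cc[i] - 1L) * nr + rr[i]])
  }
  list(nbr = nbr, rows = rows, cols = cols, idx = idx)
}

# Trace skeleton polylines between branch/end points; leftover pure cycles
# are emitted as closed polylines.
#' @noRd
.trace_segments <- function(skel) {
  if (!any(skel)) return(list())
  adj <- .skeleton_adjacency(skel)
  nbr <- adj$nbr; rows <- adj$rows; cols <- adj$cols
  idx <- adj$idx
  deg <- lengths(nbr)
  is_node <- deg != 2L
  edge_used <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  segs <- list()
  walk <- function(from, to) {
    # walk from node `from` into neighbor `to` until the next node
    path <- c(from, to)
    prev <- from; cur <- to
    while (!is_node[cur]) {
      nxt <- setdiff(nbr[[cur]], prev)
      if (length(nxt) == 0) break          # isolated loop end (shouldn't occur)
      if (length(nxt) > 1) nxt <- nxt[1]
      assign(ekey(cur, nxt), TRUE, envir = edge_used)
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
      if (cur == from && length(path) > 2) break  # cycle through a node
    }
    path
  }
  for (v in which(is_node)) {
    for (u in nbr[[v]]) {
      k <- ekey(v, u)
      if (!is.null(edge_used[[k]])) next
      assign(k, TRUE, envir = edge_used)
      segs[[length(segs) + 1L]] <- walk(v, u)
    }
  }
  # pure cycles: remaining degree-2 pixels with no incident traversed edge
  visited <- logical(length(idx))
  for (s in segs) visited[s] <- TRUE
  for (v in which(!visited & deg == 2L)) {
    if (visited[v]) next
    path <- c(v)
    prev <- v; cur <- nbr[[v]][1]
    assign(ekey(prev, cur), TRUE, envir = edge_used)
    while (cur != v) {
      visited[cur] <- TRUE
      path <- c(path, cur)
      nxt <- setdiff(nbr[[cur]], prev)
      if (length(nxt) == 0) break
      nxt <- nxt[1]
      prev <- cur; cur <- nxt
    }
    visited[v] <- TRUE
    path <- c(path, v)  # close the loop
    segs[[length(segs) + 1L]] <- path
  }
  lapply(segs, function(s) cbind(row = rows[s], col = cols[s]))
}

#' Skeletonize a vessel mask
#'
#' Topology-preserving medial-axis thinning (Zhang-Suen) followed by tracing
#' of centerline polylines between branch/end points (pixels of skeleton
#' degree != 2); pure cycles (e.g. an annulus) become closed polylines.
#' If `binary` is supplied, per-skeleton-pixel local vessel diameters are
#' attached via [local_diameter()].
#'
#' @param mask logical matrix, or a [binary_vessel_map()].
#' @param binary optional [binary_vessel_map()] the skeleton derives from,
#'   used to attach local diameters (defaults to `mask` itself when `mask`
#'   is a `binary_vessel_map`).
#' @param pixel_size_mm pixel pitch, required when `mask` is a bare matrix
#'   and diameters are wanted.
#' @return object of class `skeleton_map`: `pixels` (logical matrix),
#'   `segments` (list of (row, col) polylines), `diameter_um` (numeric matrix,
#'   `NA` off the skeleton), `endpoints`/`branchpoints` counts.
#' @export
skeletonize_map <- function(mask, binary = NULL, pixel_size_mm = NULL) {
  if (inherits(mask, "binary_vessel_map")) {
    if (is.null(binary)) binary <- mask
    pixel_size_mm <- mask$pixel_size_mm
    mask <- mask$pixels
  }
  .assert(is.matrix(mask) && is.logical(mask), "mask must be logical")
  if (!any(mask)) {
    return(structure(list(pixels = mask, segments = list(),
                          diameter_um = matrix(NA_real_, nrow(mask), ncol(mask)),
                          endpoints = 0L, branchpoints = 0L,
                          pixel_size_mm = pixel_size_mm),
                     class = "skeleton_map"))
  }
  skel <- .zhang_suen(mask)
  segs <- .trace_segments(skel)
  deg <- lengths(.skeleton_adjacency(skel)$nbr)
  sk <- structure(list(pixels = skel, segments = segs,
                       diameter_um = matrix(NA_real_, nrow(mask), ncol(mask)),
                       endpoints = sum(deg == 1),
                       branchpoints = sum(deg >= 3),
                       pixel_size_mm = pixel_size_mm),
                  class = "skeleton_map")
  if (!is.null(binary)) sk <- local_diameter(binary, sk)
  sk
}

#' @export
print.skeleton_map <- function(x, ...) {
  cat(sprintf("<skeleton_map> %d px, %d segments, %d endpoints, %d branchpoints\n",
              sum(x$pixels), length(x$segments), x$endpoints, x$branchpoints))
  invisible(x)
}

#' Local vessel diameter along a skeleton
#'
#' Diameter at a skeleton pixel is estimated from the Euclidean distance
#' transform of the vessel mask: `d = (2 EDT - 1) * pixel pitch`, the width of
#' the maximal disc inscribed at the centerline (the half-pixel correction
#' accounts for distances being measured to background pixel centers; a
#' 1-pixel line gets diameter exactly one pixel).
#'
#' @param binary a [binary_vessel_map()] (or logical matrix).
#' @param skeleton a `skeleton_map` derived from `binary`.
#' @param pixel_size_mm required if `binary` is a bare matrix.
#' @return `skeleton` with `diameter_um` filled in at skeleton pixels.
#' @export
local_diameter <- function(binary, skeleton, pixel_size_mm = NULL) {
  if (inherits(binary, "binary_vessel_map")) {
    pixel_size_mm <- binary$pixel_size_mm
    binary <- binary$pixels
  }
  .assert(!is.null(pixel_size_mm), "pixel_size_mm required")
  .assert(all(binary[skeleton$pixels]),
          "skeleton pixel outside the vessel mask", "octacrmb_consistency_error")
  dt <- as.numeric(EBImage::distmap(EBImage::Image(binary * 1)))
  dt <- matrix(dt, nrow(binary), ncol(binary))
  dum <- matrix(NA_real_, nrow(binary), ncol(binary))
  sel <- skeleton$pixels
  dum[sel] <- pmax(2 * dt[sel] - 1, 1) * pixel_size_mm * 1000
  skeleton$diameter_um <- dum
  skeleton$pixel_size_mm <- pixel_size_mm
  skeleton
}

#' Separate retinal large vessels from capillaries
#'
#' Heuristic separation in the superficial plexus using signal intensity and
#' local caliber: seed pixels are vessel pixels whose locally smoothed
#' intensity reaches `intensity_threshold` and whose distance-transform
#' caliber reaches `diameter_threshold_um`; full vessel cross-sections are
#' then reconstructed as the union of the maximal inscribed discs of the seed
#' pixels, clipped to the vessel mask. Components smaller than
#' `min_component_px` are removed as speckle. The complement within the
#' vessel map is the superficial capillary mask.
#'
#' @param dvm the SCP [dvm_image()].
#' @param binary the [binary_vessel_map()] derived from `dvm`.
#' @param intensity_threshold absolute intensity cut on the (smoothed,
#'   normalized) DVM; default is the 0.8 quantile of vessel-pixel intensities.
#' @param diameter_threshold_um caliber cut; default 25 um, the conventional
#'   capillary/arteriole boundary.
#' @param min_component_px speckle-control component size (default 50).
#' @return object of class `large_vessel_mask`: `pixels`, `capillary_pixels`,
#'   thresholds used.
#' @export
delineate_large_vessels <- function(dvm, binary, intensity_threshold = NULL,
                                    diameter_threshold_um = 25,
                                    min_component_px = 50) {
  stopifnot(inherits(dvm, "dvm_image"), inherits(binary, "binary_vessel_map"))
  .assert(all(dim(dvm$pixels) == dim(binary$pixels)),
          "binary must derive from dvm")
  .assert(diameter_threshold_um >= 0, "diameter threshold must be >= 0",
          "octacrmb_config_error")
  px <- dvm$pixels
  rng <- range(px)
  if (diff(rng) > 0) px <- (px - rng[1]) / diff(rng)
  sm <- .box_mean(px, 3)
  if (is.null(intensity_threshold)) {
    intensity_threshold <- as.numeric(stats::quantile(sm[binary$pixels], 0.8))
  }
  .assert(intensity_threshold >= 0 && intensity_threshold <= 1,
          "intensity_threshold must be in [0, 1]", "octacrmb_config_error")
  dt <- matrix(as.numeric(EBImage::distmap(EBImage::Image(binary$pixels * 1))),
               nrow(binary$pixels), ncol(binary$pixels))
  dpx <- diameter_threshold_um / (binary$pixel_size_mm * 1000)
  seeds <- binary$pixels & (2 * dt - 1 >= dpx) & (sm >= intensity_threshold)
  if (!any(seeds)) {
    message("no structure above the diameter/intensity thresholds; empty large-vessel mask")
    lv <- matrix(FALSE, nrow(px), ncol(px))
  } else {
    w <- which(seeds)
    nr <- nrow(px)
    lv <- .stamp_discs(dim(px),
                       rows = ((w - 1L) %% nr) + 1L,
                       cols = ((w - 1L) %/% nr) + 1L,
                       radii = pmax(dt[w] - 0.5, 0))
    lv <- lv & binary$pixels
    if (min_component_px > 0 && any(lv)) {
      lab <- EBImage::bwlabel(lv)
      sz <- tabulate(lab[lab > 0])
      lv <- array(lab > 0 & sz[pmax(lab, 1)] >= min_component_px, dim = dim(lv))
    }
  }
  structure(list(pixels = lv,
                 capillary_pixels = binary$pixels & !lv,
                 intensity_threshold = intensity_threshold,
                 diameter_threshold_um = diameter_threshold_um,
                 min_component_px = min_component_px,
                 pixel_size_mm = binary$pixel_size_mm,
                 center_rc = binary$center_rc),
            class = "large_vessel_mask")
}

#' @export
print.large_vessel_mask <- function(x, ...) {
  cat(sprintf("<large_vessel_mask> %d px (%.3f of scan), thresholds: intensity %.3f, diameter %.1f um\n",
              sum(x$pixels), mean(x$pixels), x$intensity_threshold,
              x$diameter_threshold_um))
  invisible(x)
}

#' Export skeleton segments as JSON polylines
#' @param skeleton a `skeleton_map`.
#' @param path output JSON file.
#' @export
write_skeleton_json <- function(skeleton, path) {
  segs <- lapply(skeleton$segments, function(s) {
    list(row = s[, "row"], col = s[, "col"],
         diameter_um = skeleton$diameter_um[s])
  })
  jsonlite::write_json(segs, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
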