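# The twelve computational retinal microvascular biomarkers (CRMBs).

#' Perfusion density of a vascular compartment
#'
#' Mean pixel signal intensity of a compartment over an analysis region:
#' the sum of DVM intensities over `compartment & region` divided by the
#' pixel count of the region. With `binary_mode = TRUE` intensities are
#' replaced by the binary mask (area fraction instead of flow-weighted
#' density).
#'
#' @param dvm a [dvm_image()].
#' @param compartment_mask logical matrix (e.g. large vessels, capillaries).
#' @param region_mask logical matrix (e.g. the ETDRS parafovea).
#' @param binary_mode use mask membership instead of intensities.
#' @return scalar in \[0, 1\].
#' @export
perfusion_density <- function(dvm, compartment_mask, region_mask,
                              binary_mode = FALSE) {
  stopifnot(inherits(dvm, "dvm_image"))
  .assert(all(dim(compartment_mask) == dim(dvm$pixels)) &&
            all(dim(region_mask) == dim(dvm$pixels)),
          "masks must align to the DVM")
  n <- sum(region_mask)
  .assert(n > 0, "empty analysis region", "octacrmb_undefined_region")
  sel <- compartment_mask & region_mask
  if (binary_mode) sum(sel) / n else sum(dvm$pixels[sel]) / n
}

#' Box-counting fractal dimension
#'
#' Counts, for each box side `s`, the number `N(s)` of cells of an `s x s`
#' grid anchored at the image origin that contain at least one vessel pixel,
#' and returns the ordinary least-squares slope of `log N(s)` versus
#' `log(1/s)`. Default box sides are dyadic from 2 to a quarter of the
#' smaller image side.
#'
#' @param binary logical matrix or [binary_vessel_map()].
#' @param box_sizes integer vector of box sides (>= 4 values recommended).
#' @return scalar fractal dimension.
#' @export
box_counting_fd <- function(binary, box_sizes = NULL) {
  if (inherits(binary, "binary_vessel_map")) binary <- binary$pixels
  .assert(any(binary), "empty mask has no fractal dimension")
  n <- min(dim(binary))
  if (is.null(box_sizes)) {
    box_sizes <- 2^(1:floor(log2(n / 4)))
  }
  .assert(length(box_sizes) >= 2, "need at least 2 box sizes",
          "octacrmb_config_error")
  idx <- which(binary)
  nr <- nrow(binary)
  r <- ((idx - 1L) %% nr)
  c <- ((idx - 1L) %/% nr)
  counts <- vapply(box_sizes, function(s) {
    br <- r %/% s
    bc <- c %/% s
    length(unique(br * (ncol(binary) %/% s + 2L) + bc))
  }, numeric(1))
  .assert(length(unique(counts)) >= 2, "degenerate box-count sequence",
          "octacrmb_degenerate_fit")
  as.numeric(stats::coef(stats::lm(log(counts) ~ I(log(1 / box_sizes))))[2])
}

# Smooth a polyline by a centered moving average (window 5), endpoints kept.
#' @noRd
.smooth_polyline <- function(p) {
  m <- nrow(p)
  if (m < 5) return(p)
  s <- p
  for (i in 2:(m - 1)) {
    lo <- max(1, i - 2); hi <- min(m, i + 2)
    s[i, ] <- colMeans(p[lo:hi, , drop = FALSE])
  }
  s
}

#' @noRd
.polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  d <- diff(p)
  sum(sqrt(rowSums(d^2)))
}

# Split a polyline into maximal runs whose pixels fall inside region_mask.
#' @noRd
.clip_polyline <- function(p, region_mask) {
  inside <- region_mask[p]
  if (!any(inside)) return(list())
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(k) p[starts[k]:ends[k], , drop = FALSE])
}

#' Macular vessel tortuosity (MVT)
#'
#' Per centerline segment, tortuosity is the arc length over the straight
#' chord between its endpoints; segments are clipped to the analysis region
#' and only runs with chord >= `min_chord_px` pixels qualify. The arc length
#' is measured on a moving-average-smoothed polyline to suppress the
#' staircase overestimate of rasterized curves. MVT is the
#' arc-length-weighted mean over qualifying runs.
#'
#' @param skeleton a `skeleton_map`.
#' @param region_mask logical matrix; `NULL` = whole image.
#' @param min_chord_px minimum chord length (default 10).
#' @return scalar >= 1, or `NA_real_` when no run qualifies.
#' @export
vessel_tortuosity <- function(skeleton, region_mask = NULL, min_chord_px = 10) {
  stopifnot(inherits(skeleton, "skeleton_map"))
  if (is.null(region_mask)) {
    region_mask <- matrix(TRUE, nrow(skeleton$pixels), ncol(skeleton$pixels))
  }
  tor <- c(); wt <- c()
  for (seg in skeleton$segments) {
    for (run in .clip_polyline(seg, region_mask)) {
      chord <- sqrt(sum((run[nrow(run), ] - run[1, ])^2))
      if (chord < min_chord_px) next
      arc <- .polyline_length(.smooth_polyline(run))
      tor <- c(tor, max(arc / chord, 1))
      wt <- c(wt, arc)
    }
  }
  if (length(tor) == 0) return(NA_real_)
  sum(tor * wt) / sum(wt)
}

#' Macular vessel diameter (MVDiam)
#'
#' Mean of the local centerline diameters (see [local_diameter()]) over
#' skeleton pixels inside the analysis region.
#'
#' @param skeleton a `skeleton_map` with diameters attached.
#' @param region_mask logical matrix; `NULL` = whole image.
#' @return mean diameter in um, or `NA_real_` if the region holds no skeleton.
#' @export
mean_vessel_diameter <- function(skeleton, region_mask = NULL) {
  stopifnot(inherits(skeleton, "skeleton_map"))
  sel <- skeleton$pixels
  if (!is.null(region_mask)) sel <- sel & region_mask
  if (!any(sel)) return(NA_real_)
  mean(skeleton$diameter_um[sel], na.rm = TRUE)
}

#' Macular vessel dispersion (MVDisp)
#'
#' Degree of centripetalism of the vessels around the fovea. For each
#' skeleton pixel in the region, the local tangent direction is the first
#' principal component of the skeleton pixels within a square window of
#' half-width `radius_px` (computed in closed form from box-filtered first
#' and second coordinate moments); with theta the acute angle between that
#' tangent and the radial line to the fovea center, MVDisp is the mean of
#' `1 - |cos(theta)|`. Perfectly radial (centripetal) vasculature scores 0;
#' purely tangential (circumferential) vasculature approaches 1; an
#' isotropic orientation field scores `1 - 2/pi ~ 0.363`. Larger values mean
#' fewer centripetal parafoveal vessels.
#'
#' @param skeleton a `skeleton_map`.
#' @param center_rc fovea center (row, col).
#' @param region_mask logical matrix; `NULL` = whole image.
#' @param radius_px tangent-window half-width (default 5, an 11 x 11 window).
#' @param min_pixels minimum qualifying pixels, below which the metric is
#'   reported missing (default 20).
#' @return scalar in \[0, 1\] or `NA_real_`.
#' @export
vessel_dispersion <- function(skeleton, center_rc, region_mask = NULL,
                              radius_px = 5, min_pixels = 20) {
  stopifnot(inherits(skeleton, "skeleton_map"))
  sel <- skeleton$pixels
  if (!is.null(region_mask)) sel <- sel & region_mask
  if (sum(sel) < min_pixels) return(NA_real_)
  skel <- skeleton$pixels * 1
  nr <- nrow(skel); nc <- ncol(skel)
  w <- 2L * radius_px + 1L
  rcoord <- matrix(seq_len(nr), nr, nc)
  ccoord <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # windowed coordinate moments of skeleton pixels -> local PCA in closed form
  W <- .box_sum(skel, w)
  Sr <- .box_sum(skel * rcoord, w);  Sc <- .box_sum(skel * ccoord, w)
  Srr <- .box_sum(skel * rcoord^2, w)
  Scc <- .box_sum(skel * ccoord^2, w)
  Src <- .box_sum(skel * rcoord * ccoord, w)
  a <- Srr / W - (Sr / W)^2          # var(row)
  c_ <- Scc / W - (Sc / W)^2         # var(col)
  b <- Src / W - (Sr / W) * (Sc / W) # cov
  alpha <- 0.5 * atan2(2 * b, a - c_)  # principal (tangent) direction
  tr <- cos(alpha); tc <- sin(alpha)
  rad_r <- rcoord - center_rc[1]; rad_c <- ccoord - center_rc[2]
  nrm <- sqrt(rad_r^2 + rad_c^2)
  vals <- 1 - abs(tr * rad_r + tc * rad_c) / nrm
  ok <- sel & W >= 4 & nrm >= 1e-9
  if (sum(ok) < min_pixels) return(NA_real_)
  mean(vals[ok])
}

#' Demarcate the foveal avascular zone by ray casting
#'
#' From the fovea center, `n_rays` equally spaced rays are marched outward in
#' steps of `step_px` pixels; the first vessel-positive pixel met by each ray
#' (nearest-neighbor sampling of the binary map) becomes a polygon vertex.
#' Connecting the vertices in angular order yields the FAZ polygon, whose
#' area (shoelace), perimeter and acircularity
#' (perimeter over the perimeter of the equal-area circle) are returned.
#'
#' @details The radius at which each ray first meets a vessel is corrected by
#' half a marching step (the boundary lies between the last avascular and the
#' first vascular sample) and the per-ray radii are then smoothed with a
#' circular median filter followed by a circular moving average, each of
#' angular width `smooth_deg` degrees. The median suppresses isolated rays
#' that escape through small rim gaps; the average removes the pixelation
#' jitter that would otherwise inflate the polygon perimeter (and hence the
#' acircularity) of a rasterized boundary.
#'
#' @param binary a [binary_vessel_map()].
#' @param center_rc fovea center; defaults to the map's center.
#' @param n_rays number of rays (>= 36; default 360).
#' @param step_px marching step (default 0.5 px).
#' @param smooth_deg angular width of the radial smoothing filters, in
#'   degrees (default 7; 0 disables smoothing).
#' @return object of class `faz_polygon`: `vertices` (n_rays x 2, row/col,
#'   smoothed), `radii_px` (raw hit radii), `area_mm2`, `perimeter_mm`,
#'   `acircularity`, `open` (TRUE if any ray left the image without hitting
#'   a vessel).
#' @export
demarcate_faz <- function(binary, center_rc = NULL, n_rays = 360,
                          step_px = 0.5, smooth_deg = 7) {
  stopifnot(inherits(binary, "binary_vessel_map"))
  .assert(n_rays >= 36, "n_rays must be >= 36", "octacrmb_config_error")
  if (is.null(center_rc)) center_rc <- binary$center_rc
  nr <- nrow(binary$pixels); nc <- ncol(binary$pixels)
  .assert(center_rc[1] >= 1 && center_rc[1] <= nr &&
            center_rc[2] >= 1 && center_rc[2] <= nc,
          "center must lie inside the image")
  ang <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
  radii <- numeric(n_rays)
  hit <- logical(n_rays)
  tmax <- sqrt(nr^2 + nc^2)
  for (k in seq_len(n_rays)) {
    dr <- sin(ang[k]); dc <- cos(ang[k])
    t <- step_px
    while (t <= tmax) {
      r <- round(center_rc[1] + t * dr)
      c <- round(center_rc[2] + t * dc)
      if (r < 1 || r > nr || c < 1 || c > nc) break
      if (binary$pixels[r, c]) {
        hit[k] <- TRUE
        break
      }
      t <- t + step_px
    }
    radii[k] <- t
  }
  open_faz <- !all(hit)
  if (open_faz) warning("open FAZ: some rays reached the image border without a vessel hit")
  # boundary lies between the last avascular and first vascular sample
  rs <- pmax(radii - step_px / 2, step_px / 2)
  if (smooth_deg > 0) {
    w <- max(3L, round(n_rays * smooth_deg / 360))
    if (w %% 2 == 0) w <- w + 1L
    h <- (w - 1L) / 2L
    circ <- function(x, f) {
      vapply(seq_len(n_rays), function(i) {
        f(x[((i - 1L + (-h:h)) %% n_rays) + 1L])
      }, numeric(1))
    }
    rs <- circ(circ(rs, stats::median), mean)
  }
  verts <- cbind(row = center_rc[1] + rs * sin(ang),
                 col = center_rc[2] + rs * cos(ang))
  psz <- binary$pixel_size_mm
  area <- .shoelace_area(verts) * psz^2
  perim <- .poly_perimeter(verts) * psz
  structure(list(vertices = verts, radii_px = radii, area_mm2 = area,
                 perimeter_mm = perim,
                 acircularity = perim / (2 * sqrt(pi * area)),
                 open = open_faz, n_rays = n_rays, center_rc = center_rc),
            class = "faz_polygon")
}

#' @export
print.faz_polygon <- function(x, ...) {
  cat(sprintf("<faz_polygon> area %.4f mm^2, perimeter %.3f mm, acircularity %.3f%s\n",
              x$area_mm2, x$perimeter_mm, x$acircularity,
              if (x$open) " (open)" else ""))
  invisible(x)
}

#' Default analysis configuration
#'
#' All tunable parameters of the extraction pipeline, recorded verbatim in
#' the provenance block of every [compute_crmbs()] run.
#'
#' @param threshold_method,local_window_mm,offset,min_object_px see [binarize()].
#' @param intensity_threshold,diameter_threshold_um,min_component_px see
#'   [delineate_large_vessels()].
#' @param n_rays,step_px,smooth_deg see [demarcate_faz()].
#' @param min_chord_px see [vessel_tortuosity()].
#' @param disp_radius_px,disp_min_pixels see [vessel_dispersion()].
#' @param box_sizes see [box_counting_fd()] (`NULL` = dyadic default).
#' @param pd_binary use binary (area-fraction) perfusion densities instead of
#'   intensity-weighted ones.
#' @return named list of class `crmb_config`.
#' @export
crmb_config <- function(threshold_method = "local_mean", local_window_mm = 0.2,
                        offset = 0.08, min_object_px = 10,
                        intensity_threshold = NULL, diameter_threshold_um = 25,
                        min_component_px = 50, n_rays = 360, step_px = 0.5,
                        smooth_deg = 7, min_chord_px = 10, disp_radius_px = 5,
                        disp_min_pixels = 20, box_sizes = NULL,
                        pd_binary = FALSE) {
  structure(as.list(environment()), class = "crmb_config")
}

#' Compute the twelve CRMBs from an SCP/DCP angiogram pair
#'
#' Runs the full pipeline: binarize both layers; separate SCP large vessels
#' from capillaries; skeletonize; then compute parafoveal perfusion densities
#' (PDL, PDCS, PDCD), full-scan fractal dimensions (FDS, FDD), large-vessel
#' tortuosity and diameter (MVT, MVDiam), full-skeleton parafoveal dispersion
#' (MVDisp) and per-layer FAZ area and acircularity (FAS/FAD, FACS/FACD).
#'
#' @param scp,dcp aligned [dvm_image()]s of equal geometry.
#' @param config a [crmb_config()].
#' @return object of class `crmb_record`: the 12 metrics plus a `provenance`
#'   list (thresholds actually used, flags) and the two `faz_polygon`s.
#' @export
compute_crmbs <- function(scp, dcp, config = crmb_config()) {
  stopifnot(inherits(scp, "dvm_image"), inherits(dcp, "dvm_image"))
  .assert(all(dim(scp$pixels) == dim(dcp$pixels)) &&
            isTRUE(all.equal(scp$pixel_size_mm, dcp$pixel_size_mm)),
          "SCP and DCP must share geometry")
  cfg <- config
  stage <- function(lbl, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", lbl, conditionMessage(e)), call. = FALSE)
    })
  }
  bin_scp <- stage("binarize:scp",
                   binarize(scp, cfg$threshold_method, cfg$local_window_mm,
                            cfg$offset, cfg$min_object_px))
  bin_dcp <- stage("binarize:dcp",
                   binarize(dcp, cfg$threshold_method, cfg$local_window_mm,
                            cfg$offset, cfg$min_object_px))
  lv <- stage("large_vessels",
              delineate_large_vessels(scp, bin_scp, cfg$intensity_threshold,
                                      cfg$diameter_threshold_um,
                                      cfg$min_component_px))
  regions <- make_etdrs_masks(scp)
  para <- regions$parafovea_mask
  sk_lv <- stage("skeleton:large",
                 skeletonize_map(lv$pixels, binary = bin_scp,
                                 pixel_size_mm = scp$pixel_size_mm))
  sk_all <- stage("skeleton:scp", skeletonize_map(bin_scp))
  faz_s <- stage("faz:scp", demarcate_faz(bin_scp, scp$center_rc,
                                          cfg$n_rays, cfg$step_px,
                                          cfg$smooth_deg))
  faz_d <- stage("faz:dcp", demarcate_faz(bin_dcp, dcp$center_rc,
                                          cfg$n_rays, cfg$step_px,
                                          cfg$smooth_deg))
  rec <- list(
    PDL   = perfusion_density(scp, lv$pixels, para, cfg$pd_binary),
    PDCS  = perfusion_density(scp, lv$capillary_pixels, para, cfg$pd_binary),
    PDCD  = perfusion_density(dcp, bin_dcp$pixels, para, cfg$pd_binary),
    MVT   = vessel_tortuosity(sk_lv, para, cfg$min_chord_px),
    MVDiam = mean_vessel_diameter(sk_lv, para),
    MVDisp = vessel_dispersion(sk_all, scp$center_rc, para,
                               cfg$disp_radius_px, cfg$disp_min_pixels),
    FDS   = box_counting_fd(bin_scp, cfg$box_sizes),
    FDD   = box_counting_fd(bin_dcp, cfg$box_sizes),
    FAS   = faz_s$area_mm2,
    FAD   = faz_d$area_mm2,
    FACS  = faz_s$acircularity,
    FACD  = faz_d$acircularity
  )
  rec$provenance <- list(
    config = unclass(cfg),
    scp_threshold = bin_scp$threshold_used,
    dcp_threshold = bin_dcp$threshold_used,
    lv_intensity_threshold = lv$intensity_threshold,
    lv_diameter_threshold_um = lv$diameter_threshold_um,
    lv_empty = !any(lv$pixels),
    faz_open = c(scp = faz_s$open, dcp = faz_d$open)
  )
  rec$faz <- list(scp = faz_s, dcp = faz_d)
  structure(rec, class = "crmb_record")
}

#' CRMB metric names
#' @return character vector of the twelve biomarker column names.
#' @export
crmb_names <- function() {
  c("PDL", "PDCS", "PDCD", "MVT", "MVDiam", "MVDisp",
    "FDS", "FDD", "FAS", "FAD", "FACS", "FACD")
}

#' @export
print.crmb_record <- function(x, ...) {
  v <- unlist(x[crmb_names()])
  cat("<crmb_record>\n")
  print(round(v, 4))
  invisible(x)
}

#' @export
as.data.frame.crmb_record <- function(x, ...) {
  as.data.frame(x[crmb_names()])
}
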