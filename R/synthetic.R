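# Ground-truthed synthetic OCTA angiograms: an elliptical avascular zone,
# radially oriented large vessels, and a stroke-based capillary mesh with
# controllable orientation, plus cohort-level group effects.

#' Parameters of a synthetic angiogram pair
#'
#' @param faz_radius_mm equivalent radius of the (elliptical) avascular zone;
#'   the ellipse preserves area `pi r^2` regardless of eccentricity. 0
#'   disables the zone.
#' @param faz_eccentricity shape factor in \[0, 1): semi-axes are
#'   `r / sqrt(1 - e)` and `r * sqrt(1 - e)`.
#' @param n_large_vessels number of radial large vessels (SCP only).
#' @param large_vessel_width_um,large_vessel_intensity caliber and rendered
#'   intensity of the large vessels.
#' @param capillary_density target vessel-area fraction of each layer's
#'   truth mask, in \[0, 0.9\].
#' @param capillary_width_um,capillary_intensity caliber and rendered
#'   intensity of capillary strokes.
#' @param tangential_fraction share of capillary strokes with uniformly
#'   random (non-centripetal) orientation; the remainder are radial with
#'   small jitter. 1 yields an isotropic orientation field.
#' @param noise_sigma additive Gaussian intensity noise SD.
#' @param seed RNG seed; the sample is bit-reproducible from it.
#' @param size_px raster side (default 304, the common 3 x 3 mm export).
#' @param width_mm physical scan width.
#' @return validated list of class `synthetic_params`.
#' @export
synthetic_params <- function(faz_radius_mm = 0.25, faz_eccentricity = 0.1,
                             n_large_vessels = 6, large_vessel_width_um = 60,
                             large_vessel_intensity = 0.95,
                             capillary_density = 0.38,
                             capillary_width_um = 15,
                             capillary_intensity = 0.6,
                             tangential_fraction = 0.25,
                             noise_sigma = 0.05, seed = 1L,
                             size_px = 304L, width_mm = 3) {
  .assert(faz_radius_mm >= 0 && faz_radius_mm < width_mm / 2,
          "faz_radius_mm must be in [0, width/2)", "octacrmb_config_error")
  .assert(faz_eccentricity >= 0 && faz_eccentricity < 1,
          "faz_eccentricity must be in [0, 1)", "octacrmb_config_error")
  .assert(capillary_density >= 0 && capillary_density <= 0.9,
          "capillary_density above 0.9 is unreachable", "octacrmb_config_error")
  .assert(large_vessel_width_um > 0 && capillary_width_um > 0,
          "vessel widths must be positive", "octacrmb_config_error")
  .assert(tangential_fraction >= 0 && tangential_fraction <= 1,
          "tangential_fraction must be in [0, 1]", "octacrmb_config_error")
  structure(as.list(environment()), class = "synthetic_params")
}

# Elliptical avascular-zone mask (TRUE inside the zone).
#' @noRd
.faz_mask <- function(size, center, r_px, ecc, phi) {
  if (r_px <= 0) return(matrix(FALSE, size, size))
  a <- r_px / sqrt(1 - ecc); b <- r_px * sqrt(1 - ecc)
  rr <- outer(seq_len(size) - center[1], rep(1, size))
  cc <- outer(rep(1, size), seq_len(size) - center[2])
  u <- rr * cos(phi) + cc * sin(phi)
  v <- -rr * sin(phi) + cc * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

# Stamp a polyline sampled at `pts` (k x 2) with radius rad_px into mask,
# excluding `avoid` pixels.
#' @noRd
.stamp_path <- function(mask, pts, rad_px, avoid = NULL) {
  size <- dim(mask)
  add <- .stamp_discs(size, round(pts[, 1]), round(pts[, 2]),
                      rep(max(rad_px, 0.5), nrow(pts)))
  if (!is.null(avoid)) add <- add & !avoid
  mask | add
}

#' Generate one ground-truthed synthetic SCP/DCP sample
#'
#' Renders, reproducibly from the seed: an elliptical avascular zone at the
#' scan center, bounded by a terminal capillary ring (the perifoveal
#' capillary ring that closes the zone in real retinas); smooth radial large
#' vessels of the stated caliber avoiding the zone (SCP only; the deep layer
#' has a 15% larger zone and no large vessels); a random capillary stroke
#' mesh grown until the target vessel fraction; and additive Gaussian
#' intensity noise.
#'
#' @param params a [synthetic_params()].
#' @return object of class `synthetic_sample`: `scp`/`dcp` ([dvm_image()]s),
#'   logical truth masks `truth_scp_mask`, `truth_dcp_mask`,
#'   `truth_large_vessel_mask`, and `params`.
#' @export
generate_sample <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  p <- params
  n <- as.integer(p$size_px)
  psz <- p$width_mm / n
  center <- rep((n + 1) / 2, 2)
  .with_seed(p$seed, {
    phi <- stats::runif(1, 0, pi)
    faz_s <- .faz_mask(n, center, p$faz_radius_mm / psz, p$faz_eccentricity, phi)
    faz_d <- .faz_mask(n, center, 1.15 * p$faz_radius_mm / psz,
                       p$faz_eccentricity, phi)
    ## large vessels (SCP)
    large <- matrix(FALSE, n, n)
    if (p$n_large_vessels > 0) {
      w_px <- p$large_vessel_width_um / (psz * 1000)
      r_start <- max(1.15 * p$faz_radius_mm / psz / sqrt(1 - p$faz_eccentricity), 3)
      for (k in seq_len(p$n_large_vessels)) {
        a0 <- 2 * pi * (k - 1) / p$n_large_vessels + stats::rnorm(1, 0, 0.15)
        amp <- stats::runif(1, 0.03, 0.1)
        per <- stats::runif(1, n / 3, n)
        ph <- stats::runif(1, 0, 2 * pi)
        t <- seq(r_start, n, by = 0.5)
        ang <- a0 + amp * sin(2 * pi * (t - r_start) / per + ph)
        pts <- cbind(center[1] + t * sin(ang), center[2] + t * cos(ang))
        keep <- pts[, 1] >= 1 & pts[, 1] <= n & pts[, 2] >= 1 & pts[, 2] <= n
        if (!any(keep)) next
        pts <- pts[keep, , drop = FALSE]
        large <- .stamp_path(large, pts, w_px / 2, avoid = faz_s)
      }
    }
    ## terminal capillary ring bounding the avascular zone (the perifoveal
    ## capillary ring); gives the zone a closed, well-defined vascular rim
    ring_mask <- function(faz, r_px) {
      if (r_px <= 0) return(matrix(FALSE, n, n))
      a <- r_px / sqrt(1 - p$faz_eccentricity)
      b <- r_px * sqrt(1 - p$faz_eccentricity)
      th <- seq(0, 2 * pi, length.out = ceiling(4 * pi * a))
      u <- a * cos(th); v <- b * sin(th)
      pts <- cbind(center[1] + u * cos(phi) - v * sin(phi),
                   center[2] + u * sin(phi) + v * cos(phi))
      keep <- pts[, 1] >= 1 & pts[, 1] <= n & pts[, 2] >= 1 & pts[, 2] <= n
      if (!any(keep)) return(matrix(FALSE, n, n))
      cw_px <- p$capillary_width_um / (psz * 1000)
      .stamp_path(matrix(FALSE, n, n), pts[keep, , drop = FALSE],
                  cw_px / 2, avoid = faz)
    }
    if (p$capillary_density > 0) {
      ring_s <- ring_mask(faz_s, p$faz_radius_mm / psz)
      ring_d <- ring_mask(faz_d, 1.15 * p$faz_radius_mm / psz)
    } else {
      ring_s <- ring_d <- matrix(FALSE, n, n)
    }
    ## capillary meshes
    grow_mesh <- function(base, faz, target) {
      mesh <- base
      cw_px <- p$capillary_width_um / (psz * 1000)
      stroke_px <- max(1, round(0.14 / psz)) * max(1, 2 * round(cw_px / 2) + 1)
      guard <- 0L
      while (mean(mesh) < target && guard < 2000L) {
        guard <- guard + 1L
        need <- (target - mean(mesh)) * n * n
        nb <- max(5L, min(400L, ceiling(need / stroke_px / 1.5)))
        for (s in seq_len(nb)) {
          rc <- stats::runif(2, 1, n)
          if (p$faz_radius_mm > 0 &&
              faz[round(rc[1]), round(rc[2])]) next
          if (stats::runif(1) < p$tangential_fraction) {
            th <- stats::runif(1, 0, pi)
          } else {
            th <- atan2(rc[1] - center[1], rc[2] - center[2]) +
              stats::rnorm(1, 0, 0.15)
          }
          L <- stats::runif(1, 0.08, 0.2) / psz
          t <- seq(-L / 2, L / 2, by = 0.5)
          pts <- cbind(rc[1] + t * sin(th), rc[2] + t * cos(th))
          keep <- pts[, 1] >= 1 & pts[, 1] <= n & pts[, 2] >= 1 & pts[, 2] <= n
          if (!any(keep)) next
          mesh <- .stamp_path(mesh, pts[keep, , drop = FALSE], cw_px / 2,
                              avoid = faz)
        }
      }
      mesh
    }
    scp_truth <- grow_mesh(large | ring_s, faz_s, p$capillary_density)
    dcp_truth <- grow_mesh(ring_d, faz_d, p$capillary_density)
    ## render intensities
    render <- function(truth, lv = NULL) {
      img <- matrix(0.12, n, n)
      img[truth] <- p$capillary_intensity
      if (!is.null(lv)) img[lv] <- p$large_vessel_intensity
      img <- img + stats::rnorm(n * n, 0, p$noise_sigma)
      pmin(pmax(img, 0), 1)
    }
    scp_img <- render(scp_truth, large)
    dcp_img <- render(dcp_truth)
    structure(list(scp = dvm_image(scp_img, p$width_mm),
                   dcp = dvm_image(dcp_img, p$width_mm),
                   truth_scp_mask = scp_truth,
                   truth_dcp_mask = dcp_truth,
                   truth_large_vessel_mask = large,
                   params = p),
              class = "synthetic_sample")
  })
}

#' Group effects for a synthetic case-control cohort
#'
#' Additive shifts applied to the mean generator parameters of the RVO group
#' relative to healthy controls. The defaults emulate the ischemic phenotype:
#' sparser capillaries, thinner large vessels, a larger and more eccentric
#' avascular zone, and more disorganized (less centripetal) capillary
#' orientation.
#'
#' @param faz_radius_mm,faz_eccentricity,capillary_density,large_vessel_width_um,tangential_fraction
#'   additive shifts; set all to 0 for exchangeable groups.
#' @return named list of class `cohort_effects`.
#' @export
cohort_effects <- function(faz_radius_mm = 0.15, faz_eccentricity = 0.15,
                           capillary_density = -0.10,
                           large_vessel_width_um = -12,
                           tangential_fraction = 0.25) {
  structure(as.list(environment()), class = "cohort_effects")
}

#' Generate a synthetic case-control cohort
#'
#' Draws per-subject generator parameters from group-specific distributions
#' (healthy means shifted by [cohort_effects()] for the RVO group), renders
#' each subject's SCP/DCP pair, extracts the twelve CRMBs, and attaches
#' clinical covariates. Initial visual acuity follows a stated linear model
#' on the true generator parameters,
#' `BCVA = 0.05 + 2.2 density - 1.2 (faz_radius - 0.25) + N(0, 0.08)`,
#' used only for recovery testing, not as a claim about biology.
#'
#' @param n_normal,n_rvo group sizes (>= 2 each).
#' @param effect a [cohort_effects()].
#' @param seed master seed; everything (parameters, images, covariates) is
#'   reproducible from it.
#' @param size_px raster side per subject.
#' @param config [crmb_config()] used for extraction.
#' @param extract run [compute_crmbs()] per subject (default TRUE).
#' @param keep_images retain the rendered samples in the result (default
#'   FALSE; a 73-subject cohort of 304 px images retains ~270 MB otherwise).
#' @return data.frame of class `cohort_table`: id, group, eye, age, sex,
#'   comorbidities, bcva_initial, the 12 CRMB columns (if extracted) and the
#'   per-subject true generator parameters (`truth_*` columns). When
#'   `keep_images = TRUE` the samples are attached as
#'   `attr(x, "samples")`.
#' @export
generate_cohort <- function(n_normal = 30, n_rvo = 43,
                            effect = cohort_effects(), seed = 1L,
                            size_px = 304L, config = crmb_config(),
                            extract = TRUE, keep_images = FALSE) {
  .assert(n_normal >= 2 && n_rvo >= 2, "need >= 2 subjects per group",
          "octacrmb_config_error")
  stopifnot(inherits(effect, "cohort_effects"))
  ntot <- n_normal + n_rvo
  base <- list(faz_radius_mm = 0.25, faz_eccentricity = 0.10,
               capillary_density = 0.38, large_vessel_width_um = 62,
               tangential_fraction = 0.25)
  sds <- list(faz_radius_mm = 0.04, faz_eccentricity = 0.05,
              capillary_density = 0.035, large_vessel_width_um = 6,
              tangential_fraction = 0.08)
  .with_seed(seed, {
    grp <- rep(c("normal", "rvo"), c(n_normal, n_rvo))
    draw <- function(name, lo, hi) {
      mu <- base[[name]] + ifelse(grp == "rvo", effect[[name]], 0)
      pmin(pmax(stats::rnorm(ntot, mu, sds[[name]]), lo), hi)
    }
    radius <- draw("faz_radius_mm", 0.08, 0.9)
    ecc <- draw("faz_eccentricity", 0, 0.6)
    dens <- draw("capillary_density", 0.1, 0.6)
    widt <- draw("large_vessel_width_um", 25, 120)
    tang <- draw("tangential_fraction", 0, 1)
    age <- round(pmin(pmax(stats::rnorm(ntot, ifelse(grp == "rvo", 55, 45),
                                        ifelse(grp == "rvo", 13, 15)), 18), 90))
    sex <- sample(c("men", "women"), ntot, replace = TRUE)
    eye <- sample(c("right", "left"), ntot, replace = TRUE)
    crate <- function(pn, pr) stats::rbinom(ntot, 1, ifelse(grp == "rvo", pr, pn)) == 1
    diabetes <- crate(0.02, 0.05)
    hypertension <- crate(0.05, 0.35)
    hyperlipidaemia <- crate(0.03, 0.14)
    atherosclerosis <- crate(0.05, 0.26)
    bcva <- pmin(pmax(0.05 + 2.2 * dens - 1.2 * (radius - 0.25) +
                        stats::rnorm(ntot, 0, 0.08), 0.05), 1.5)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, ntot)
    tab <- data.frame(id = sprintf("S%03d", seq_len(ntot)), group = grp,
                      eye = eye, age = age, sex = sex,
                      diabetes = diabetes, hypertension = hypertension,
                      hyperlipidaemia = hyperlipidaemia,
                      atherosclerosis = atherosclerosis,
                      bcva_initial = bcva,
                      stringsAsFactors = FALSE)
    samples <- if (keep_images) vector("list", ntot) else NULL
    if (extract || keep_images) {
      crmbs <- matrix(NA_real_, ntot, 12,
                      dimnames = list(NULL, crmb_names()))
      for (i in seq_len(ntot)) {
        sp <- synthetic_params(faz_radius_mm = radius[i],
                               faz_eccentricity = ecc[i],
                               large_vessel_width_um = widt[i],
                               capillary_density = dens[i],
                               tangential_fraction = tang[i],
                               seed = sub_seeds[i], size_px = size_px)
        smp <- generate_sample(sp)
        if (keep_images) samples[[i]] <- smp
        if (extract) {
          rec <- compute_crmbs(smp$scp, smp$dcp, config)
          crmbs[i, ] <- unlist(rec[crmb_names()])
        }
      }
      if (extract) tab <- cbind(tab, as.data.frame(crmbs))
    }
    tab$truth_faz_radius_mm <- radius
    tab$truth_faz_eccentricity <- ecc
    tab$truth_capillary_density <- dens
    tab$truth_large_vessel_width_um <- widt
    tab$truth_tangential_fraction <- tang
    class(tab) <- c("cohort_table", "data.frame")
    if (keep_images) attr(tab, "samples") <- samples
    tab
  })
}

## --- deterministic geometric fixtures -------------------------------------

#' Radial-spoke mask (perfectly centripetal vasculature)
#'
#' Straight 1-pixel rays from the center to the border, a limiting fixture
#' for the vessel-dispersion metric (MVDisp ~ 0).
#'
#' @param size raster side.
#' @param n_spokes number of rays.
#' @param inner_px start radius.
#' @return logical matrix.
#' @export
synth_spokes_mask <- function(size = 304, n_spokes = 12, inner_px = 8) {
  m <- matrix(FALSE, size, size)
  ctr <- (size + 1) / 2
  for (k in seq_len(n_spokes)) {
    a <- 2 * pi * (k - 1) / n_spokes
    t <- seq(inner_px, size, by = 0.4)
    r <- round(ctr + t * sin(a)); c <- round(ctr + t * cos(a))
    keep <- r >= 1 & r <= size & c >= 1 & c <= size
    m[cbind(r[keep], c[keep])] <- TRUE
  }
  m
}

#' Concentric-ring mask (purely tangential vasculature)
#'
#' 1-pixel circles around the center, the opposite MVDisp limit (~ 1).
#'
#' @param size raster side.
#' @param spacing_px radial distance between rings.
#' @param inner_px innermost ring radius.
#' @return logical matrix.
#' @export
synth_rings_mask <- function(size = 304, spacing_px = 14, inner_px = 20) {
  m <- matrix(FALSE, size, size)
  ctr <- (size + 1) / 2
  for (rad in seq(inner_px, size / 2 - 2, by = spacing_px)) {
    th <- seq(0, 2 * pi, length.out = ceiling(2 * pi * rad * 3))
    r <- round(ctr + rad * sin(th)); c <- round(ctr + rad * cos(th))
    keep <- r >= 1 & r <= size & c >= 1 & c <= size
    m[cbind(r[keep], c[keep])] <- TRUE
  }
  m
}

#' Isotropic random stroke mask
#'
#' Short straight strokes with uniformly random orientation and position;
#' the orientation field is isotropic, so MVDisp should approach
#' `1 - 2/pi ~ 0.363`.
#'
#' @param size raster side.
#' @param density target area fraction.
#' @param seed RNG seed.
#' @return logical matrix.
#' @export
synth_isotropic_mask <- function(size = 304, density = 0.15, seed = 1) {
  .with_seed(seed, {
    m <- matrix(FALSE, size, size)
    guard <- 0L
    while (mean(m) < density && guard < 20000L) {
      guard <- guard + 1L
      rc <- stats::runif(2, 1, size)
      th <- stats::runif(1, 0, pi)
      L <- stats::runif(1, 15, 30)
      t <- seq(-L / 2, L / 2, by = 0.5)
      r <- round(rc[1] + t * sin(th)); c <- round(rc[2] + t * cos(th))
      keep <- r >= 1 & r <= size & c >= 1 & c <= size
      m[cbind(r[keep], c[keep])] <- TRUE
    }
    m
  })
}

#' Sierpinski-carpet raster
#'
#' Deterministic fractal fixture of side `3^depth` with known box-counting
#' dimension `log 8 / log 3 ~ 1.8928`.
#'
#' @param depth recursion depth (default 5, a 243 x 243 raster).
#' @return logical matrix.
#' @export
sierpinski_carpet <- function(depth = 5) {
  n <- 3^depth
  i <- 0:(n - 1)
  keep <- matrix(TRUE, n, n)
  for (k in seq_len(depth)) {
    d <- (i %/% 3^(k - 1)) %% 3 == 1
    keep <- keep & !outer(d, d, `&`)
  }
  keep
}
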