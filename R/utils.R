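# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.assert <- function(ok, msg, class = "octacrmb_error") {
  if (!isTRUE(ok)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(TRUE)
}

# Box-mean filter with edge replication; w must be odd.
#' @noRd
.box_mean <- function(mat, w) {
  .assert(w >= 1 && w %% 2 == 1, "box filter width must be odd")
  if (w == 1) return(mat)
  h <- (w - 1L) / 2L
  nr <- nrow(mat); nc <- ncol(mat)
  # replicate-pad
  ri <- c(rep(1L, h), seq_len(nr), rep(nr, h))
  ci <- c(rep(1L, h), seq_len(nc), rep(nc, h))
  p <- mat[ri, ci]
  # running sums along rows then columns via cumsum
  cs <- apply(p, 2, cumsum)
  rowsum <- cs[(w):(nr + w - 1L), , drop = FALSE] -
    rbind(0, cs[seq_len(nr - 1L), , drop = FALSE])
  cs2 <- t(apply(rowsum, 1, cumsum))
  out <- cs2[, (w):(nc + w - 1L), drop = FALSE] -
    cbind(0, cs2[, seq_len(nc - 1L), drop = FALSE])
  out / (w * w)
}

# Zero-padded box sum over a w x w window; w must be odd.
#' @noRd
.box_sum <- function(mat, w) {
  if (w == 1) return(mat)
  h <- (w - 1L) / 2L
  nr <- nrow(mat); nc <- ncol(mat)
  p <- matrix(0, nr + 2L * h, nc + 2L * h)
  p[(h + 1L):(h + nr), (h + 1L):(h + nc)] <- mat
  cs <- apply(p, 2, cumsum)
  rowsum <- cs[(w):(nr + w - 1L), , drop = FALSE] -
    rbind(0, cs[seq_len(nr - 1L), , drop = FALSE])
  cs2 <- t(apply(rowsum, 1, cumsum))
  cs2[, (w):(nc + w - 1L), drop = FALSE] -
    cbind(0, cs2[, seq_len(nc - 1L), drop = FALSE])
}

# Integer (dr, dc) offsets within Euclidean radius r (r >= 0).
#' @noRd
.disc_offsets <- function(r) {
  ri <- floor(r)
  if (ri < 1) return(cbind(dr = 0L, dc = 0L))
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g <- g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

# Stamp discs of per-point radius into a logical matrix.
#' @noRd
.stamp_discs <- function(dim_rc, rows, cols, radii) {
  out <- matrix(FALSE, dim_rc[1], dim_rc[2])
  if (length(rows) == 0) return(out)
  rint <- round(radii * 2) / 2   # half-pixel granularity keeps offset sets small
  for (r in sort(unique(rint))) {
    off <- .disc_offsets(r)
    sel <- rint == r
    rr <- outer(off[, "dr"], rows[sel], `+`)
    cc <- outer(off[, "dc"], cols[sel], `+`)
    keep <- rr >= 1 & rr <= dim_rc[1] & cc >= 1 & cc <= dim_rc[2]
    out[cbind(rr[keep], cc[keep])] <- TRUE
  }
  out
}

# Shoelace area of a closed polygon given (row, col) vertices (pixel units).
#' @noRd
.shoelace_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' @noRd
.poly_perimeter <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(sqrt((v[j, 1] - v[, 1])^2 + (v[j, 2] - v[, 2])^2))
}

# Distance (in pixels) of every pixel center from a center point.
#' @noRd
.radius_grid <- function(nr, nc, center_rc) {
  dr <- (seq_len(nr) - center_rc[1])
  dc <- (seq_len(nc) - center_rc[2])
  sqrt(outer(dr^2, dc^2, `+`))
}

# Run code with a private RNG stream, restoring the caller's state.
#' @noRd
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Dice overlap of two logical masks.
#' @export
#' @title Dice overlap coefficient
#' @description Dice similarity between two logical masks of equal shape:
#'   `2 |A ∩ B| / (|A| + |B|)`.
#' @param a,b logical matrices of identical dimension.
#' @return scalar in \[0, 1\].
dice_coefficient <- function(a, b) {
  .assert(all(dim(a) == dim(b)), "masks must share dimensions")
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
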