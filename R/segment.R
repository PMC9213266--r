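## T1-map-driven tissue classification (GM / WM / CSF) and tissue means.
##
## The anatomical-prior segmentation used clinically (SPM-style) is
## replaced here by intensity-only classification on the T1 map itself:
## either a 3-component 1-D Gaussian mixture fitted by EM with a
## deterministic quantile initialization, or fixed T1 windows.  Components
## map to tissues by ascending mean T1: WM < GM < CSF.

#' Default T1 windows (ms) for fixed-window segmentation
#'
#' Spans chosen around typical 3-T values: WM 500-1100, GM 1100-2000,
#' CSF 3000-8000.
#' @return Named list of `(lo, hi)` pairs for `wm`, `gm`, `csf`.
#' @export
default_t1_windows <- function() {
  list(wm = c(500, 1100), gm = c(1100, 2000), csf = c(3000, 8000))
}

## Exact 1-D k-means by dynamic programming on a histogram (the classic
## optimal segmentation of sorted data into k contiguous groups).  Returns
## the k group means/sds/weights.  Deterministic and initialization-free;
## B bins keep it O(k B^2) regardless of voxel count.
kmeans1d_dp <- function(z, k = 3L, bins = 512L) {
  br <- seq(min(z), max(z), length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(z, br, rightmost.closed = TRUE), 1L), bins)
  n <- tabulate(idx, bins)
  s <- tapply(z, factor(idx, levels = seq_len(bins)), sum)
  s[is.na(s)] <- 0
  q <- tapply(z^2, factor(idx, levels = seq_len(bins)), sum)
  q[is.na(q)] <- 0
  cn <- c(0, cumsum(n)); cs <- c(0, cumsum(s)); cq <- c(0, cumsum(q))
  seg <- function(i, j) {           # SSE of bins i..j around their mean
    nn <- cn[j + 1] - cn[i]
    ss <- cs[j + 1] - cs[i]
    qq <- cq[j + 1] - cq[i]
    out <- qq - ss^2 / pmax(nn, 1)
    out[nn == 0] <- 0
    pmax(out, 0)
  }
  D <- matrix(Inf, k, bins)
  back <- matrix(1L, k, bins)
  D[1, ] <- seg(1, seq_len(bins))
  for (kk in 2:k) {
    for (j in kk:bins) {
      i <- kk:j
      v <- D[kk - 1, i - 1] + seg(i, j)
      bi <- which.min(v)
      D[kk, j] <- v[bi]; back[kk, j] <- i[bi]
    }
  }
  bounds <- integer(k + 1); bounds[k + 1] <- bins
  j <- bins
  for (kk in k:1) { bounds[kk] <- back[kk, j]; j <- back[kk, j] - 1L }
  grp <- findInterval(idx, bounds[1:k])
  list(group = grp,
       mu = tapply(z, grp, mean),
       sig = tapply(z, grp, sd),
       w = as.numeric(table(factor(grp, levels = 1:k))) / length(z))
}

## Deterministic 1-D EM for a 3-component Gaussian mixture, fitted on the
## log scale (T1 noise is closer to multiplicative, and the log compresses
## the heavy upper tail of slope-near-1 fit outliers that would otherwise
## capture a component).  Initialized from the exact 1-D k-means partition.
gmm3_fit <- function(x, max_iter = 200, tol = 1e-8) {
  k <- 3L
  z <- log(x)
  init <- kmeans1d_dp(z, k)
  mu <- as.numeric(init$mu)
  sig <- as.numeric(init$sig)
  sig[!is.finite(sig) | sig < 1e-6] <- max(sd(z) / 10, 1e-6)
  w <- pmax(init$w, 1e-6)
  x <- z
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:k, function(j) w[j] * dnorm(x, mu[j], sig[j]),
                   numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    mu <- colSums(resp * x) / nk
    sig <- sqrt(pmax(colSums(resp * (outer(x, mu, `-`))^2) / nk, 1e-8))
    w <- nk / length(x)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, sig = sig, w = w, resp = resp)
}

#' Segment a T1 map into gray matter, white matter and CSF
#'
#' @param map An `asl_t1_map` from [fit_t1_vfa()].
#' @param method `"gmm3"` (default): fit a 3-component 1-D Gaussian
#'   mixture to the valid T1 values by EM with deterministic quantile
#'   initialization, assign each voxel to its maximum-posterior component,
#'   and name components WM, GM, CSF by ascending mean.  `"fixed-windows"`:
#'   assign by T1 ranges; voxels matching no window stay unassigned.
#' @param windows For `"fixed-windows"`: named list of `(lo, hi)` ms
#'   ranges for `wm`, `gm`, `csf` (default [default_t1_windows()]).
#'   Intervals are `(lo, hi]`.
#' @param fit_range For `"gmm3"`: the physiologic T1 range (ms) the
#'   mixture is fitted over.  Two-point fits at low SNR produce wild
#'   estimates when the slope lands near 0 or 1; values outside the range
#'   are treated as fit failures and left unassigned (never clipped).
#'   Default 200-8000 ms, generous around brain tissue at 3 T.
#' @param m0_min_frac Foreground mask: voxels whose fitted M0 falls below
#'   this fraction of the median valid M0 are excluded before
#'   classification (default 0.1).  Pure-noise voxels outside the head
#'   pass the slope validity test by chance but fit near-zero M0; an
#'   intensity floor is the usual brain-masking remedy.  Set to 0 (or
#'   supply a map without M0) to disable.
#' @param seed Accepted for interface stability; the EM initialization is
#'   deterministic, so the seed is not consumed.
#' @return Object of class `asl_tissue_masks`: logical arrays `gm`, `wm`,
#'   `csf`, pairwise disjoint and confined to the valid region.
#' @export
segment_t1 <- function(map, method = c("gmm3", "fixed-windows"),
                       windows = default_t1_windows(),
                       fit_range = c(200, 8000), m0_min_frac = 0.1,
                       seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(map, "asl_t1_map"))
  dims <- dim(map$t1)
  gm <- wm <- csf <- array(FALSE, dim = dims)
  vi <- which(map$valid)
  if (m0_min_frac > 0 && any(is.finite(map$m0[vi]))) {
    m0v <- map$m0[vi]
    vi <- vi[is.finite(m0v) & m0v >= m0_min_frac * stats::median(m0v, na.rm = TRUE)]
  }
  if (method == "gmm3") {
    vi <- vi[map$t1[vi] >= fit_range[1] & map$t1[vi] <= fit_range[2]]
  }
  x <- map$t1[vi]

  if (method == "gmm3") {
    if (length(unique(x)) < 3L) {
      abort_data("gmm3 needs at least 3 distinct valid T1 values")
    }
    fit <- gmm3_fit(x)
    cls <- max.col(fit$resp, ties.method = "first")
    ord <- order(fit$mu)          # ascending mean: WM, GM, CSF
    wm[vi] <- cls == ord[1]
    gm[vi] <- cls == ord[2]
    csf[vi] <- cls == ord[3]
  } else {
    in_win <- function(w) x > w[1] & x <= w[2]
    wm[vi] <- in_win(windows$wm)
    gm[vi] <- in_win(windows$gm) & !wm[vi]
    csf[vi] <- in_win(windows$csf) & !wm[vi] & !gm[vi]
  }
  structure(list(gm = gm, wm = wm, csf = csf), class = "asl_tissue_masks")
}

#' @export
print.asl_tissue_masks <- function(x, ...) {
  cat(sprintf("Tissue masks: GM %d, WM %d, CSF %d voxels\n",
              sum(x$gm), sum(x$wm), sum(x$csf)))
  invisible(x)
}

#' Mean tissue T1 under a mask
#'
#' Arithmetic mean of the T1 map over `mask & valid`; invalid voxels never
#' contribute.  This is the whole-brain mean gray matter T1 that drives
#' the background suppression timing when called with the GM mask.
#'
#' @param map An `asl_t1_map`.
#' @param mask Logical array of the map's shape.
#' @return Scalar mean T1 in ms.
#' @examples
#' \dontrun{mean_tissue_t1(fit, masks$gm)}
#' @export
mean_tissue_t1 <- function(map, mask) {
  stopifnot(inherits(map, "asl_t1_map"))
  check_same_dim(map$t1, mask, "map and mask")
  sel <- mask & map$valid
  if (!any(sel)) abort_data("mask does not intersect the valid region")
  mean(map$t1[sel])
}
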