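## Perfusion image quality metrics on a label/control difference volume.

#' Evaluate a perfusion difference volume
#'
#' Summarizes a (mean) control-minus-label volume: the mean difference
#' signal over gray matter (`mean_gm_diff`, also reported as the relative
#' CBF readout `rcbf_gm`, arbitrary units — no absolute quantification),
#' the standard deviation over a background region (`background_sd`), and
#' their ratio, the signal-to-background ratio (`sbr`).  A zero
#' `background_sd` flags `sbr` as `Inf` rather than erroring — the
#' noiseless perfect-suppression limit.
#'
#' The background region is caller-chosen.  The air region (`labels == 0`)
#' carries only thermal noise; to measure how well a suppression schedule
#' controls physiological leakage, pass a static-tissue region instead —
#' the pipeline uses the white matter mask (see the package vignette for
#' why CSF is excluded).
#'
#' @param diff_volume 3-D numeric array, control minus label.
#' @param masks An `asl_tissue_masks`; the GM mask is the signal region.
#' @param background Logical array: background region; must be disjoint
#'   from every tissue mask and non-empty.
#' @return Object of class `asl_perfusion_report` with fields
#'   `mean_gm_diff`, `background_sd`, `sbr`, `rcbf_gm`, `n_gm`, `n_background`.
#' @export
evaluate_perfusion <- function(diff_volume, masks, background) {
  stopifnot(inherits(masks, "asl_tissue_masks"))
  check_same_dim(diff_volume, masks$gm, "diff volume and masks")
  check_same_dim(diff_volume, background, "diff volume and background")
  if (!any(masks$gm)) abort_data("GM mask is empty")
  if (!any(background)) abort_data("background mask is empty")
  for (nm in c("gm", "wm", "csf")) {
    if (any(masks[[nm]] & background)) {
      abort_data(sprintf("background region overlaps the %s mask", nm))
    }
  }
  mgm <- mean(diff_volume[masks$gm])
  bsd <- if (sum(background) > 1) sd(diff_volume[background]) else 0
  sbr <- if (bsd > 0) mgm / bsd else Inf
  structure(list(mean_gm_diff = mgm, background_sd = bsd, sbr = sbr,
                 rcbf_gm = mgm, n_gm = sum(masks$gm),
                 n_background = sum(background)),
            class = "asl_perfusion_report")
}

#' @export
print.asl_perfusion_report <- function(x, ...) {
  cat(sprintf("Perfusion: GM diff %.4g (n=%d), background SD %.4g (n=%d), SBR %.4g\n",
              x$mean_gm_diff, x$n_gm, x$background_sd, x$n_background, x$sbr))
  invisible(x)
}
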