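#' Shrinkage scaling factor for brain sectioning
#'
#' Fixation and antigen retrieval shrink the specimen; sectioning
#' coordinates read off the atlas must be rescaled. The scaling factor is
#' the ratio of the measured specimen length `L` to the atlas
#' anterior-posterior extent `a - p` (all mm):
#' `alpha = L / (a - p)`.
#'
#' @param L_mm measured specimen length (mm).
#' @param a_mm atlas most-anterior extent (mm, Bregma-referenced; the atlas
#'   value is 5.6 mm).
#' @param p_mm atlas most-posterior extent (mm, Bregma-referenced; must be
#'   supplied — no default is assumed).
#' @return The scaling factor alpha (dimensionless).
#' @export
shrink_factor <- function(L_mm, a_mm, p_mm) {
  assert_scalar_number(L_mm, "L_mm", positive = TRUE)
  assert_scalar_number(a_mm, "a_mm")
  assert_scalar_number(p_mm, "p_mm")
  if (a_mm <= p_mm) {
    stop_irritmap("`a_mm` must exceed `p_mm`.", "irritmap_geometry_error")
  }
  L_mm / (a_mm - p_mm)
}

#' Map an atlas offset to specimen coordinates
#'
#' Multiplies a Bregma-referenced atlas coordinate (anterior positive) by
#' the shrinkage factor; the sign convention and the Bregma origin are
#' preserved.
#'
#' @param atlas_offset_mm Bregma-referenced atlas coordinate(s), mm.
#' @param alpha scaling factor from [shrink_factor()] (> 0).
#' @return Specimen coordinate(s), mm.
#' @export
atlas_to_specimen <- function(atlas_offset_mm, alpha) {
  assert_scalar_number(alpha, "alpha", positive = TRUE)
  atlas_offset_mm * alpha
}

#' Sectioning plan for a brain block
#'
#' Collects the shrinkage-corrected distances needed to cut the histology
#' block: `B2`, the scaled distance from the most anterior cortex to Bregma,
#' and `l`, the scaled distance from Bregma to the block center.
#'
#' @param L_mm measured specimen length (mm).
#' @param a_mm,p_mm atlas anterior/posterior extents (mm).
#' @param block_center_mm Bregma-referenced atlas coordinate of the block
#'   center (mm; caudal negative).
#' @param block_width_mm block extent along the anterior-posterior axis, mm
#'   (atlas units).
#' @return An `irritmap_sectioning_plan`: list with `alpha`, `L_mm`, `a_mm`,
#'   `p_mm`, `B2_mm`, `l_mm`, and the scaled block `limits_mm`.
#' @export
sectioning_plan <- function(L_mm, a_mm, p_mm, block_center_mm,
                            block_width_mm = 4) {
  alpha <- shrink_factor(L_mm, a_mm, p_mm)
  if (alpha > 1.2) {
    stop_irritmap("Scaling factor above 1.2: check the measured length.",
                  "irritmap_geometry_error")
  }
  b2 <- atlas_to_specimen(a_mm, alpha)
  l <- atlas_to_specimen(block_center_mm, alpha)
  limits <- atlas_to_specimen(block_center_mm + c(-0.5, 0.5) * block_width_mm,
                              alpha)
  structure(list(alpha = alpha, L_mm = L_mm, a_mm = a_mm, p_mm = p_mm,
                 B2_mm = b2, l_mm = l, limits_mm = limits),
            class = "irritmap_sectioning_plan")
}

#' @export
print.irritmap_sectioning_plan <- function(x, ...) {
  cat(sprintf(
    paste0("<irritmap_sectioning_plan> alpha = %.3f\n  B2 = %.2f mm, ",
           "l = %.2f mm, block [%.2f, %.2f] mm (specimen, Bregma origin)\n"),
    x$alpha, x$B2_mm, x$l_mm, x$limits_mm[1], x$limits_mm[2]))
  invisible(x)
}

#' @export
tidy.irritmap_sectioning_plan <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, L_mm = x$L_mm, a_mm = x$a_mm,
                 p_mm = x$p_mm, B2_mm = x$B2_mm, l_mm = x$l_mm,
                 block_from_mm = x$limits_mm[1],
                 block_to_mm = x$limits_mm[2])
}

#' Write sectioning block boundaries as CSV
#'
#' @param plan an `irritmap_sectioning_plan`.
#' @param path output path.
#' @export
write_sectioning_csv <- function(plan, path) {
  readr::write_csv(tidy(plan), path)
  invisible(path)
}
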