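#' Parenchyma cell wall density from the spherical-cell model
#'
#' Cells are modelled as spheres of radius R = mean size / 2 with walls of
#' constant thickness; the wall volume fraction is then
#' `3 * thickness / R * 100` percent. Strictly decreasing in the mean size
#' and linear in the wall thickness.
#'
#' @param mean_size_um grey-level mean cell size, micrometres.
#' @param wall_thickness_um cell wall thickness (default 0.5).
#' @return cell wall density, percent of volume.
#' @examples
#' cell_wall_density(70)   # 4.29 %
#' @export
cell_wall_density <- function(mean_size_um, wall_thickness_um = 0.5) {
  if (any(mean_size_um <= 0)) stop("invalid-input: non-positive mean size")
  if (any(wall_thickness_um < 0)) stop("invalid-input: negative wall thickness")
  if (any(mean_size_um <= 2 * wall_thickness_um))
    stop("invalid-input: mean size must exceed twice the wall thickness")
  3 * wall_thickness_um / (mean_size_um / 2) * 100
}

#' Parenchyma cell wall amounts
#'
#' Wall area of each parenchyma zone: density times zone area. The
#' near-rind zone area is total parenchyma minus middle parenchyma, so it
#' includes the 500-1000 um band.
#'
#' @param Pa_A total parenchyma area, cm^2.
#' @param middle_area middle-parenchyma area, cm^2.
#' @param Pm_CD,Pr_CD cell wall densities, percent.
#' @return list `Pm_wall`, `Pr_wall` (cm^2).
#' @export
parenchyma_wall_amounts <- function(Pa_A, middle_area, Pm_CD, Pr_CD) {
  if (middle_area > Pa_A)
    stop("invalid-input: middle area exceeds total parenchyma area")
  list(Pm_wall = Pm_CD / 100 * middle_area,
       Pr_wall = Pr_CD / 100 * (Pa_A - middle_area))
}

#' Tissue cell wall proportions (cylinder-internode model)
#'
#' Total cell wall = rind area + bundle area + parenchyma wall amounts
#' (rind and bundles counted as 100 percent wall). Each tissue is reported
#' as percent of the total; `CW_T` is the total as percent of the stem
#' area. Under the cylinder model relative volumes equal relative areas;
#' no axial integration is performed.
#'
#' @param Ri_A_est estimated rind area, cm^2.
#' @param Vb_A bundle area, cm^2.
#' @param Pm_wall,Pr_wall parenchyma wall areas, cm^2.
#' @param St_A stem area, cm^2.
#' @param Pm_CD,Pr_CD densities carried through for reporting (optional).
#' @param wall_thickness_um model constant carried through (default 0.5).
#' @return object of class `stereology_result`.
#' @export
tissue_wall_proportions <- function(Ri_A_est, Vb_A, Pm_wall, Pr_wall, St_A,
                                    Pm_CD = NA_real_, Pr_CD = NA_real_,
                                    wall_thickness_um = 0.5) {
  vals <- c(Ri_A_est, Vb_A, Pm_wall, Pr_wall)
  if (any(vals < 0)) stop("invalid-input: negative wall amount")
  total <- sum(vals)
  if (total <= 0) stop("invalid-input: zero total cell wall")
  structure(list(
    Cw_thickness_um = wall_thickness_um,
    Pm_CD = Pm_CD, Pr_CD = Pr_CD,
    Ri_Cw = Ri_A_est / total * 100,
    Vb_Cw = Vb_A / total * 100,
    Pm_Cw = Pm_wall / total * 100,
    Pr_Cw = Pr_wall / total * 100,
    CW_T = total / St_A * 100,
    total_wall_cm2 = total
  ), class = "stereology_result")
}

#' @export
print.stereology_result <- function(x, ...) {
  cat("stereology_result\n")
  cat(sprintf("  CW(T) %.1f%% of stem area\n", x$CW_T))
  cat(sprintf("  of total cell wall: Ri %.1f%%  Vb %.1f%%  Pm %.1f%%  Pr %.1f%%\n",
              x$Ri_Cw, x$Vb_Cw, x$Pm_Cw, x$Pr_Cw))
  invisible(x)
}

#' Stereology from a descriptor set
#'
#' Applies the spherical-cell and cylinder-internode models to the
#' descriptors of one section.
#'
#' @param desc [stem_descriptors()].
#' @param wall_thickness_um cell wall thickness, micrometres.
#' @return [tissue_wall_proportions()] result.
#' @export
stereology_from_descriptors <- function(desc, wall_thickness_um = 0.5) {
  stopifnot(inherits(desc, "stem_descriptors"))
  Pm_CD <- cell_wall_density(desc$Pm_Cd, wall_thickness_um)
  Pr_CD <- cell_wall_density(desc$Pr_Cd, wall_thickness_um)
  w <- parenchyma_wall_amounts(desc$Pa_A, desc$middle_area, Pm_CD, Pr_CD)
  Ri_used <- if (desc$rind_damaged) desc$Ri_A_est else desc$Ri_A_measured
  tissue_wall_proportions(Ri_used, desc$Vb_A, w$Pm_wall, w$Pr_wall,
                          desc$St_A, Pm_CD, Pr_CD, wall_thickness_um)
}
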