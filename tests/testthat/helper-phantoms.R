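# Shared fixtures, built in code. The sphere and ellipsoid match the
# control / myopia group mean geometries so length recovery can be checked
# against known diameters.

sphere_mask <- function(r = 11.6, voxel = 0.7, rotation = c(0, 0, 0)) {
  make_eye_mask(eye_phantom_spec(r, r, r, rotation = rotation,
                                 voxel_size = voxel))
}

ellipsoid_mask <- function(ap = 12.8, ml = 12.15, si = 12.15, voxel = 0.7,
                           rotation = c(0, 0, 0), bump = 0) {
  make_eye_mask(eye_phantom_spec(ap, ml, si, bump_amplitude = bump,
                                 rotation = rotation, voxel_size = voxel))
}

strip_landmarks <- function(mask) {
  mask$landmarks <- list()
  mask
}

# tiny cohort for statistics tests: two eyes per subject, all five groups
small_cohort <- function(seed = 1, scale = 1) {
  gp <- default_group_params()
  gp$n_eyes <- as.integer(ceiling(gp$n_eyes * scale))
  sample_cohort(gp, seed = seed)
}

with_glaucoma_label <- function(cohort) {
  tab <- dplyr::filter(cohort, group != "ppg")
  tab$glaucoma <- tab$group %in% c("glaucoma", "glaucoma_myopia")
  tab$myopia_label <- tab$group %in% c("myopia", "glaucoma_myopia")
  tab
}

measure_axial_length_of <- function(mask) {
  measure_axial_length(mask, build_axis_frame(mask))
}

# angular difference (degrees) between the composition of two rotations and
# the identity: how far `rec` is from undoing `true`
rotation_residual_deg <- function(rec_angles, true_angles) {
  R <- eyemorph:::rotation_matrix(rec_angles) %*%
    eyemorph:::rotation_matrix(true_angles)
  acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}
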