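# small in-code fixtures shared across test files

uniform_vol <- function(value, dim = c(8, 8, 8), spacing = c(3, 3, 3),
                        modality = "PET") {
  image_volume(array(value, dim), spacing, modality)
}

full_mask <- function(vol) {
  binary_mask(array(TRUE, dim(vol$values)), vol$spacing)
}

# tiny two-component marrow pair: n_hi of the bone voxels at suv_hi
tiny_marrow <- function(n_bone = 40, n_hi = 14, suv_hi = 3, suv_lo = 0.5,
                        dim = c(6, 6, 6), spacing = c(3, 3, 3)) {
  ct <- array(40, dim)
  idx <- seq_len(n_bone)
  ct[idx] <- 700
  pet <- array(0.4, dim)
  pet[idx] <- c(rep(suv_hi, n_hi), rep(suv_lo, n_bone - n_hi))
  list(ct = image_volume(ct, spacing, "CT"),
       pet = image_volume(pet, spacing, "PET"),
       roi = pelvic_roi(1, dim[3]),
       n_bone = n_bone, n_hi = n_hi)
}

# fast small phantom config for pipeline-level tests
small_phantom_config <- function(...) {
  phantom_config(spacing = c(4, 4, 4), extent = c(120, 120, 120),
                 bone = list(outer_r = 50, inner_r = 38, z = c(20, 100)),
                 lesion = list(sigma = 8, peak = 17.5), ...)
}

# one-patient blood series from analyte nadirs (baseline first)
series_from_nadirs <- function(wbc, anc = 3, hgb = 120, plt = 180,
                               baseline = c(wbc = 7.3, anc = 5.1,
                                            hgb = 133, plt = 248)) {
  data.frame(day = c(0, 7, 14),
             wbc = c(baseline["wbc"], (baseline["wbc"] + wbc) / 2, wbc),
             anc = c(baseline["anc"], (baseline["anc"] + anc) / 2, anc),
             hgb = c(baseline["hgb"], (baseline["hgb"] + hgb) / 2, hgb),
             plt = c(baseline["plt"], (baseline["plt"] + plt) / 2, plt))
}
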