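#!/usr/bin/env Rscript
# Calibrates the default joint amplitudes of joint_config() on the default
# spine template:
#   - flexion amplitude:  mean inter-DSP decrease of 8.95 mm in flexion
#   - extension amplitude: mean inter-DSP increase of 8.95 mm in extension
#     (symmetric split of the 17.9 mm pre-desmotomy per-space range of motion)
#   - desmotomy flexion multiplier: mean per-space ROM of 23.5 mm post
# The resulting values are frozen as the joint_config() defaults.

library(spinekin)

pose <- build_template(spine_template())

rom_at <- function(flex_deg, ext_deg, mult = 1) {
  jc <- joint_config(flex_deg, ext_deg, max(1, mult))
  cond <- if (mult > 1) "post" else "pre"
  fl <- articulate(pose, jc, "flexion", cond)$truth$inter_dsp
  ex <- articulate(pose, jc, "extension", cond)$truth$inter_dsp
  c(flex = mean(fl), ext = mean(ex), rom = mean(abs(fl - ex)))
}

gap0 <- mean(articulate(pose, joint_config(0, 0), "resting", "pre")$truth$inter_dsp)

flex <- uniroot(function(a) rom_at(a, 0)["flex"] - (gap0 - 8.95),
                c(0.3, 1.8), tol = 1e-10)$root
ext <- uniroot(function(a) rom_at(0, a)["ext"] - (gap0 + 8.95),
               c(0.3, 1.8), tol = 1e-10)$root
mult <- uniroot(function(m) rom_at(flex, ext, m)["rom"] - 23.5,
                c(1.0001, 2.0), tol = 1e-10)$root

cat(sprintf("flexion_amplitude_deg    = %.6f\n", flex))
cat(sprintf("extension_amplitude_deg  = %.6f\n", ext))
cat(sprintf("isld_flexion_multiplier  = %.6f\n", mult))
cat(sprintf("check: pre ROM  %.4f mm\n", rom_at(flex, ext)["rom"]))
cat(sprintf("check: post ROM %.4f mm\n", rom_at(flex, ext, mult)["rom"]))
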