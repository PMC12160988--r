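# Scene builders for geometric/photometric tests.

# Vessel-free, noise-free, flat-illumination float scene: the measured pallor
# of each zone has the closed form pallor(zone) = zone_contrast[zone].
clean_scene <- function(zone_contrast = c(T = 1, TS = 1, NS = 1, N = 1,
                                          NI = 1, TI = 1),
                        ...) {
  fundus_scene(zone_contrast = zone_contrast, n_vessels = 0, noise_sd = 0,
               illumination = c(0, 0, 0), bit_depth = "float", ...)
}

# Distinct per-zone contrasts: any zone mix-up (swap, mirror error) shows up
# as a wrong measured value.
distinct_contrasts <- function() {
  c(T = 1.40, TS = 1.25, NS = 1.10, N = 1.18, NI = 1.05, TI = 1.32)
}

measured_vector <- function(res) {
  unlist(res[c("temporal", "temporal_superior", "nasal_superior", "nasal",
               "nasal_inferior", "temporal_inferior")])
}

contrast_vector <- function(zc) {
  c(zc[["T"]], zc[["TS"]], zc[["NS"]], zc[["N"]], zc[["NI"]], zc[["TI"]])
}
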