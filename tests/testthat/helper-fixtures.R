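# Shared fixtures: small deterministic scenes and datasets built in code.

quiet_spec <- function(..., seed = 1L) {
  scene_spec(..., stain_jitter_sd = 0, noise_sd = 0, seed = seed)
}

# A tiny balanced record set (n per class) at full 256 patch size.
tiny_records <- function(n_per_class = 2L, seed = 7L, noise_sd = 0,
                         jitter = 0) {
  generate_dataset(n_per_class, seed = seed, stain_jitter_sd = jitter,
                   noise_sd = noise_sd)$records
}

# Unit-norm H-DAB rows used by the renderer's noise-free default.
hdab_rows <- function() as_matrix(stain_matrix_hdab())[1:2, ]
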