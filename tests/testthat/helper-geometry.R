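# shared fixtures: a small fast geometry for numerics-only tests and the
# standard 2-degree / 64 samples-per-degree field for battery contracts
g_small <- stim_geometry(1, 32)      # 32 x 32, Nyquist 16 cpd
g_full <- stim_geometry()            # 128 x 128, Nyquist 32 cpd

uniform_opp <- function(lum, geometry = g_full)
  opponent_image(matrix(lum, geometry$n, geometry$n), geometry = geometry)

# all curves of a curve_family_set as a matrix (rows = abscissa)
family_matrix <- function(family)
  vapply(family$curves, function(cv) cv$visibility,
         numeric(length(family$curves[[1]]$abscissa)))
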