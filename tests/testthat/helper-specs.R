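# Shared fixture builders: everything is generated in code at test time.

const_density <- function(D, L) {
  density_spec("custom", L = L, profile = function(l) rep(D, length(l)))
}

lin100 <- function(D_min = 0.01, D_max = 0.30) {
  density_spec("linear", D_min, D_max, L = 100)
}

exp100 <- function(D_min = 0.01, D_max = 0.30, k = 3) {
  density_spec("exponential", D_min, D_max, L = 100, k = k)
}

# the non-monotonic showcase profile: sinusoid (A = 0.10, B = 20) on an
# exponential trend (k1 = 3) with exponentially growing amplitude (k2 = 3)
sin100 <- function() {
  density_spec("sinusoid_exponential_trend", 0.01, 0.30, L = 100,
               A = 0.10, B = 20, k1 = 3, k2 = 3)
}

# ~1000 well-separated dots: ordered constant-density 20 x 20 um field
thousand_dot_design <- function(pixel_size = 0.02) {
  spec <- gradient_spec(width = 20, length = 20,
                        density = const_density(0.1, 20))
  rasterize(generate_ordered(spec), pixel_size)
}
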