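# shared fixtures: canonical model parameters with a real branch
# (a2 * zeta > 0) and per-family free-coefficient sets
std_params <- function() pb_params(a1 = 1, a2 = 1, eta = 1, zeta = 1)

std_coeffs <- function(family) {
  switch(family,
         solitary = list(B0 = -1, B1 = 0, B2 = 1),
         soliton = list(B1 = -1, B2 = 3),
         elliptic = list(B2 = -0.5, B4 = 1),
         periodic_rational = list(B0 = 1, B2 = 2, C1 = 1.5),
         soliton_rational = list(B0 = 0.3, B1 = -2.5, B2 = 2, C1 = 2))
}

# a comfortable evaluation window per family (clear of s-poles for the
# standard coefficient sets)
std_window <- function(family) {
  switch(family,
         solitary = seq(-3, 3, length.out = 400),
         soliton = seq(-5, 5, length.out = 400),
         elliptic = seq(-6, 6, length.out = 400),
         periodic_rational = seq(-1, 1, length.out = 400),
         soliton_rational = seq(-4, 4, length.out = 400))
}

psym_ <- function(s) pbwave:::p_sym(s)
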