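# Element tables used by formula arithmetic.
#
# Monoisotopic masses are the masses of the most abundant stable isotope
# (AME2020 / IUPAC-CIAAW, >= 6 decimals); average weights are the IUPAC 2021
# conventional standard atomic weights. Both tables cover the elements seen
# in drug-like organic molecules plus common salts.

.mono_mass <- c(
  H  = 1.007825032,
  B  = 11.009305400,
  C  = 12.000000000,
  N  = 14.003074005,
  O  = 15.994914620,
  F  = 18.998403163,
  Na = 22.989769282,
  Mg = 23.985041697,
  Si = 27.976926535,
  P  = 30.973761998,
  S  = 31.972071174,
  Cl = 34.968852682,
  K  = 38.963706486,
  Ca = 39.962590863,
  Fe = 55.934936326,
  Zn = 63.929142012,
  Se = 79.916521800,
  Br = 78.918337600,
  I  = 126.904471900
)

.avg_weight <- c(
  H  = 1.008,  B  = 10.81,  C  = 12.011, N  = 14.007, O  = 15.999,
  F  = 18.998, Na = 22.990, Mg = 24.305, Si = 28.085, P  = 30.974,
  S  = 32.06,  Cl = 35.45,  K  = 39.098, Ca = 40.078, Fe = 55.845,
  Zn = 65.38,  Se = 78.971, Br = 79.904, I  = 126.904
)

# allowed valence states used for implicit-hydrogen completion (smallest
# state >= bond-order sum is taken; elements absent here get no implicit H)
.valences <- list(
  H = 1, B = 3, C = 4, N = c(3, 5), O = 2, F = 1,
  Si = 4, P = c(3, 5), S = c(2, 4, 6), Cl = 1, Br = 1, I = 1
)

.proton_mass <- 1.007276467

.known_elements <- function() names(.mono_mass)
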