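# Amino-acid scales and reference tables used throughout the package.
# All tables are indexed by the 20 canonical one-letter codes in
# alphabetical order ("ACDEFGHIKLMNPQRSTVWY").

#' @keywords internal
AA_ALPHA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Kyte-Doolittle hydropathy
KD_SCALE <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)[AA_ALPHA]

# Average residue masses (Da); MW of a chain adds one water
AA_MASS <- c(
  A =  71.0788, C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G =  57.0519, H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P =  97.1167, Q = 128.1307, R = 156.1875,
  S =  87.0782, T = 101.1051, V =  99.1326, W = 186.2132, Y = 163.1760
)[AA_ALPHA]
WATER_MASS <- 18.0153

# Vihinen average flexibility indices
AA_FLEX <- c(
  A = 0.984, C = 0.906, D = 1.068, E = 1.094, F = 0.915,
  G = 1.031, H = 0.950, I = 0.927, K = 1.102, L = 0.935,
  M = 0.952, N = 1.048, P = 1.049, Q = 1.037, R = 1.008,
  S = 1.046, T = 0.997, V = 0.931, W = 0.904, Y = 0.929
)[AA_ALPHA]

# EMBOSS pKa set for the isoelectric point model
PKA_POS <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
PKA_NEG <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

# Approximate human (Swiss-Prot) proteome residue frequencies; the fixed
# background composition of the synthetic-data generator.
HUMAN_AA_FREQ <- c(
  A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.037,
  G = 0.066, H = 0.026, I = 0.043, K = 0.057, L = 0.100,
  M = 0.021, N = 0.036, P = 0.063, Q = 0.048, R = 0.056,
  S = 0.083, T = 0.054, V = 0.060, W = 0.012, Y = 0.027
)[AA_ALPHA]
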