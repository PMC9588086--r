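# Independent oracles and frozen reference values used across the suite.

# Error function via the normal CDF (independent of the package internals).
erf_oracle <- function(x) 2 * pnorm(x * sqrt(2)) - 1
erfinv_oracle <- function(y) qnorm((1 + y) / 2) / sqrt(2)

# Population coefficient of variation, the AMI definition, written directly.
ami_oracle <- function(x) sqrt(mean((x - mean(x))^2)) / mean(x)

# The published transport table: molecular weight (g/mol), density
# (g/cm^3), and the printed radius (units of 1e-10 m), diffusivity
# (1e-10 m^2/s) and 150-um crossing time (s), all at 3 significant
# figures. Radii and diffusivities are kept as scaled mantissas so that
# numeric comparisons at these magnitudes are meaningful (all.equal falls
# back to absolute differences below its tolerance).
printed_transport_table <- function() {
  data.frame(
    name = c("Brilliant Blue FCF", "Temozolomide", "Paclitaxel",
             "Doxorubicin", "Carmustine", "Lomustine"),
    mw = c(792.9, 194.2, 853.9, 543.5, 214.1, 233.7),
    density = c(1.0, 2.0, 1.4, 1.6, 1.7, 1.4),
    r10 = c(6.80, 3.38, 6.23, 5.13, 3.69, 4.05),
    d10 = c(3.31, 6.66, 3.61, 4.39, 6.09, 5.56),
    t = c(34.0, 16.9, 31.2, 25.6, 18.5, 20.2),
    stringsAsFactors = FALSE
  )
}

# The published viability means (%) at 0/0.5/1/2 mM doses for the
# non-degradable gel (UV-polymerized PEG diacrylate) and the degradable
# adhesive 4-arm gel, and for the nitrosourea drug at uM doses.
printed_viability_tables <- function() {
  list(
    pegda_tmz = data.frame(dose = c(0, 0.5, 1, 2),
                           viability = c(86.4, 75.0, 34.0, 15.8)),
    pegac_tmz = data.frame(dose = c(0, 0.5, 1, 2),
                           viability = c(95.6, 83.9, 59.1, 44.0))
  )
}

# Direct closed-form inversion of the erf penetration model, used as the
# oracle for the bracketing root search in time_to_threshold().
time_to_threshold_oracle <- function(c_target, x, d, c0) {
  x^2 / (4 * d * erfinv_oracle(1 - c_target / c0)^2)
}

# Triplet-model autocorrelation written out independently of the package.
fcs_g_oracle <- function(tau, n, tau_d, p, trip, tau_t) {
  (1 / n) * (1 / (1 + tau / tau_d)) / sqrt(1 + p^2 * (tau / tau_d)) *
    (1 + trip / (1 - trip) * exp(-tau / tau_t))
}
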