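# Names of the structural parameters, in the order the compiled code expects.
.struct_names <- c("CL", "V1", "V2", "Q", "Kss", "kint", "Rtot", "Rtotp",
                   "kout", "Smax", "S50", "gamma")

# All estimable parameter names: the 12 structural parameters, the 50 mg
# cohort effect on V1, the two IIV standard deviations and the residual SD.
.all_par_names <- c(.struct_names, "v1_dose50_change",
                    "omega_Rtotp", "omega_kout", "sigma_log")

# Parameters estimated by default.  Kss, kint, Rtot and gamma are held at
# their published values: a 20-subject single-dose trial does not identify
# them jointly with the rest (see the methods vignette).
.free_default <- c("CL", "V1", "V2", "Q", "Rtotp", "kout", "Smax", "S50",
                   "v1_dose50_change", "omega_Rtotp", "omega_kout",
                   "sigma_log")

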