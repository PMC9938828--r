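# Shared fixtures built in code: the default registries and the reference
# seasonal moments, loaded once per test run.
ref_summary <- reference_summary()
metals_reg <- default_metals()
profiles_def <- default_profiles()
epa_reg <- metals_reg[metals_reg$agency == "EPA", ]

# Seasonal mean concentration for one metal (ug/L).
ref_mean <- function(metal, season) {
  ref_summary$mean[ref_summary$metal == metal &
                     ref_summary$season == season]
}
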