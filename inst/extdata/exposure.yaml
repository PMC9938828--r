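# Receptor exposure profiles for the drinking-water ingestion pathway.
# ir: water intake rate (L/day); ef: exposure frequency (days/year, triangular
# min/mode/max); ed: exposure duration (years); bw: body weight (kg);
# f: unit conversion ug -> mg; lifetime_years: carcinogenic averaging lifetime.
version: 1
profiles:
  children:
    ir: 1.25
    ef: {min: 180, mode: 345, max: 365}
    ed: 6
    bw: 10.64
    f: 1000
    lifetime_years: 70
  adults:
    ir: 1.95
    ef: {min: 180, mode: 345, max: 365}
    ed: 50
    bw: 61.68
    f: 1000
    lifetime_years: 70
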