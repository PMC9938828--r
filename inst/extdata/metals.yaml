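# Regulatory and toxicological constants per metal.
# standards: permissible concentrations S_i (ug/L) per agency.
# ideal:     desirable concentration I_i (ug/L) used by the HPI sub-index.
# rfd/tdi:   noncarcinogenic safe dose (mg/kg/day); exactly one per metal.
# sf:        carcinogenic slope factor (kg day/mg); only for metals with a
#            linear dose-response assessment (Pb here).
version: 1
metals:
  Pb:
    standards: {EPA: 15, WHO: 10}
    ideal: 0
    tdi: 0.0035
    sf: 0.0085
  Hg:
    standards: {EPA: 2, WHO: 6}
    ideal: 0
    rfd: 0.0003
  Mn:
    standards: {EPA: 50, WHO: 400}
    ideal: 100
    rfd: 0.14
  Fe:
    standards: {EPA: 300, WHO: 300}
    ideal: 0
    rfd: 0.7
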