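# Reference PBPK parameter set, stavudine solution group, 250 g rat.
# Units: Q, PS, Cl in L/h; V_total in L; Vd_per_kg in L/kg; BW in kg;
# P, Pgt, f_vasc dimensionless.  f_vasc values are package defaults
# (vascular fractions are not tabulated in the source physiology data).
group_label: solution
systemic:
  Qp: 3.09
  Cl: 0.46
  Vd_per_kg: 1.84
  BW: 0.250
  Pgt: 1.0
tissues:
  brain:
    Q: 0.08
    V_total: 1.5e-03
    f_vasc: 0.03
    PS: 3.75e-07
    P: 0.36
  liver:
    Q: 0.60
    V_total: 1.2e-02
    f_vasc: 0.21
    PS: 2.65e-06
    P: 0.27
  spleen:
    Q: 0.18
    V_total: 7.0e-04
    f_vasc: 0.22
    PS: 7.50e-06
    P: 0.70
  thymus:
    Q: 0.02
    V_total: 5.0e-04
    f_vasc: 0.03
    PS: 9.62e-08
    P: 0.28
formulation:
  kind: solution
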