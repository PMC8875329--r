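# Reference PBPK parameter set, stavudine gold-nanoparticle group, 250 g rat.
# Units as in rat_solution.yaml; Krel, Kup, Kup_plasma in 1/h.
# Krel is the in vitro release estimate at physiological pH (7.4).
group_label: nanoparticle
systemic:
  Qp: 3.09
  Cl: 0.73
  Vd_per_kg: 2.92
  BW: 0.250
  Pgt: 1.0
  Kup_plasma: 0.56
tissues:
  brain:
    Q: 0.08
    V_total: 1.5e-03
    f_vasc: 0.03
    PS: 0.17
    P: 0.46
    Kup: 7.9e-03
  liver:
    Q: 0.60
    V_total: 1.2e-02
    f_vasc: 0.21
    PS: 14.4
    P: 0.55
    Kup: 0.15
  spleen:
    Q: 0.18
    V_total: 7.0e-04
    f_vasc: 0.22
    PS: 0.49
    P: 0.77
    Kup: 0.03
  thymus:
    Q: 0.02
    V_total: 5.0e-04
    f_vasc: 0.03
    PS: 0.10
    P: 0.61
    Kup: 1.0e-03
formulation:
  kind: nanoparticle
  Krel: 0.058
  loading_fraction: 1.0
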