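# Worked calibration example: a 6-cm circular FFF msr field (SSD 70 cm,
# depth 10 cm, SDD 80 cm) measured with a calibrated Farmer-type chamber.
# The influence corrections, raw reading and quality-correction values
# are measured/tabulated inputs; the four scenarios compare the adapted
# TG-51 route against three ways of applying the msr code of practice.

calibration:
  nd_w_cGy_per_nC: 4.87
  chamber_id: exradin-a12
  laboratory: NRC

readings:
  # averaged over five repetitions of 200 MU
  m_raw_per_mu_nC: 0.1529
  repeats: 5

corrections:
  ptp: 0.9935
  pion: 1.0065
  ppol: 1.0
  pelec: 1.0
  pleak: 1.0
  # in-house volume-averaging correction from the measured profile
  prp: 1.0107

specifier:
  pdd10_esfs: 64.90
  esfs_side: 6.75

significance:
  coverage: 1

scenarios:
  - name: adapted-tg51
    formalism: tg51
    baseline: true
    include_prp_in_reading: true
    quality:
      # from the chamber-specific quadratic fit at %dd(10,10)X = 66.94
      value: 0.992
      includes_volume_averaging: false
      source: tg51_fit
      rel_uncertainty: 0.01

  - name: trs483-excluding-generic-kvol
    formalism: trs483
    include_prp_in_reading: true
    quality:
      # tabulated msr factor with the generic volume-averaging
      # component divided out, used with the in-house Prp
      recipe: strip
      tabulated: 1.004
      kvol_generic: 1.011
      rel_uncertainty: 0.01

  - name: trs483-including-generic-kvol
    formalism: trs483
    include_prp_in_reading: false
    quality:
      value: 1.004
      includes_volume_averaging: true
      source: trs483_table
      rel_uncertainty: 0.01

  - name: trs483-monte-carlo
    formalism: trs483
    include_prp_in_reading: false
    quality:
      # Monte-Carlo-evaluated factor (includes kvol = 1.0072 by
      # construction); uncertainty from beam-modeling only
      value: 1.0004
      includes_volume_averaging: true
      source: monte_carlo
      rel_uncertainty: 0.0002
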