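# Minimal synthetic-study configuration: two-batch panel subset at 1% area
# noise. Keys mirror the arguments of study_truth(); omitted keys keep the
# package defaults (nine-analyte panel, published calibration truth).
noise_cv: 0.01
mass_g: 0.1
volume_ml: 10
injection_volumes: [1, 2, 4, 6, 10, 16, 20]
seed: 42
contents:
  B1:
    neobavaisoflavone: 8.5
    bavachin: 4.2
    bavachinin: 7.9
    isobavachalcone: 8.8
    corylifol_a: 6.1
    methylbavachalcone: 1.5
  B2:
    neobavaisoflavone: 6.2
    bavachin: 3.3
    bavachinin: 5.5
    isobavachalcone: 7.1
    corylifol_a: 4.4
    methylbavachalcone: 1.1
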