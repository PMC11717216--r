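# Generic static single-chamber culture (plated hepatocytes).
name: generic_one_chamber
media_volume_ml: 1.0
cell_number: 1.0e+5
n_media_chambers: 1
recirculating: no
q_mix_ml_min: 0
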