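# Single-chamber recirculating liver chip, primary human hepatocytes.
name: cnbio
media_volume_ml: 1.60
cell_number: 3.0e+5
n_media_chambers: 1
recirculating: yes
q_mix_ml_min: 0.5        # nominal recirculation rate; single well-mixed chamber
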