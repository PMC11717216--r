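# Two-chamber recirculating liver chip; hepatocytes attached to chamber 1,
# chambers exchanged by the mixing flow Q_mix.
name: javelin
media_volume_ml: 1.30
cell_number: 2.15e+5
n_media_chambers: 2
recirculating: yes
q_mix_ml_min: 0.5        # nominal mixing flow between the two chambers
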