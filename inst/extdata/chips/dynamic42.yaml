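# Perfused liver chip placeholder: no published geometry is encoded here.
# Supply media_volume_ml and cell_number as overrides before building a model,
# e.g. load_chip_preset("dynamic42", media_volume_ml = 1.0, cell_number = 2e5).
name: dynamic42
media_volume_ml: .na
cell_number: .na
n_media_chambers: 1
recirculating: yes
q_mix_ml_min: 0.5
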