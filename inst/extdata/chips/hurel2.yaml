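# Static 3D hepatocyte spheroid, larger-format plate.
name: hurel2
media_volume_ml: 0.10
cell_number: 3.0e+4
n_media_chambers: 1
recirculating: no
q_mix_ml_min: 0
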