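# Per-cusp width and height of the human pulmonary valve (mean, SD, mm),
# published cadaveric morphometry.
cusp,width_mean,width_sd,height_mean,height_sd
left,21.61,3.56,11.78,2.36
right,21.58,4.25,12.03,2.38
anterior,21.41,4.14,12.05,2.40
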