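# Cadaveric pulmonary-valve reference values (mean, SD), Yang's series.
# Units: areas mm^2, lengths mm.
metric,mean,sd
cusp_area,238.71,63.47
annulus_diameter,18.2,3.2
annulus_circumference,57.177,10.053
orifice_area,456.60,106.62
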