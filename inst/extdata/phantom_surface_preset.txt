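# Surface-mode render preset calibrated for the bundled phantoms
# (background 0, soft tissue 40, bone 100). The opacity ramp isolates the
# bone band; use it together with a picking threshold of 60.
low=50
high=90
max_opacity=1
reflectivity_gain=1
mode=surface
ambient=0.2
background=0,0,0
# headlight plus a warm fill light from the upper left
light=0,0,-1,1
light=-1,1,-1,0.4,1,0.85,0.7
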