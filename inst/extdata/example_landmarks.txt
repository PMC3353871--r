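# Example landmark definition file: running numbers, optional Bookstein
# type tag, free-text description. Landmarks 1-3 double as the median-plane
# anchors (PL1-3), landmarks 4-5 as the horizontal axis (A1-2).
1 type=1 anterior midline suture intersection (PL1)
2 type=1 posterior midline suture intersection (PL2)
3 type=1 ventral midline point (PL3)
4 type=3 anterior-most midline point (A1)
5 type=3 posterior-most midline point (A2)
6 type=3 tip of left coronoid process
7 type=3 tip of right coronoid process
8 type=2 left molar cusp maximum
9 type=2 right molar cusp maximum
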