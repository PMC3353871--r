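# Symmetry map for example_landmarks.txt: midline points lie on the
# sagittal plane; pairs are linked left/right for the visual ordering check.
midline 1 2 3 4 5
pair 6 7
pair 8 9
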