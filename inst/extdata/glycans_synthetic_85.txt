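# Synthetic representative N-glycan composition database (85 compositions).
# One composition per line: H=Hex, N=HexNAc, F=Fuc, S=NeuAc, G=NeuGc.
H3N2
H3N2F1
H4N2
H3N3
H4N2F1
H5N2
H3N3F1
H4N3
H3N4
H5N2F1
H6N2
H3N3S1
H4N3F1
H5N3
H3N4F1
H4N4
H3N5
H6N2F1
H3N3F1S1
H7N2
H4N3S1
H5N3F1
H6N3
H3N4S1
H4N4F1
H5N4
H3N5F1
H4N5
H7N2F1
H4N3F1S1
H8N2
H3N6
H5N3S1
H6N3F1
H3N4F1S1
H7N3
H4N4S1
H5N4F1
H6N4
H3N5S1
H4N5F1
H5N5
H8N2F1
H3N6F1
H5N3F1S1
H9N2
H4N6
H6N3S1
H3N4S2
H7N3F1
H4N4F1S1
H8N3
H5N4S1
H6N4F1
H3N5F1S1
H7N4
H4N5S1
H5N5F1
H6N5
H3N6S1
H9N2F1
H4N6F1
H6N3F1S1
H3N4F1S2
H5N6
H7N3S1
H4N4S2
H8N3F1
H5N4F1S1
H9N3
H6N4S1
H3N5S2
H7N4F1
H4N5F1S1
H8N4
H5N5S1
H6N5F1
H3N6F1S1
H7N5
H4N6S1
H5N6F1
H7N3F1S1
H4N4F1S2
H6N6
H8N3S1
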