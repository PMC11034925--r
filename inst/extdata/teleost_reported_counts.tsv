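quantity	value
atcne_vertebrate	6585
atcne_neopterygian	6934
atcne_3r	12411
zones_with_atcne	1982
zones_without_atcne	682
paralog_atcne_2r_derived	215
paralog_atcne_3r_derived	762
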