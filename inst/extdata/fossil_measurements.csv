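taxon,dentary_mm,lifespan_yr
Morganucodon,20,14
Kuehneotherium,21.9,9
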