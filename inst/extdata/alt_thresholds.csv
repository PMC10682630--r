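# Alternate intake benchmarks reported alongside (never substituted for) the
# USEPA reference doses: the WHO/EFSA acceptable daily intake for nitrate and
# the EFSA adequate intake for fluoride (which covers all exposure sources).
parameter,threshold,source,label
NO3,3.7,WHO-EFSA,acceptable daily intake
F,0.05,EFSA,adequate intake
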