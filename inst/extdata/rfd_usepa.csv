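# Chronic oral reference doses (RfD, mg per kg body weight per day).
# The Ag value is the standard USEPA IRIS 5.0e-3 mg/kg/day; override via
# hazard_quotient()/run_config() if a different value is required.
parameter,rfd,source
NO3,1.6,USEPA
F,0.04,USEPA
Ag,0.005,USEPA
Ba,0.2,USEPA
Cr,1.5,USEPA
Fe,0.7,USEPA
Mn,0.024,USEPA
Sr,0.6,USEPA
Zn,0.3,USEPA
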