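complex,dG_solv,dG_coul,dG_nonelec,dG_b_reported
PGAL-Protonated His,46,-96,-5.0,-55
PGAL-Zwitterionic His,33,-116,-5.0,-88
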