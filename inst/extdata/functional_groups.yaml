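# Functional-group SMARTS library for coverage analysis.
# Editable: labels map to patterns in the package's supported SMARTS
# dialect (see ?smarts_matches). This starter set covers the chemistry of
# the built-in toy templates.
alkyl_carbon: "[#6X4:1]"
hydroxyl: "[#8X2H1+0:1]"
ether_oxygen: "[#8X2H0+0:1]"
primary_amine: "[#7X3H2:1]"
carbonyl: "[#6X3:1]=[#8X1]"
amide: "[#6X3:1](=[#8X1])-[#7]"
sulfonyl: "[#16X4:1](=[#8])=[#8]"
nitrile: "[#6X2:1]#[#7X1]"
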