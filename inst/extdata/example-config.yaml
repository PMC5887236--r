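# Example configuration for the rxnpath command-line driver.
# Atom indices are 0-based into the concatenated reactant atom order.
reactant: "ICl.ICl.[H][H]"
product: "Cl.Cl.II"
charge: 0
active: [0, 1, 2, 3, 4, 5]
max_form: 2
max_break: 2
molecularity: 2
ring_max: 0
localized_charges: true
delta: 6
e_tol: 20
topq: 0.5
outdir: rxnpath-out
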