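# Bundled CCD component-code lookup for the PFAS ligands used in the
# package's worked examples. Only this curated subset is resolvable;
# arbitrary CCD lookup is out of scope.
code	name	smiles
8PF	perfluorooctanoic acid (PFOA)	OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F
4EI	perfluoroheptanoic acid (PFHpA)	OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F
4I6	perfluorononanoic acid (PFNA)	OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F
P8S	perfluorooctanesulfonic acid (PFOS)	OS(=O)(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F
TFA	trifluoroacetic acid	OC(=O)C(F)(F)F
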