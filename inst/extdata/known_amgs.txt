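# Functional labels already reported in prior marine virome surveys.
# One label per line; matched case-insensitively. Edit or replace via
# known_amg_functions(path = ...).
photosystem II psbA
photosystem II psbD
photosystem I psaA
high light inducible protein
plastocyanin petE
ferredoxin petF
transaldolase
mazG pyrophosphohydrolase
phoH phosphate starvation
pstS phosphate ABC transporter
ribonucleotide reductase
thymidylate synthase
dUTPase
cobS cobalamin synthase
speD S-adenosylmethionine decarboxylase
prnA tryptophan halogenase
2OG-Fe(II) oxygenase
glycosyltransferase
methyltransferase
carbon metabolism talC
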