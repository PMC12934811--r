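# Salt / formulation suffixes stripped (when trailing) during drug-name
# normalization. One token per line; matching is done on the normalized
# (lowercase, punctuation-free) form. Edit freely.
hydrochloride
hcl
dihydrochloride
hydrobromide
hbr
mesylate
methanesulfonate
maleate
tosylate
tartrate
citrate
fumarate
succinate
acetate
phosphate
sulfate
sodium
disodium
potassium
calcium
besylate
oxalate
malate
lactate
trifluoroacetate
tfa
hydrate
monohydrate
dihydrate
trihydrate
hemihydrate
freebase
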