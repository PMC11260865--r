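# Trailing salt / ester / counter-ion tokens stripped during drug
# deduplication (case-insensitive, applied repeatedly to trailing words).
hydrochloride
dihydrochloride
hydrobromide
tartrate
bitartrate
succinate
fumarate
maleate
mesylate
besylate
tosylate
citrate
phosphate
diphosphate
sulfate
sulphate
nitrate
acetate
dipropionate
propionate
valerate
palmitate
decanoate
enanthate
pamoate
lactate
gluconate
carbonate
bicarbonate
chloride
bromide
iodide
sodium
potassium
calcium
magnesium
disodium
dipotassium
hemihydrate
monohydrate
dihydrate
trihydrate
anhydrous
pegylated
liposomal
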