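# Conjugates of two active moieties that stay distinct parent drugs
# (one name per line, case-insensitive match on the full normalised name).
trastuzumab emtansine
trastuzumab deruxtecan
brentuximab vedotin
gemtuzumab ozogamicin
inotuzumab ozogamicin
polatuzumab vedotin
enfortumab vedotin
sacituzumab govitecan
estramustine
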