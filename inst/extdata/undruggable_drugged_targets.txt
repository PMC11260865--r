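# Targets with associated drugs that do not appear in the druggable-genome
# list (published list, transcribed literally; FDPS is printed even though the
# drugged-target table itself lists FDFT1).
FDPS
TNNT3
AOPEP
NDUFAF3
MET
RPS2
RAF1
WT1
RPL32
MYH7
MYH6
POLR2A
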