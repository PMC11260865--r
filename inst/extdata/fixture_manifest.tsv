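file	md5
table1_targets.tsv	d366deb1b8eb91fcfac899344d1f2ef6
table2_evidence.tsv	4526f513456f4487254ad987999b97bd
bp_associated_targets.txt	3ba246cfcab13350e8ea494c3d824017
undruggable_drugged_targets.txt	bb43634d33ffec601b0a466af00e6b0c
salt_lexicon.txt	30cff63ab5f29aba962a92a791d8e496
conjugate_whitelist.txt	9242bc0924715f206ac14edf21dcf09a
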