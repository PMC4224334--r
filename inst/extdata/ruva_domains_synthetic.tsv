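# SYNTHETIC stand-in fixture: RuvA structural domain coordinate map.
# Domain roles are from the published description (I and II: tetramerization
# and junction-DNA binding; III: branch migration via heteroduplex contact
# with RuvB); the residue boundaries are constructed placeholders consistent
# with the domain assignments of the published substitution table.
domain	aa_start	aa_end	role
I	1	63	tetramerization and junction-DNA binding
II	64	128	tetramerization and junction-DNA binding
III	129	203	branch migration (heteroduplex contact with RuvB)
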