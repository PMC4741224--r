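# Registrability of nomenclatural acts, one row per act descriptor.
# Cell values: "+" recorded, "-" not recorded, "n/a" not applicable under the
# registry's code, "(+)" recorded but not attested in the published grid
# (table_blank annotation: these cells are filled in on the reading that the
# governing code covers the act, and are excluded from transcription diffs).
# fungal_names mirrors index_fungorum: both are official fungal registries
# with the same scope.
kind	descriptor	ipni	index_fungorum	mycobank	fungal_names	zoobank
new_taxon	suprafamilial	-	+	+	+	(+)
new_taxon	familial	+	+	+	+	+
new_taxon	infrafamilial	+	+	+	+	+
new_taxon	generic	+	+	+	+	+
new_taxon	infrageneric	+	+	+	+	+
new_taxon	specific	+	+	+	+	+
new_taxon	infraspecific	+	+	+	+	+
new_taxon	hybrid	+	+	+	+	n/a
new_replacement_name	-	+	+	+	+	(+)
new_combination	-	+	+	+	+	(+)
tautonym	-	+	+	+	+	n/a
typification	holotype	+	+	+	+	(+)
typification	lectotype	-	+	+	+	(+)
typification	neotype	-	+	+	+	(+)
typification	epitype	-	+	+	+	n/a
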