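# Status-phrase vocabulary: maps the status phrase printed in a treatment's
# nomenclature block to an act kind and (where applicable) a rank or type
# kind.  Journals vary in the phrases they print; edit this file, not code.
phrase	kind	rank	type_kind
ordo nov.	new_taxon	suprafamilial
fam. nov.	new_taxon	familial
subfam. nov.	new_taxon	infrafamilial
trib. nov.	new_taxon	infrafamilial
gen. nov.	new_taxon	generic
subgen. nov.	new_taxon	infrageneric
sp. nov.	new_taxon	specific
subsp. nov.	new_taxon	infraspecific
var. nov.	new_taxon	infraspecific
nom. nov.	new_replacement_name
comb. nov.	new_combination
holotype designated	typification		holotype
lectotype designated	typification		lectotype
neotype designated	typification		neotype
epitype designated	typification		epitype
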