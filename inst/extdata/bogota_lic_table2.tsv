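species	lic	introduced
Sambucus nigra	6.5	1
Matricaria chamomilla	6.3	1
Ocimum basilicum	5.7	1
Lippia alba	5.2	0
Calendula officinalis	5.1	0
Ruta graveolens	5.0	1
Aloysia citriodora	4.9	0
Foeniculum vulgare	4.4	1
Trichanthera gigantea	4.2	0
Juglans neotropica	4.2	0
Persea americana	4.0	0
Allium sativum	4.0	1
Uncaria tomentosa	3.9	0
Valeriana officinalis	3.5	1
Ambrosia peruviana	3.5	0
Equisetum bogotense	3.5	0
Columnea kalbreyeriana	3.4	0
Cymbopogon citratus	3.3	0
Petiveria alliacea	3.2	0
Lantana camara	3.2	0
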