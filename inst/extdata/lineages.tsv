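label	taxid	superkingdom	phylum	class	order	family	genus	species
Alistipes	239759	Bacteria	Bacteroidetes	Bacteroidia	Bacteroidales	Rikenellaceae	Alistipes
Bacteroides	29523	Bacteria	Bacteroidetes	Bacteroidia	Bacteroidales	Bacteroidaceae	Bacteroides
Bacteroides fragilis	817	Bacteria	Bacteroidetes	Bacteroidia	Bacteroidales	Bacteroidaceae	Bacteroides	Bacteroides fragilis
Prevotella copri	165179	Bacteria	Bacteroidetes	Bacteroidia	Bacteroidales	Prevotellaceae	Prevotella	Prevotella copri
Phocaeicola coprocola	310298	Bacteria	Bacteroidetes	Bacteroidia	Bacteroidales	Bacteroidaceae	Phocaeicola	Phocaeicola coprocola
Parabacteroides distasonis	823	Bacteria	Bacteroidetes	Bacteroidia	Bacteroidales	Tannerellaceae	Parabacteroides	Parabacteroides distasonis
Pedobacter	84567	Bacteria	Bacteroidetes	Sphingobacteriia	Sphingobacteriales	Sphingobacteriaceae	Pedobacter
Bifidobacterium	41200	Bacteria	Actinobacteria	Actinomycetia	Bifidobacteriales	Bifidobacteriaceae	Bifidobacterium
Blautia	572511	Bacteria	Firmicutes	Clostridia	Clostridiales	Lachnospiraceae	Blautia
Dorea	189330	Bacteria	Firmicutes	Clostridia	Clostridiales	Lachnospiraceae	Dorea
Coprococcus	33042	Bacteria	Firmicutes	Clostridia	Clostridiales	Lachnospiraceae	Coprococcus
Lachnospira	28050	Bacteria	Firmicutes	Clostridia	Clostridiales	Lachnospiraceae	Lachnospira
Lachnospiraceae	186803	Bacteria	Firmicutes	Clostridia	Clostridiales	Lachnospiraceae
Roseburia	841	Bacteria	Firmicutes	Clostridia	Clostridiales	Lachnospiraceae	Roseburia
Clostridium	1506	Bacteria	Firmicutes	Clostridia	Clostridiales	Clostridiaceae	Clostridium
Ruminococcaceae	219	Bacteria	Firmicutes	Clostridia	Clostridiales	Ruminococcaceae
Ruminococcus	41978	Bacteria	Firmicutes	Clostridia	Clostridiales	Ruminococcaceae	Ruminococcus
Faecalibacterium	216851	Bacteria	Firmicutes	Clostridia	Clostridiales	Ruminococcaceae	Faecalibacterium
Faecalibacterium prausnitzii	853	Bacteria	Firmicutes	Clostridia	Clostridiales	Ruminococcaceae	Faecalibacterium	Faecalibacterium prausnitzii
Anaerotruncus	244127	Bacteria	Firmicutes	Clostridia	Clostridiales	Ruminococcaceae	Anaerotruncus
Butyricicoccus	580596	Bacteria	Firmicutes	Clostridia	Clostridiales	Butyricicoccaceae	Butyricicoccus
Christensenella	990721	Bacteria	Firmicutes	Clostridia	Clostridiales	Christensenellaceae	Christensenella
Lactobacillus	1591	Bacteria	Firmicutes	Bacilli	Lactobacillales	Lactobacillaceae	Lactobacillus
Streptococcus	1301	Bacteria	Firmicutes	Bacilli	Lactobacillales	Streptococcaceae	Streptococcus
Enterococcus	1350	Bacteria	Firmicutes	Bacilli	Lactobacillales	Enterococcaceae	Enterococcus
Enterococcaceae	81852	Bacteria	Firmicutes	Bacilli	Lactobacillales	Enterococcaceae
Holdemania	61170	Bacteria	Firmicutes	Erysipelotrichia	Erysipelotrichales	Erysipelotrichaceae	Holdemania
Phascolarctobacterium	33024	Bacteria	Firmicutes	Negativicutes	Acidaminococcales	Acidaminococcaceae	Phascolarctobacterium
Dialister	39948	Bacteria	Firmicutes	Negativicutes	Veillonellales	Veillonellaceae	Dialister
Shigella	625	Bacteria	Proteobacteria	Gammaproteobacteria	Enterobacterales	Enterobacteriaceae	Shigella
Desulfovibrio	872	Bacteria	Proteobacteria	Deltaproteobacteria	Desulfovibrionales	Desulfovibrionaceae	Desulfovibrio
Bilophila	35832	Bacteria	Proteobacteria	Deltaproteobacteria	Desulfovibrionales	Desulfovibrionaceae	Bilophila
Akkermansia muciniphila	239935	Bacteria	Verrucomicrobia	Verrucomicrobiae	Verrucomicrobiales	Akkermansiaceae	Akkermansia	Akkermansia muciniphila
Methanobrevibacter	2172	Archaea	Euryarchaeota	Methanobacteria	Methanobacteriales	Methanobacteriaceae	Methanobrevibacter
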